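#' @keywords internal
with_seed_ <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

sample_one <- function(x) if (length(x) == 1) x else sample(x, 1)

# Draw one clip inside a segment and lay out its frame indices.
# Strides with 64*a frames beyond the clip are infeasible; if none of the
# stride range fits (clip shorter than 256 frames at stride 4), the stride
# is capped at the range minimum and indices are loop-padded into the clip
# by wrapping, flagged via `padded`.
draw_clip <- function(start_s, end_s, clip_len_s, fps, frames_per_clip,
                      stride_range) {
  seg_len <- end_s - start_s
  if (seg_len >= clip_len_s) {
    clip_start <- stats::runif(1, start_s, end_s - clip_len_s)
    clip_len <- clip_len_s
  } else {
    clip_start <- start_s
    clip_len <- seg_len
  }
  f <- floor(clip_len * fps)
  feasible <- stride_range[frames_per_clip * stride_range <= f]
  if (length(feasible)) {
    a <- sample_one(feasible)
    padded <- FALSE
    offsets <- a * (seq_len(frames_per_clip) - 1L)
  } else {
    a <- min(stride_range)
    padded <- TRUE
    offsets <- (a * (seq_len(frames_per_clip) - 1L)) %% max(f, 1L)
  }
  c0 <- floor(clip_start * fps)
  list(clip_start_s = clip_start, stride_a = as.integer(a), padded = padded,
       frame_indices = as.integer(c0 + offsets))
}

#' Annotation-segment-balanced sampling plan (ASBS)
#'
#' Generates a training-clip manifest in which every annotation segment —
#' surgical phase and background alike — contributes the same number of
#' clips per epoch. For each segment, `clips_per_segment` clips of
#' `clip_len_s` seconds are placed uniformly at random inside the segment
#' (a segment shorter than the clip length yields the whole segment);
#' `frames_per_clip` frames are taken at a stride drawn uniformly from
#' `stride_range`. With v videos totalling `sum(n + m)` segments, each
#' epoch holds exactly `clips_per_segment * sum(n + m)` records.
#'
#' @param ann Annotation tibble (see [read_annotations()]).
#' @param vocab A [phase_vocabulary()].
#' @param epochs Number of training epochs to plan.
#' @param clips_per_segment Clips drawn per segment per epoch (default 5).
#' @param clip_len_s Clip length in seconds (default 20).
#' @param fps Video frame rate (default 30).
#' @param frames_per_clip Frames sampled per clip (default 64).
#' @param stride_range Allowed frame strides (default 4:9).
#' @param durations Optional `video_id, duration_s` tibble.
#' @param seed Integer seed; the plan is byte-identical across runs with
#'   the same seed.
#' @return A clip-plan tibble: `video_id, segment_id, phase, epoch, clip,
#'   clip_start_s, stride_a, padded, frame_indices` (list column of
#'   absolute 0-based frame numbers).
#' @export
asbs_plan <- function(ann, vocab, epochs = 1, clips_per_segment = 5,
                      clip_len_s = 20, fps = 30, frames_per_clip = 64,
                      stride_range = 4:9, durations = NULL, seed = 1) {
  stopifnot(clips_per_segment >= 1, epochs >= 1)
  covers <- segment_covers(ann, vocab, durations)
  with_seed_(seed, {
    purrr::map_dfr(seq_len(epochs), function(ep) {
      purrr::map_dfr(seq_len(nrow(covers)), function(k) {
        seg <- covers[k, ]
        if (seg$end_s <= seg$start_s) {
          rlang::warn(sprintf("skipping zero-length segment %d of video '%s'",
                              seg$segment_id, seg$video_id))
          return(NULL)
        }
        purrr::map_dfr(seq_len(clips_per_segment), function(j) {
          cl <- draw_clip(seg$start_s, seg$end_s, clip_len_s, fps,
                          frames_per_clip, stride_range)
          tibble::tibble(
            video_id = seg$video_id, segment_id = seg$segment_id,
            phase = seg$phase, epoch = ep, clip = j,
            clip_start_s = cl$clip_start_s, stride_a = cl$stride_a,
            padded = cl$padded, frame_indices = list(cl$frame_indices))
        })
      })
    })
  })
}

segment_covers <- function(ann, vocab, durations = NULL) {
  durs <- video_durations(ann, durations)
  purrr::map_dfr(sort(unique(ann$video_id)), function(vid) {
    seg <- dplyr::filter(ann, .data$video_id == vid)
    d <- durs$duration_s[durs$video_id == vid]
    cov <- segment_cover(seg, d, vocab)
    dplyr::mutate(cov, segment_id = dplyr::row_number())
  })
}

#' Class-balanced sampling plan
#'
#' The class-balanced baseline sampler: per epoch, `total_per_epoch` clips
#' are split as evenly as possible across the classes present in the
#' annotations (remainder to the earliest classes in vocabulary order) —
#' upsampling minority classes with replacement and undersampling majority
#' classes. Clips are drawn uniformly over each class's segments.
#'
#' @inheritParams asbs_plan
#' @param total_per_epoch Total clips per epoch (>= number of classes with
#'   annotated time).
#' @return A clip-plan tibble with the same columns as [asbs_plan()].
#' @export
balanced_plan <- function(ann, vocab, epochs = 1, total_per_epoch,
                          clip_len_s = 20, fps = 30, frames_per_clip = 64,
                          stride_range = 4:9, durations = NULL, seed = 1) {
  covers <- segment_covers(ann, vocab, durations)
  covers <- covers[covers$end_s > covers$start_s, ]
  present_idx <- sort(unique(phase_index(covers$phase, vocab)))
  absent <- setdiff(seq_len(n_classes(vocab)), present_idx)
  if (length(absent)) {
    rlang::warn(paste0("class(es) with no annotated time excluded: ",
                       paste(vocab$names[absent], collapse = ", ")))
  }
  k <- length(present_idx)
  if (total_per_epoch < k) {
    rlang::abort("total_per_epoch must be at least the number of classes present")
  }
  quota <- rep(total_per_epoch %/% k, k)
  rem <- total_per_epoch %% k
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L

  with_seed_(seed, {
    purrr::map_dfr(seq_len(epochs), function(ep) {
      purrr::map_dfr(seq_len(k), function(ci) {
        cls <- vocab$names[present_idx[ci]]
        segs <- covers[covers$phase == cls, ]
        purrr::map_dfr(seq_len(quota[ci]), function(j) {
          seg <- segs[sample_one(seq_len(nrow(segs))), ]
          cl <- draw_clip(seg$start_s, seg$end_s, clip_len_s, fps,
                          frames_per_clip, stride_range)
          tibble::tibble(
            video_id = seg$video_id, segment_id = seg$segment_id,
            phase = cls, epoch = ep, clip = j,
            clip_start_s = cl$clip_start_s, stride_a = cl$stride_a,
            padded = cl$padded, frame_indices = list(cl$frame_indices))
        })
      })
    })
  })
}

#' Per-class clip counts of a sampling plan
#'
#' @param plan A clip-plan tibble.
#' @return Tibble `epoch, phase, n_clips`.
#' @export
plan_summary <- function(plan) {
  dplyr::count(plan, .data$epoch, .data$phase, name = "n_clips")
}

#' Write a sampling plan as JSON Lines
#'
#' One clip record per line.
#'
#' @param plan A clip-plan tibble.
#' @param path Output path.
#' @return `plan`, invisibly.
#' @export
write_clip_plan <- function(plan, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(plan))) {
    row <- as.list(plan[k, ])
    row$frame_indices <- row$frame_indices[[1]]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(plan)
}
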