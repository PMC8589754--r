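#' Validate an annotation table
#'
#' Annotations are tibbles with columns `video_id`, `phase` (class name),
#' `start_s`, `end_s` on a seconds timeline; segments are half-open
#' `[start_s, end_s)`, must not overlap within a video, and seconds not
#' covered by any segment are implicitly background.
#'
#' @param ann Annotation tibble.
#' @param vocab A [phase_vocabulary()].
#' @return The validated tibble, sorted by video and start time, invisibly
#'   usable in a pipe.
#' @export
validate_annotations <- function(ann, vocab) {
  req <- c("video_id", "phase", "start_s", "end_s")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    rlang::abort(paste0("annotation table missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "pkfilter_parse_error")
  }
  phase_index(ann$phase, vocab)  # errors on unknown names
  if (any(ann$start_s < 0) || any(ann$start_s >= ann$end_s)) {
    rlang::abort("segments must satisfy 0 <= start_s < end_s",
                 class = "pkfilter_validation_error")
  }
  ann <- dplyr::arrange(ann, .data$video_id, .data$start_s)
  for (vid in unique(ann$video_id)) {
    seg <- dplyr::filter(ann, .data$video_id == vid)
    if (nrow(seg) > 1) {
      bad <- which(seg$start_s[-1] < seg$end_s[-nrow(seg)])
      if (length(bad)) {
        i <- bad[1]
        rlang::abort(sprintf(
          "video '%s': overlapping segments [%g,%g) '%s' and [%g,%g) '%s'",
          vid, seg$start_s[i], seg$end_s[i], seg$phase[i],
          seg$start_s[i + 1], seg$end_s[i + 1], seg$phase[i + 1]
        ), class = "pkfilter_validation_error")
      }
    }
  }
  ann
}

#' Read phase annotations from CSV
#'
#' Expects a header `video_id,phase,start_s,end_s` with phases given by name.
#'
#' @param path CSV file path.
#' @param vocab A [phase_vocabulary()].
#' @return A validated annotation tibble (possibly zero rows).
#' @export
read_annotations <- function(path, vocab) {
  ann <- readr::read_csv(path, col_types = readr::cols(
    video_id = readr::col_character(),
    phase = readr::col_character(),
    start_s = readr::col_double(),
    end_s = readr::col_double()
  ))
  validate_annotations(ann, vocab)
}

#' Write phase annotations to CSV
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `ann`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  readr::write_csv(ann[, c("video_id", "phase", "start_s", "end_s")], path)
  invisible(ann)
}

#' Per-video durations implied by an annotation table
#'
#' @param ann Annotation tibble.
#' @param durations Optional tibble `video_id, duration_s` overriding the
#'   inferred values (the maximum segment end per video).
#' @return Tibble `video_id, duration_s`.
#' @export
video_durations <- function(ann, durations = NULL) {
  if (!is.null(durations)) {
    return(tibble::as_tibble(durations)[, c("video_id", "duration_s")])
  }
  dplyr::summarise(dplyr::group_by(ann, .data$video_id),
                   duration_s = max(.data$end_s), .groups = "drop")
}

#' Rasterize one video's annotation to a per-second label sequence
#'
#' The timeline is 1 Hz, 0-based and half-open: second `t` represents
#' `[t, t+1)` and receives the label of the segment containing `t + 0.5`,
#' or the background class if no segment covers it.
#'
#' @param ann Annotation tibble for a single video (its `video_id` column
#'   must have one unique value; zero rows allowed).
#' @param duration_s Video duration in seconds (>= 1).
#' @param vocab A [phase_vocabulary()].
#' @return Integer vector of length `floor(duration_s)` of class indices.
#' @export
labels_from_annotation <- function(ann, duration_s, vocab) {
  if (duration_s < 1) rlang::abort("duration_s must be >= 1")
  if (nrow(ann) > 0 && length(unique(ann$video_id)) > 1) {
    rlang::abort("labels_from_annotation expects a single video")
  }
  n <- floor(duration_s)
  labels <- rep(vocab$background_index, n)
  if (nrow(ann) > 0) {
    idx <- phase_index(ann$phase, vocab)
    mid <- seq_len(n) - 0.5
    for (k in seq_len(nrow(ann))) {
      hit <- mid >= ann$start_s[k] & mid < ann$end_s[k]
      labels[hit] <- idx[k]
    }
  }
  labels
}

#' Explicit segment cover of a video, including background gaps
#'
#' Returns the annotation segments together with the background segments
#' filling every uncovered interval of `[0, duration_s)`, sorted by start.
#' This is the segment inventory the clip samplers draw from: a video with
#' n surgical segments has at most n + 1 background segments.
#'
#' @inheritParams labels_from_annotation
#' @return Tibble `video_id, phase, start_s, end_s` covering `[0, duration_s)`.
#' @export
segment_cover <- function(ann, duration_s, vocab) {
  bg <- vocab$names[vocab$background_index]
  vid <- if (nrow(ann) > 0) ann$video_id[1] else NA_character_
  ann <- dplyr::arrange(ann, .data$start_s)
  out <- list()
  cursor <- 0
  for (k in seq_len(nrow(ann))) {
    if (ann$start_s[k] > cursor) {
      out[[length(out) + 1]] <- tibble::tibble(
        video_id = vid, phase = bg, start_s = cursor, end_s = ann$start_s[k])
    }
    out[[length(out) + 1]] <- ann[k, c("video_id", "phase", "start_s", "end_s")]
    cursor <- ann$end_s[k]
  }
  if (cursor < duration_s) {
    out[[length(out) + 1]] <- tibble::tibble(
      video_id = vid, phase = bg, start_s = cursor, end_s = duration_s)
  }
  dplyr::bind_rows(out)
}
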