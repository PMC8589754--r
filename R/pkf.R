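#' PKF parameters
#'
#' Tunable parameters of prior knowledge filtering. The per-phase sliding
#' window is `W_i = round(min(max(w_min, eta * T_i), w_max))` seconds, the
#' in-window prediction threshold is `J_i = mu_i * W_i`, and the gap
#' connection threshold is `L_i = min(nu_i * T_i, l_max)` seconds, where
#' `T_i` is the phase's minimum phase time prior. Defaults are the values
#' selected by grid search on surgical validation data: `w_min = 10`,
#' `w_max = 60`, `eta = 0.2`, `mu = 0.5`, `nu = 0.4`, `l_max = 180`.
#'
#' @param w_min,w_max Minimum / maximum sliding-window size (seconds).
#' @param eta Window weight applied to the minimum phase time.
#' @param mu In-window majority weight; scalar, or a named per-phase vector.
#' @param nu Connection weight; scalar, or a named per-phase vector.
#' @param l_max Maximum gap connection threshold (seconds).
#' @return A `pkf_params` object.
#' @export
pkf_params <- function(w_min = 10, w_max = 60, eta = 0.2,
                       mu = 0.5, nu = 0.4, l_max = 180) {
  stopifnot(eta > 0, all(mu > 0), all(mu <= 1), all(nu > 0),
            w_min >= 1, w_min <= w_max, l_max >= 0)
  structure(list(w_min = w_min, w_max = w_max, eta = eta,
                 mu = mu, nu = nu, l_max = l_max),
            class = "pkf_params")
}

#' @export
print.pkf_params <- function(x, ...) {
  cat(sprintf(
    "<pkf_params> w_min=%g w_max=%g eta=%g mu=%s nu=%s l_max=%g\n",
    x$w_min, x$w_max, x$eta,
    paste(x$mu, collapse = ","), paste(x$nu, collapse = ","), x$l_max))
  invisible(x)
}

per_phase_weight <- function(w, phase_name) {
  if (length(w) == 1 && is.null(names(w))) return(unname(w))
  if (!phase_name %in% names(w)) {
    rlang::abort(paste0("no per-phase weight for '", phase_name, "'"))
  }
  unname(w[[phase_name]])
}

#' Sliding-window size for a phase
#'
#' `W_i = round(min(max(w_min, eta * t_i), w_max))`, in whole seconds.
#'
#' @param t_i Minimum phase time of the phase, seconds (> 0).
#' @param params A [pkf_params()].
#' @return Integer window size in seconds.
#' @examples
#' window_size(100)   # 20
#' window_size(1000)  # 60, clipped at w_max
#' @export
window_size <- function(t_i, params = pkf_params()) {
  if (any(t_i <= 0)) rlang::abort("minimum phase time must be positive")
  as.integer(round(pmin(pmax(params$w_min, params$eta * t_i), params$w_max)))
}

#' In-window prediction threshold
#'
#' `J_i = mu_i * W_i`. A second is smoothed to phase i when the count of
#' phase-i predictions in its window is strictly greater than this value.
#'
#' @param w_i Window size, seconds (>= 1).
#' @param mu_i Majority weight.
#' @return The (real-valued) threshold.
#' @export
pkf_threshold <- function(w_i, mu_i = 0.5) {
  if (any(w_i < 1)) rlang::abort("window size must be >= 1")
  mu_i * w_i
}

#' Gap connection threshold for a phase
#'
#' `L_i = min(nu_i * t_i, l_max)`: same-phase prediction runs separated by a
#' gap of at most `L_i` seconds are connected.
#'
#' @inheritParams window_size
#' @param nu_i Optional connection weight overriding `params$nu`.
#' @return Threshold in seconds.
#' @export
connection_threshold <- function(t_i, params = pkf_params(), nu_i = NULL) {
  if (any(t_i <= 0)) rlang::abort("minimum phase time must be positive")
  nu_i <- nu_i %||% params$nu
  pmin(nu_i * t_i, params$l_max)
}

#' Apply phase-order rules to a label sequence
#'
#' Some phases are tied to a part of the procedure (e.g. exploration/
#' inspection happens at the beginning); predictions of such a phase wholly
#' outside its allowed fractional span of the video are wrong and are
#' relabeled as background.
#'
#' @param labels Integer label sequence (1 Hz).
#' @param rules Order-rule tibble `phase, start_frac, end_frac` (phase by
#'   name), e.g. `priors$order_rules`.
#' @param vocab A [phase_vocabulary()].
#' @return The corrected label sequence.
#' @export
apply_order_rules <- function(labels, rules, vocab) {
  if (length(labels) == 0) rlang::abort("labels must be non-empty")
  if (is.null(rules) || nrow(rules) == 0) return(labels)
  n <- length(labels)
  t0 <- seq_len(n) - 1L  # second t covers [t, t+1)
  for (k in seq_len(nrow(rules))) {
    idx <- phase_index(rules$phase[k], vocab)
    lo <- rules$start_frac[k] * n
    hi <- rules$end_frac[k] * n
    outside <- labels == idx & (t0 + 1 <= lo | t0 > hi)
    labels[outside] <- vocab$background_index
  }
  labels
}

#' Sliding-window majority track for one phase
#'
#' For each second `t` the window is seconds
#' `[t - floor(w_i/2), t + floor(w_i/2)]` intersected with the video; the
#' track is TRUE where the count of phase predictions in the window strictly
#' exceeds `mu_i * |window|`. Truncating the window at the video boundaries
#' and rescaling the threshold keeps the majority semantics uniform at the
#' edges.
#'
#' @param labels Integer label sequence.
#' @param phase Class index of the phase.
#' @param w_i Window size, seconds (>= 1).
#' @param mu_i Majority weight.
#' @return Logical vector, one entry per second.
#' @export
smooth_phase_track <- function(labels, phase, w_i, mu_i = 0.5) {
  if (w_i < 1) rlang::abort("window size must be >= 1")
  n <- length(labels)
  h <- floor(w_i / 2)
  x <- cumsum(labels == phase)
  t <- seq_len(n)
  lo <- pmax(1L, t - h)
  hi <- pmin(n, t + h)
  cnt <- x[hi] - c(0, x)[lo]
  cnt > mu_i * (hi - lo + 1)
}

#' Segments of a boolean track, with gap connection
#'
#' Extracts maximal TRUE runs as half-open `[start_s, end_s)` intervals and
#' connects consecutive runs whose gap is at most `l_i` seconds,
#' transitively (merging is iterated to its closure).
#'
#' @param track Logical per-second track.
#' @param l_i Gap connection threshold, seconds.
#' @return Tibble `start_s, end_s` (integer seconds), possibly zero rows.
#' @export
track_to_segments <- function(track, l_i = 0) {
  if (length(track) == 0 || !any(track)) {
    return(tibble::tibble(start_s = integer(), end_s = integer()))
  }
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- r$values
  s <- starts[keep]; e <- ends[keep]
  # runs are sorted, so a left-to-right sweep realizes the transitive closure
  out_s <- s[1]; out_e <- e[1]
  if (length(s) > 1) {
    for (k in 2:length(s)) {
      if (s[k] - out_e[length(out_e)] <= l_i) {
        out_e[length(out_e)] <- e[k]
      } else {
        out_s <- c(out_s, s[k]); out_e <- c(out_e, e[k])
      }
    }
  }
  tibble::tibble(start_s = as.integer(out_s), end_s = as.integer(out_e))
}

#' Mean model confidence over an interval
#'
#' The arithmetic mean of the trace's probability for `phase` over the
#' half-open interval `[start_s, end_s)` — the average confidence used to
#' settle overlapping phase claims.
#'
#' @param trace Trace tibble.
#' @param phase Class index or name.
#' @param start_s,end_s Interval bounds in whole seconds.
#' @param vocab A [phase_vocabulary()].
#' @return Mean probability in `[0, 1]`.
#' @export
mean_confidence <- function(trace, phase, start_s, end_s, vocab) {
  if (start_s < 0 || start_s >= end_s || end_s > nrow(trace)) {
    rlang::abort("require 0 <= start_s < end_s <= duration")
  }
  idx <- phase_index(phase, vocab)
  col <- trace[[vocab$names[idx]]]
  mean(col[(start_s + 1):end_s])
}

#' Resolve overlapping per-phase segments by mean confidence
#'
#' Per-phase smoothing produces one segment list per phase; where segments
#' of different phases overlap, each maximal interval with a constant set of
#' two or more claiming phases is assigned to the phase with the highest
#' mean confidence over that interval (ties to the lower class index).
#' Intervals claimed by a single phase keep it. Adjacent same-phase pieces
#' are re-merged and each final segment carries its own mean confidence.
#'
#' @param phase_segments Named list (by phase name) of `start_s, end_s`
#'   tibbles, each individually non-overlapping.
#' @param trace Trace tibble supplying the confidences.
#' @param vocab A [phase_vocabulary()].
#' @return A segment tibble `video_id, phase, start_s, end_s, mean_conf`,
#'   sorted and non-overlapping.
#' @export
resolve_overlaps <- function(phase_segments, trace, vocab) {
  vid <- trace_video_id(trace)
  empty <- tibble::tibble(video_id = character(), phase = character(),
                          start_s = integer(), end_s = integer(),
                          mean_conf = double())
  phase_segments <- phase_segments[purrr::map_int(phase_segments, nrow) > 0]
  if (length(phase_segments) == 0) return(empty)

  flat <- dplyr::bind_rows(purrr::imap(phase_segments, function(seg, ph) {
    dplyr::mutate(seg, phase = ph, .before = 1)
  }))
  cuts <- sort(unique(c(flat$start_s, flat$end_s)))
  lo <- cuts[-length(cuts)]; hi <- cuts[-1]
  # claimant set per elementary interval
  claim <- purrr::map(seq_along(lo), function(k) {
    sort(phase_index(
      flat$phase[flat$start_s <= lo[k] & flat$end_s >= hi[k]], vocab))
  })
  covered <- purrr::map_int(claim, length) > 0
  lo <- lo[covered]; hi <- hi[covered]; claim <- claim[covered]
  if (length(lo) == 0) return(empty)

  # group consecutive, touching intervals with identical claimant sets
  sig <- purrr::map_chr(claim, paste, collapse = ",")
  grp <- cumsum(c(TRUE, sig[-1] != sig[-length(sig)] |
                    lo[-1] != hi[-length(hi)]))
  assigned <- purrr::map_dfr(split(seq_along(lo), grp), function(ix) {
    a <- min(lo[ix]); b <- max(hi[ix])
    cand <- claim[[ix[1]]]
    if (length(cand) > 1) {
      conf <- vapply(cand, function(p)
        mean_confidence(trace, p, a, b, vocab), double(1))
      cand <- cand[which.max(conf)]  # which.max takes the first: lower index
    }
    tibble::tibble(phase_idx = cand, start_s = a, end_s = b)
  })

  assigned <- dplyr::arrange(assigned, .data$start_s)
  merged <- list()
  for (k in seq_len(nrow(assigned))) {
    m <- length(merged)
    if (m > 0 && merged[[m]]$phase_idx == assigned$phase_idx[k] &&
        merged[[m]]$end_s == assigned$start_s[k]) {
      merged[[m]]$end_s <- assigned$end_s[k]
    } else {
      merged[[m + 1]] <- as.list(assigned[k, ])
    }
  }
  out <- dplyr::bind_rows(merged)
  tibble::tibble(
    video_id = vid,
    phase = vocab$names[out$phase_idx],
    start_s = as.integer(out$start_s),
    end_s = as.integer(out$end_s),
    mean_conf = purrr::pmap_dbl(out, function(phase_idx, start_s, end_s)
      mean_confidence(trace, phase_idx, start_s, end_s, vocab))
  )
}

#' Remove segments shorter than the minimum phase time
#'
#' Segments with `end_s - start_s < T_i` are too short to be their phase and
#' are replaced by background (dropped from the segment list).
#'
#' @param segments Segment tibble (`phase, start_s, end_s`, ...).
#' @param priors A `phase_priors` object.
#' @return The filtered segment tibble.
#' @export
drop_short_segments <- function(segments, priors) {
  if (nrow(segments) == 0) return(segments)
  t_i <- prior_lookup(priors, "min_duration_s")
  keep <- (segments$end_s - segments$start_s) >= t_i[segments$phase]
  segments[keep, ]
}

#' Cap per-phase segment counts at the maximum incidence
#'
#' A phase appearing more often than its maximum incidence `I_i` keeps only
#' its `I_i` most confident segments (ties to the earlier start); surplus
#' segments are replaced by background.
#'
#' @inheritParams drop_short_segments
#' @return The capped segment tibble, sorted by start.
#' @export
cap_incidence <- function(segments, priors) {
  if (nrow(segments) == 0) return(segments)
  i_max <- prior_lookup(priors, "max_incidence")
  segments |>
    dplyr::group_by(.data$phase) |>
    dplyr::arrange(dplyr::desc(.data$mean_conf), .data$start_s,
                   .by_group = TRUE) |>
    dplyr::mutate(.rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.rank <= i_max[.data$phase]) |>
    dplyr::select(-".rank") |>
    dplyr::arrange(.data$start_s)
}

#' Prior knowledge filtering of a prediction trace
#'
#' Runs the full PKF pipeline on a per-second probability trace:
#' \enumerate{
#'   \item argmax labels (ties to the lower class index);
#'   \item phase-order correction of raw labels ([apply_order_rules()]);
#'   \item per-phase sliding-window majority smoothing
#'     ([smooth_phase_track()]) with window `W_i` and threshold `J_i`,
#'     followed by gap connection at `L_i` ([track_to_segments()]);
#'   \item confidence-based overlap resolution ([resolve_overlaps()]);
#'   \item short-segment removal ([drop_short_segments()]) and incidence
#'     capping ([cap_incidence()]).
#' }
#' The result is deterministic in its inputs.
#'
#' @param trace Trace tibble (see [read_trace()] / [new_trace()]).
#' @param priors A `phase_priors` object covering all non-background phases.
#' @param params A [pkf_params()].
#' @return A `pkf_result`: list with `segments` (tibble `video_id, phase,
#'   start_s, end_s, mean_conf`), `labels` (the filtered per-second label
#'   sequence), `raw_labels`, `duration_s`, `video_id` and `vocab`.
#' @export
apply_pkf <- function(trace, priors, params = pkf_params()) {
  vocab <- priors$vocab
  trace <- validate_trace(trace, vocab)
  raw <- argmax_labels(trace, vocab)
  labels <- apply_order_rules(raw, priors$order_rules, vocab)

  t_i <- prior_lookup(priors, "min_duration_s")
  per_phase <- list()
  for (idx in surgical_indices(vocab)) {
    ph <- vocab$names[idx]
    w <- window_size(t_i[[ph]], params)
    mu <- per_phase_weight(params$mu, ph)
    l <- connection_threshold(t_i[[ph]], params,
                              nu_i = per_phase_weight(params$nu, ph))
    track <- smooth_phase_track(labels, idx, w, mu)
    per_phase[[ph]] <- track_to_segments(track, l)
  }

  segments <- resolve_overlaps(per_phase, trace, vocab) |>
    drop_short_segments(priors) |>
    cap_incidence(priors)

  out_labels <- rep(vocab$background_index, length(raw))
  for (k in seq_len(nrow(segments))) {
    sp <- (segments$start_s[k] + 1):segments$end_s[k]
    out_labels[sp] <- phase_index(segments$phase[k], vocab)
  }
  structure(
    list(segments = segments, labels = out_labels, raw_labels = raw,
         duration_s = length(raw), video_id = trace_video_id(trace),
         vocab = vocab, params = params),
    class = "pkf_result"
  )
}

#' @export
print.pkf_result <- function(x, ...) {
  cat(sprintf("<pkf_result> video '%s', %d s, %d segment(s)\n",
              x$video_id, x$duration_s, nrow(x$segments)))
  print(x$segments, n = 20)
  invisible(x)
}

#' Write filtered segments to JSON or CSV
#'
#' @param result A `pkf_result` or a segment tibble.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return The segment tibble, invisibly.
#' @export
write_segments <- function(result, path) {
  seg <- if (inherits(result, "pkf_result")) result$segments else result
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(seg, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    readr::write_csv(seg, path)
  }
  invisible(seg)
}
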