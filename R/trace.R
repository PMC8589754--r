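#' Prediction traces
#'
#' A prediction trace is a tibble with one row per second of video: a column
#' `t` (0-based second) and one probability column per vocabulary class,
#' named after the classes. Each row sums to 1.
#'
#' @param probs Numeric matrix, `duration_s x n_classes`.
#' @param vocab A [phase_vocabulary()].
#' @param video_id Video identifier attached as the `video_id` attribute.
#' @return A trace tibble.
#' @export
new_trace <- function(probs, vocab, video_id = "video") {
  probs <- as.matrix(probs)
  if (ncol(probs) != n_classes(vocab)) {
    rlang::abort("probs must have one column per vocabulary class")
  }
  colnames(probs) <- vocab$names
  tr <- tibble::as_tibble(probs)
  tr <- tibble::add_column(tr, t = seq_len(nrow(probs)) - 1L, .before = 1)
  attr(tr, "video_id") <- video_id
  validate_trace(tr, vocab)
}

#' Validate a prediction trace
#'
#' Rows whose sum deviates from 1 by at most `tol` are silently
#' renormalized; a larger deviation is a validation error.
#'
#' @param trace Trace tibble (`t` plus one column per class).
#' @param vocab A [phase_vocabulary()].
#' @param tol Row-sum tolerance (default 1e-3).
#' @return The validated (possibly renormalized) trace.
#' @export
validate_trace <- function(trace, vocab, tol = 1e-3) {
  miss <- setdiff(vocab$names, names(trace))
  if (length(miss)) {
    rlang::abort(paste0("trace missing class column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "pkfilter_parse_error")
  }
  m <- trace_matrix(trace, vocab)
  if (any(m < -1e-12) || any(m > 1 + 1e-9)) {
    rlang::abort("trace probabilities must lie in [0, 1]",
                 class = "pkfilter_validation_error")
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    bad <- which(abs(rs - 1) > tol)[1]
    rlang::abort(sprintf("trace row %d sums to %.6f (|1 - sum| > %g)",
                         bad, rs[bad], tol),
                 class = "pkfilter_validation_error")
  }
  if (any(abs(rs - 1) > 1e-12)) {
    m <- m / rs
    trace[vocab$names] <- tibble::as_tibble(m)
  }
  trace
}

#' Read a prediction trace from CSV
#'
#' Expects a column `t` followed by one probability column per class.
#'
#' @inheritParams validate_trace
#' @param path CSV file path.
#' @param video_id Video identifier; defaults to the file name without
#'   extension.
#' @return A validated trace tibble.
#' @export
read_trace <- function(path, vocab,
                       video_id = tools::file_path_sans_ext(basename(path))) {
  tr <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  tr <- validate_trace(tr, vocab)
  attr(tr, "video_id") <- video_id
  tr
}

#' Write a prediction trace to CSV
#'
#' Probabilities are serialized with six decimal places.
#'
#' @param trace Trace tibble.
#' @param path Output path.
#' @return `trace`, invisibly.
#' @export
write_trace <- function(trace, path) {
  out <- trace
  num <- setdiff(names(out), "t")
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  readr::write_csv(out, path)
  invisible(trace)
}

trace_matrix <- function(trace, vocab) {
  as.matrix(trace[, vocab$names, drop = FALSE])
}

trace_video_id <- function(trace) {
  attr(trace, "video_id") %||% "video"
}

#' Per-second argmax labels of a trace
#'
#' Ties are broken toward the lowest class index, which favors the
#' background class when it is listed first.
#'
#' @param trace Trace tibble.
#' @param vocab A [phase_vocabulary()].
#' @return Integer label sequence, one entry per second.
#' @export
argmax_labels <- function(trace, vocab) {
  m <- trace_matrix(trace, vocab)
  max.col(m, ties.method = "first")
}
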