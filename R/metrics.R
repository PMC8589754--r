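#' Frame-level accuracy
#'
#' Proportion of seconds where the predicted label equals ground truth.
#'
#' @param pred,truth Equal-length integer label sequences.
#' @return Fraction in `[0, 1]`.
#' @export
frame_accuracy <- function(pred, truth) {
  check_same_length(pred, truth)
  mean(pred == truth)
}

check_same_length <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 1) {
    rlang::abort("pred and truth must be non-empty sequences of equal length")
  }
}

#' Support-weighted Jaccard score
#'
#' Per class c, the frame-level Jaccard index
#' `J_c = |pred_c intersect truth_c| / |pred_c union truth_c|` over seconds;
#' classes absent from both sequences are skipped. The score is the mean of
#' the `J_c` weighted by ground-truth support (seconds of truth labeled c,
#' renormalized over the non-skipped classes). The background class is
#' included like any other.
#'
#' @inheritParams frame_accuracy
#' @param vocab A [phase_vocabulary()].
#' @return Score in `[0, 1]`; 1 iff the sequences are identical.
#' @export
weighted_jaccard <- function(pred, truth, vocab) {
  check_same_length(pred, truth)
  n <- length(truth)
  score <- 0
  wsum <- 0
  for (c in seq_len(n_classes(vocab))) {
    inter <- sum(pred == c & truth == c)
    union <- sum(pred == c | truth == c)
    if (union == 0) next
    w <- sum(truth == c) / n
    score <- score + w * inter / union
    wsum <- wsum + w
  }
  if (wsum == 0) return(0)
  score / wsum
}

#' Per-phase precision, recall and F1
#'
#' One-vs-rest precision, recall and F1 per class. Ratios with a zero
#' denominator are reported as 0 and flagged in the `undefined` column.
#'
#' @inheritParams weighted_jaccard
#' @return Tibble `phase, support, precision, recall, f1, undefined`.
#' @export
per_class_prf <- function(pred, truth, vocab) {
  check_same_length(pred, truth)
  purrr::map_dfr(seq_len(n_classes(vocab)), function(c) {
    tp <- sum(pred == c & truth == c)
    fp <- sum(pred == c & truth != c)
    fn <- sum(pred != c & truth == c)
    undef <- FALSE
    prec <- if (tp + fp == 0) { undef <- TRUE; 0 } else tp / (tp + fp)
    rec <- if (tp + fn == 0) { undef <- TRUE; 0 } else tp / (tp + fn)
    f1 <- if (prec + rec == 0) { undef <- undef || tp + fp + fn == 0; 0 } else {
      2 * prec * rec / (prec + rec)
    }
    tibble::tibble(phase = vocab$names[c], support = tp + fn,
                   precision = prec, recall = rec, f1 = f1,
                   undefined = undef)
  })
}

#' Confusion matrix
#'
#' Rows are ground-truth classes, columns predicted classes. With
#' `normalize = TRUE` each row is divided by its sum (all-zero rows for
#' classes absent from the truth are left at zero).
#'
#' @inheritParams weighted_jaccard
#' @param normalize Row-normalize? Default FALSE.
#' @return A `n_classes x n_classes` matrix with class-name dimnames.
#' @export
confusion_matrix <- function(pred, truth, vocab, normalize = FALSE) {
  check_same_length(pred, truth)
  k <- n_classes(vocab)
  m <- table(factor(truth, levels = seq_len(k)),
             factor(pred, levels = seq_len(k)))
  m <- matrix(as.numeric(m), k, k,
              dimnames = list(truth = vocab$names, pred = vocab$names))
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs == 0, 1, rs)
  }
  m
}

#' Evaluate a predicted label sequence against ground truth
#'
#' Bundles frame accuracy, support-weighted Jaccard, per-phase
#' precision/recall/F1 and the confusion matrix into one report.
#'
#' @inheritParams weighted_jaccard
#' @return A `phase_eval` object.
#' @export
evaluate_phases <- function(pred, truth, vocab) {
  check_same_length(pred, truth)
  structure(
    list(
      accuracy = frame_accuracy(pred, truth),
      weighted_jaccard = weighted_jaccard(pred, truth, vocab),
      per_class = per_class_prf(pred, truth, vocab),
      confusion = confusion_matrix(pred, truth, vocab, normalize = TRUE),
      n_seconds = length(truth),
      vocab = vocab
    ),
    class = "phase_eval"
  )
}

#' @export
print.phase_eval <- function(x, ...) {
  cat(sprintf(
    "<phase_eval> %d s: frame accuracy %.4f, weighted Jaccard %.4f\n",
    x$n_seconds, x$accuracy, x$weighted_jaccard))
  print(x$per_class, n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy phase_eval
#' @export
tidy.phase_eval <- function(x, ...) x$per_class

#' @method glance phase_eval
#' @export
glance.phase_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 weighted_jaccard = x$weighted_jaccard,
                 n_seconds = x$n_seconds)
}

#' @method tidy pkf_result
#' @export
tidy.pkf_result <- function(x, ...) x$segments

#' @method glance pkf_result
#' @export
glance.pkf_result <- function(x, ...) {
  tibble::tibble(video_id = x$video_id, duration_s = x$duration_s,
                 n_segments = nrow(x$segments),
                 mean_conf = mean(x$segments$mean_conf))
}

#' Write an evaluation report to JSON
#'
#' @param eval A `phase_eval` object.
#' @param path Output path.
#' @return `eval`, invisibly.
#' @export
write_eval <- function(eval, path) {
  jsonlite::write_json(
    list(accuracy = eval$accuracy,
         weighted_jaccard = eval$weighted_jaccard,
         n_seconds = eval$n_seconds,
         per_class = eval$per_class,
         confusion = eval$confusion),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", matrix = "rowmajor")
  invisible(eval)
}
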