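#' Focal loss
#'
#' The class-imbalance loss `FL(p) = -alpha * (1 - p)^gamma * log(p)`,
#' where `p` is the model's estimated probability for the true class. The
#' `(1 - p)^gamma` factor down-weights easily classified examples so
#' training concentrates on hard ones; with `gamma = 0` the loss reduces to
#' `alpha` times the cross-entropy. Defaults `alpha = 4`, `gamma = 2` are
#' the values used for surgical phase classification.
#'
#' @param p Probabilities of the true class, in `[0, 1]`; values are
#'   clipped below at 1e-12 before the logarithm.
#' @param alpha Balance weight (> 0).
#' @param gamma Focusing exponent (>= 0).
#' @param reduce `"none"` (elementwise, default) or `"mean"` (batch mean).
#' @return Loss value(s), non-negative.
#' @examples
#' focal_loss(1)                    # 0: perfectly classified
#' focal_loss(0.5)                  # 4 * 0.25 * log(2)
#' focal_loss(c(0.2, 0.9), reduce = "mean")
#' @export
focal_loss <- function(p, alpha = 4, gamma = 2,
                       reduce = c("none", "mean")) {
  reduce <- match.arg(reduce)
  stopifnot(alpha > 0, gamma >= 0)
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    rlang::abort("p must lie in [0, 1]")
  }
  p <- pmax(p, 1e-12)
  fl <- -alpha * (1 - p)^gamma * log(p)
  if (reduce == "mean") mean(fl) else fl
}
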