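#' Ribbon plot of label sequences
#'
#' Draws one horizontal color band per label sequence over video time —
#' the standard way to compare raw predictions, filtered predictions and
#' ground truth for a video at a glance.
#'
#' @param label_list Named list of equal-length integer label sequences
#'   (e.g. `list(raw = ..., filtered = ..., truth = ...)`).
#' @param vocab A [phase_vocabulary()].
#' @return A ggplot object.
#' @export
plot_ribbon <- function(label_list, vocab) {
  stopifnot(length(label_list) > 0, !is.null(names(label_list)))
  df <- purrr::imap_dfr(label_list, function(labels, nm) {
    tibble::tibble(band = nm, t = seq_along(labels) - 1L,
                   phase = factor(vocab$names[labels],
                                  levels = vocab$names))
  })
  df$band <- factor(df$band, levels = rev(names(label_list)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$band,
                                   fill = .data$phase)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_viridis_d(drop = FALSE, name = "phase") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ribbon
#' @param object A `pkf_result`.
#' @param truth Optional ground-truth label sequence to add as a band.
#' @param ... Unused.
#' @method autoplot pkf_result
#' @export
autoplot.pkf_result <- function(object, truth = NULL, ...) {
  bands <- list(raw = object$raw_labels, filtered = object$labels)
  if (!is.null(truth)) bands$truth <- truth
  plot_ribbon(bands, object$vocab)
}

#' Confusion-matrix heatmap of an evaluation report
#'
#' @param object A `phase_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_eval
#' @export
autoplot.phase_eval <- function(object, ...) {
  m <- object$confusion
  df <- tidyr::expand_grid(truth = rownames(m), pred = colnames(m))
  df$value <- as.vector(t(m))
  df$truth <- factor(df$truth, levels = rev(rownames(m)))
  df$pred <- factor(df$pred, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), name = "rate") +
    ggplot2::labs(x = "predicted", y = "ground truth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
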