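#' PKF parameter grid
#'
#' The candidate values swept by [grid_search_pkf()]. The default grid
#' brackets the defaults of [pkf_params()] with step 0.1 in each weight.
#'
#' @param eta_values,mu_values,nu_values Candidate weights.
#' @param fixed A [pkf_params()] supplying the remaining (fixed) fields
#'   `w_min`, `w_max`, `l_max`.
#' @return A `pkf_grid` object.
#' @export
pkf_grid <- function(eta_values = seq(0.1, 0.5, by = 0.1),
                     mu_values = seq(0.3, 0.7, by = 0.1),
                     nu_values = seq(0.2, 0.6, by = 0.1),
                     fixed = pkf_params()) {
  stopifnot(length(eta_values) > 0, length(mu_values) > 0,
            length(nu_values) > 0)
  for (eta in eta_values) for (mu in mu_values) for (nu in nu_values) {
    pkf_params(fixed$w_min, fixed$w_max, eta, mu, nu, fixed$l_max)
  }
  structure(list(eta_values = eta_values, mu_values = mu_values,
                 nu_values = nu_values, fixed = fixed),
            class = "pkf_grid")
}

#' Grid search for PKF parameters on a validation set
#'
#' Evaluates [apply_pkf()] at every `(eta, mu, nu)` grid point against the
#' validation annotations and returns the best parameters. The objective is
#' mean frame accuracy across videos (the headline metric); the
#' support-weighted Jaccard is selectable instead. Ties go to the
#' lexicographically smallest `(eta, mu, nu)`.
#'
#' @param traces Named list of trace tibbles, keyed by `video_id`.
#' @param ann Validation annotation tibble covering the same videos.
#' @param priors A `phase_priors` object.
#' @param grid A [pkf_grid()].
#' @param metric `"accuracy"` (default) or `"jaccard"`.
#' @param durations Optional `video_id, duration_s` tibble.
#' @return List with `best_params` (a [pkf_params()]), `best_score`, and
#'   `scores` — a tibble `eta, mu, nu, score` over the full grid.
#' @export
grid_search_pkf <- function(traces, ann, priors, grid = pkf_grid(),
                            metric = c("accuracy", "jaccard"),
                            durations = NULL) {
  metric <- match.arg(metric)
  vocab <- priors$vocab
  vids <- sort(unique(ann$video_id))
  missing <- setdiff(vids, names(traces))
  extra <- setdiff(names(traces), vids)
  if (length(missing) || length(extra)) {
    rlang::abort(paste0(
      "traces and annotations must cover the same video ids; ",
      if (length(missing)) paste0("missing traces: ",
                                  paste(missing, collapse = ", "), "; "),
      if (length(extra)) paste0("unannotated traces: ",
                                paste(extra, collapse = ", "))))
  }
  durs <- video_durations(ann, durations)
  truths <- purrr::map(vids, function(vid) {
    labels_from_annotation(dplyr::filter(ann, .data$video_id == vid),
                           durs$duration_s[durs$video_id == vid], vocab)
  })
  names(truths) <- vids

  points <- tidyr::expand_grid(eta = grid$eta_values, mu = grid$mu_values,
                               nu = grid$nu_values)
  scores <- purrr::pmap_dbl(points, function(eta, mu, nu) {
    p <- pkf_params(grid$fixed$w_min, grid$fixed$w_max, eta, mu, nu,
                    grid$fixed$l_max)
    mean(purrr::map_dbl(vids, function(vid) {
      res <- apply_pkf(traces[[vid]], priors, p)
      truth <- truths[[vid]]
      m <- min(length(res$labels), length(truth))
      if (metric == "accuracy") {
        frame_accuracy(res$labels[seq_len(m)], truth[seq_len(m)])
      } else {
        weighted_jaccard(res$labels[seq_len(m)], truth[seq_len(m)], vocab)
      }
    }))
  })
  tab <- dplyr::mutate(points, score = scores) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$eta, .data$mu, .data$nu)
  best <- tab[1, ]
  list(
    best_params = pkf_params(grid$fixed$w_min, grid$fixed$w_max,
                             best$eta, best$mu, best$nu, grid$fixed$l_max),
    best_score = best$score,
    scores = dplyr::mutate(points, score = scores)
  )
}
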