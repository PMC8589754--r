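#' Read a unified YAML configuration
#'
#' A single YAML file can carry any of: `vocabulary` (names +
#' background_index), `priors` / `order_rules` (as in [write_priors()]),
#' `pkf_params` (fields of [pkf_params()]), `grid` (eta_values, mu_values,
#' nu_values), `template` (phases + gap_range_s) and `noise` (fields of
#' [noise_model()]). Missing blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return List with elements `vocab`, `priors` (or NULL), `params`,
#'   `grid`, `template`, `noise`.
#' @export
read_pkf_config <- function(path) {
  obj <- yaml::read_yaml(path)
  vocab <- if (!is.null(obj$vocabulary)) {
    phase_vocabulary(unlist(obj$vocabulary$names),
                     obj$vocabulary$background_index %||% 1L)
  } else {
    sleeve_gastrectomy_vocab()
  }
  priors <- NULL
  if (!is.null(obj$priors)) {
    pt <- dplyr::bind_rows(lapply(obj$priors, tibble::as_tibble))
    rules <- if (length(obj$order_rules)) {
      dplyr::bind_rows(lapply(obj$order_rules, tibble::as_tibble))
    } else {
      tibble::tibble(phase = character(), start_frac = double(),
                     end_frac = double())
    }
    priors <- new_phase_priors(pt, rules, vocab)
  }
  params <- do.call(pkf_params, as.list(obj$pkf_params %||% list()))
  grid <- if (!is.null(obj$grid)) {
    pkf_grid(unlist(obj$grid$eta_values) %||% seq(0.1, 0.5, by = 0.1),
             unlist(obj$grid$mu_values) %||% seq(0.3, 0.7, by = 0.1),
             unlist(obj$grid$nu_values) %||% seq(0.2, 0.6, by = 0.1),
             fixed = params)
  } else {
    pkf_grid(fixed = params)
  }
  template <- if (!is.null(obj$template)) {
    workflow_template(
      phases = dplyr::bind_rows(lapply(obj$template$phases, tibble::as_tibble)),
      gap_range_s = unlist(obj$template$gap_range_s) %||% c(30, 300),
      vocab = vocab)
  } else {
    workflow_template(vocab = vocab)
  }
  noise <- do.call(noise_model, as.list(obj$noise %||% list()))
  list(vocab = vocab, priors = priors, params = params, grid = grid,
       template = template, noise = noise)
}
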