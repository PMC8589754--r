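#' Derive phase priors from training annotations
#'
#' For every non-background phase the priors hold the minimum phase time
#' `T_i` (the shortest annotated duration of phase i across all training
#' videos, in seconds) and the maximum phase incidence `I_i` (the largest
#' per-video count of segments of phase i). Optionally, order rules are
#' derived for the phases listed in `order_phases`: the rule confines
#' predictions of that phase to the fractional span of video time where the
#' phase was observed in training, widened by `margin_frac` on both sides.
#'
#' Phases never observed in training fall back to `T = floor_s` seconds and
#' `I = 1`, with a warning, so the filtering pipeline stays total.
#'
#' @param ann Training annotation tibble (see [read_annotations()]).
#' @param vocab A [phase_vocabulary()].
#' @param order_phases Phases (names or indices) to derive order rules for.
#'   Default none.
#' @param margin_frac Fractional margin added around the observed span when
#'   building order rules. Default 0.05.
#' @param durations Optional `video_id, duration_s` tibble; inferred from
#'   the annotations when absent.
#' @param floor_s Minimum phase time assigned to unobserved phases.
#' @return A `phase_priors` object: list with a `priors` tibble
#'   (`phase, min_duration_s, max_incidence`) over non-background classes
#'   and an `order_rules` tibble (`phase, start_frac, end_frac`).
#' @export
derive_priors <- function(ann, vocab, order_phases = character(),
                          margin_frac = 0.05, durations = NULL,
                          floor_s = 10) {
  if (nrow(ann) == 0) rlang::abort("empty training annotation set")
  ann <- validate_annotations(ann, vocab)
  durs <- video_durations(ann, durations)
  idx <- phase_index(ann$phase, vocab)
  surg <- surgical_indices(vocab)

  stats <- ann |>
    dplyr::mutate(.idx = idx, .dur = .data$end_s - .data$start_s) |>
    dplyr::filter(.data$.idx != vocab$background_index)
  per_phase <- stats |>
    dplyr::group_by(.data$.idx) |>
    dplyr::summarise(min_duration_s = min(.data$.dur), .groups = "drop")
  per_inc <- stats |>
    dplyr::count(.data$.idx, .data$video_id) |>
    dplyr::group_by(.data$.idx) |>
    dplyr::summarise(max_incidence = max(.data$n), .groups = "drop")

  priors <- tibble::tibble(phase = vocab$names[surg]) |>
    dplyr::mutate(.idx = surg) |>
    dplyr::left_join(per_phase, by = ".idx") |>
    dplyr::left_join(per_inc, by = ".idx")
  unseen <- is.na(priors$min_duration_s)
  if (any(unseen)) {
    rlang::warn(paste0(
      "phase(s) absent from training annotations, using fallback priors (T = ",
      floor_s, " s, I = 1): ",
      paste(priors$phase[unseen], collapse = ", ")
    ))
    priors$min_duration_s[unseen] <- floor_s
    priors$max_incidence[unseen] <- 1L
  }
  priors <- priors[, c("phase", "min_duration_s", "max_incidence")]

  rules <- tibble::tibble(phase = character(), start_frac = double(),
                          end_frac = double())
  if (length(order_phases)) {
    ridx <- phase_index(order_phases, vocab)
    if (!all(ridx %in% idx)) {
      rlang::abort("every phase in order_phases must occur in the training set")
    }
    fr <- ann |>
      dplyr::mutate(.idx = idx) |>
      dplyr::left_join(durs, by = "video_id") |>
      dplyr::filter(.data$.idx %in% ridx) |>
      dplyr::group_by(.data$.idx) |>
      dplyr::summarise(
        start_frac = pmax(0, min(.data$start_s / .data$duration_s) - margin_frac),
        end_frac = pmin(1, max(.data$end_s / .data$duration_s) + margin_frac),
        .groups = "drop"
      )
    rules <- tibble::tibble(phase = vocab$names[fr$.idx],
                            start_frac = fr$start_frac,
                            end_frac = fr$end_frac)
  }
  new_phase_priors(priors, rules, vocab)
}

new_phase_priors <- function(priors, order_rules, vocab) {
  stopifnot(all(priors$min_duration_s > 0), all(priors$max_incidence >= 1))
  structure(
    list(priors = priors, order_rules = order_rules, vocab = vocab),
    class = "phase_priors"
  )
}

#' @export
print.phase_priors <- function(x, ...) {
  cat("<phase_priors> minimum phase time / maximum incidence\n")
  print(x$priors, n = Inf)
  if (nrow(x$order_rules)) {
    cat("order rules (allowed fractional span of video time):\n")
    print(x$order_rules, n = Inf)
  }
  invisible(x)
}

prior_lookup <- function(priors, what) {
  v <- priors$priors[[what]]
  names(v) <- priors$priors$phase
  v
}

#' Write vocabulary and priors to YAML
#'
#' @param priors A `phase_priors` object.
#' @param path Output YAML path.
#' @return `priors`, invisibly.
#' @export
write_priors <- function(priors, path) {
  obj <- list(
    vocabulary = list(
      names = as.list(priors$vocab$names),
      background_index = priors$vocab$background_index
    ),
    priors = purrr::pmap(priors$priors, function(phase, min_duration_s,
                                                 max_incidence) {
      list(phase = phase, min_duration_s = min_duration_s,
           max_incidence = max_incidence)
    }),
    order_rules = purrr::pmap(priors$order_rules, function(phase, start_frac,
                                                           end_frac) {
      list(phase = phase, start_frac = start_frac, end_frac = end_frac)
    })
  )
  yaml::write_yaml(obj, path)
  invisible(priors)
}

#' Read vocabulary and priors from YAML
#'
#' @param path YAML path written by [write_priors()].
#' @return A `phase_priors` object.
#' @export
read_priors <- function(path) {
  obj <- yaml::read_yaml(path)
  vocab <- phase_vocabulary(unlist(obj$vocabulary$names),
                            obj$vocabulary$background_index)
  priors <- dplyr::bind_rows(lapply(obj$priors, tibble::as_tibble))
  rules <- if (length(obj$order_rules)) {
    dplyr::bind_rows(lapply(obj$order_rules, tibble::as_tibble))
  } else {
    tibble::tibble(phase = character(), start_frac = double(),
                   end_frac = double())
  }
  new_phase_priors(priors, rules, vocab)
}
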