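#' Synthetic surgical-workflow template
#'
#' Describes the grammar a simulated procedure follows: phases in procedure
#' order, each included independently with its `occurrence_prob`, repeated
#' up to `max_repeats` times, with per-segment durations uniform in
#' `[dur_min_s, dur_max_s]` and background gaps uniform in `gap_range_s`
#' between segments and at both ends. The default mimics an
#' eight-phase sleeve gastrectomy: mandatory long ligation/transection/
#' oversew phases and short optional phases (exploration, liver retraction,
#' bougie, band removal, hernia repair), giving the strongly imbalanced
#' per-phase durations such procedures show.
#'
#' @param phases Tibble `phase, occurrence_prob, dur_min_s, dur_max_s,
#'   max_repeats` in procedure order; default is the sleeve-gastrectomy
#'   grammar.
#' @param gap_range_s Length-2 numeric, background gap range in seconds.
#' @param vocab A [phase_vocabulary()].
#' @return A `workflow_template` object.
#' @export
workflow_template <- function(phases = NULL,
                              gap_range_s = c(30, 300),
                              vocab = sleeve_gastrectomy_vocab()) {
  if (is.null(phases)) {
    phases <- tibble::tribble(
      ~phase,                              ~occurrence_prob, ~dur_min_s, ~dur_max_s, ~max_repeats,
      "Exploration/inspection",            0.5,              30,         180,        1,
      "Liver retraction",                  0.3,              30,         120,        1,
      "Gastric band removal",              0.2,              120,        600,        1,
      "Hiatal hernia repair",              0.3,              180,        900,        1,
      "Ligation of short gastric vessels", 1.0,              600,        2400,       2,
      "Bougie",                            0.7,              60,         300,        1,
      "Gastric transection",               1.0,              500,        1500,       2,
      "Oversew staple line",               0.9,              400,        1500,       1
    )
  }
  phases <- tibble::as_tibble(phases)
  phase_index(phases$phase, vocab)
  stopifnot(all(phases$occurrence_prob >= 0 & phases$occurrence_prob <= 1),
            all(phases$dur_min_s <= phases$dur_max_s),
            all(phases$max_repeats >= 1),
            length(gap_range_s) == 2, gap_range_s[1] <= gap_range_s[2])
  structure(list(phases = phases, gap_range_s = gap_range_s, vocab = vocab),
            class = "workflow_template")
}

#' Prediction-noise model
#'
#' Parametric model of the errors a per-second phase classifier makes:
#' each second's true label is replaced by a random wrong label with
#' probability `flip_prob`; with probability `burst_prob` such a flip
#' extends into a burst of geometric mean length `burst_mean_s` (emulating
#' multi-second confusions around idle or artifact-laden stretches);
#' labels within `boundary_blur_s` of a phase transition have their
#' probability mass mixed between the two adjacent labels; the emitted
#' label receives mean probability `conf_true` (jittered), the remainder
#' spread evenly over the other classes.
#'
#' @param flip_prob Per-second flip probability, in `[0, 1]`.
#' @param burst_prob Probability a flip starts a burst.
#' @param burst_mean_s Mean burst extension length, seconds.
#' @param boundary_blur_s Blur half-width around transitions, seconds.
#' @param conf_true Mean probability on the emitted label; must exceed
#'   1/n_classes.
#' @param conf_jitter Half-width of the uniform jitter on `conf_true`.
#' @param seed Default seed carried by the model.
#' @return A `noise_model` object.
#' @export
noise_model <- function(flip_prob = 0.1, burst_prob = 0.2, burst_mean_s = 5,
                        boundary_blur_s = 5, conf_true = 0.7,
                        conf_jitter = 0.05, seed = 1) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, burst_prob >= 0, burst_prob <= 1,
            burst_mean_s > 0, boundary_blur_s >= 0,
            conf_true > 0, conf_true <= 1, conf_jitter >= 0)
  structure(list(flip_prob = flip_prob, burst_prob = burst_prob,
                 burst_mean_s = burst_mean_s,
                 boundary_blur_s = boundary_blur_s, conf_true = conf_true,
                 conf_jitter = conf_jitter, seed = seed),
            class = "noise_model")
}

#' Simulate one annotated surgical workflow
#'
#' Lays the template's phases out in order: each phase is included with its
#' occurrence probability, a repeated phase contributes several segments
#' separated by background gaps, and every segment is preceded (and the
#' video terminated) by a background gap. Durations and gaps are drawn
#' uniformly from their ranges and rounded to whole seconds.
#'
#' @param template A [workflow_template()].
#' @param video_id Identifier for the simulated video.
#' @param seed Integer seed; the layout is reproducible from it.
#' @return List with `segments` (annotation tibble), `duration_s` and
#'   `video_id`.
#' @export
generate_workflow <- function(template, video_id = "sim_001", seed = 1) {
  with_seed_(seed, {
    gap <- function() round(stats::runif(1, template$gap_range_s[1],
                                         template$gap_range_s[2]))
    segs <- list()
    cursor <- gap()
    for (k in seq_len(nrow(template$phases))) {
      ph <- template$phases[k, ]
      if (stats::runif(1) > ph$occurrence_prob) next
      reps <- sample_one(seq_len(ph$max_repeats))
      for (r in seq_len(reps)) {
        if (length(segs)) cursor <- cursor + gap()
        dur <- round(stats::runif(1, ph$dur_min_s, ph$dur_max_s))
        segs[[length(segs) + 1]] <- tibble::tibble(
          video_id = video_id, phase = ph$phase,
          start_s = cursor, end_s = cursor + dur)
        cursor <- cursor + dur
      }
    }
    duration <- cursor + gap()
    segments <- if (length(segs)) dplyr::bind_rows(segs) else {
      tibble::tibble(video_id = character(), phase = character(),
                     start_s = double(), end_s = double())
    }
    list(segments = segments, duration_s = duration, video_id = video_id)
  })
}

#' Simulate a noisy per-second prediction trace
#'
#' Builds the probability trace a phase classifier would emit for an
#' annotated video under a [noise_model()]: per second the true label is
#' possibly flipped (isolated or in bursts), the emitted row concentrates
#' `conf_true` (jittered) on the emitted label with the remainder spread
#' evenly, and rows near phase transitions mix mass between the two
#' adjacent labels. Rows sum to 1 exactly.
#'
#' @param workflow A list as returned by [generate_workflow()], or any list
#'   with `segments`, `duration_s`, `video_id`.
#' @param noise A [noise_model()].
#' @param vocab A [phase_vocabulary()].
#' @param seed Seed; defaults to the model's own.
#' @return A trace tibble (see [new_trace()]).
#' @export
generate_trace <- function(workflow, noise, vocab = sleeve_gastrectomy_vocab(),
                           seed = noise$seed) {
  truth <- labels_from_annotation(workflow$segments, workflow$duration_s, vocab)
  n <- length(truth)
  k <- n_classes(vocab)
  with_seed_(seed, {
    emitted <- truth
    t <- 1L
    while (t <= n) {
      if (stats::runif(1) < noise$flip_prob) {
        wrong <- sample_one(setdiff(seq_len(k), truth[t]))
        len <- 1L
        if (noise$burst_prob > 0 && stats::runif(1) < noise$burst_prob) {
          len <- 1L + stats::rgeom(1, 1 / noise$burst_mean_s)
        }
        span <- t:min(n, t + len - 1L)
        emitted[span] <- wrong
        t <- t + len
      } else {
        t <- t + 1L
      }
    }

    conf <- noise$conf_true
    if (noise$conf_jitter > 0) {
      conf <- pmin(1, pmax(1 / k + 1e-6,
        conf + stats::runif(n, -noise$conf_jitter, noise$conf_jitter)))
    } else {
      conf <- rep(conf, n)
    }
    rest <- if (k > 1) (1 - conf) / (k - 1) else 0
    probs <- matrix(rest, n, k)
    probs[cbind(seq_len(n), emitted)] <- conf

    if (noise$boundary_blur_s > 0 && n > 1) {
      trans <- which(truth[-1] != truth[-n])  # transition after second `trans`
      for (s in trans) {
        a <- truth[s]; b <- truth[s + 1]
        lo <- max(1L, s - as.integer(noise$boundary_blur_s) + 1L)
        hi <- min(n, s + as.integer(noise$boundary_blur_s))
        for (tt in lo:hi) {
          lambda <- ((tt - 0.5) - s) / (2 * noise$boundary_blur_s) + 0.5
          lambda <- min(1, max(0, lambda))
          row_a <- rep(rest[tt], k); row_a[a] <- conf[tt]
          row_b <- rep(rest[tt], k); row_b[b] <- conf[tt]
          probs[tt, ] <- (1 - lambda) * row_a + lambda * row_b
        }
      }
    }
    probs <- probs / rowSums(probs)
    new_trace(probs, vocab, workflow$video_id)
  })
}

#' Desk-scale PKF improvement experiment
#'
#' Simulates `n_videos` annotated workflows with noisy traces, runs prior
#' knowledge filtering on each, and compares the raw argmax labels with the
#' filtered labels against ground truth. When `priors` is `NULL` they are
#' derived from the generated cohort's own annotations, playing the role of
#' the training-set derivation.
#'
#' @param template A [workflow_template()].
#' @param noise A [noise_model()].
#' @param params A [pkf_params()].
#' @param priors Optional `phase_priors`; derived from the cohort if NULL.
#' @param n_videos Number of simulated videos.
#' @param seed Master seed; video v uses `seed + v`.
#' @return List with `per_video` (tibble `video_id, raw_accuracy,
#'   pkf_accuracy, raw_jaccard, pkf_jaccard`) and `summary` (one-row tibble
#'   of means plus the fraction of videos PKF improved or tied).
#' @export
improvement_experiment <- function(template, noise, params = pkf_params(),
                                   priors = NULL, n_videos = 20, seed = 1) {
  vocab <- template$vocab
  workflows <- purrr::map(seq_len(n_videos), function(v) {
    generate_workflow(template, sprintf("sim_%03d", v), seed = seed + v)
  })
  if (is.null(priors)) {
    ann <- dplyr::bind_rows(purrr::map(workflows, "segments"))
    durs <- tibble::tibble(
      video_id = purrr::map_chr(workflows, "video_id"),
      duration_s = purrr::map_dbl(workflows, "duration_s"))
    priors <- derive_priors(ann, vocab, durations = durs)
  }
  per_video <- purrr::map_dfr(seq_len(n_videos), function(v) {
    wf <- workflows[[v]]
    trace <- generate_trace(wf, noise, vocab, seed = seed + n_videos + v)
    truth <- labels_from_annotation(wf$segments, wf$duration_s, vocab)
    res <- apply_pkf(trace, priors, params)
    tibble::tibble(
      video_id = wf$video_id,
      raw_accuracy = frame_accuracy(res$raw_labels, truth),
      pkf_accuracy = frame_accuracy(res$labels, truth),
      raw_jaccard = weighted_jaccard(res$raw_labels, truth, vocab),
      pkf_jaccard = weighted_jaccard(res$labels, truth, vocab))
  })
  summary <- tibble::tibble(
    raw_accuracy = mean(per_video$raw_accuracy),
    pkf_accuracy = mean(per_video$pkf_accuracy),
    raw_jaccard = mean(per_video$raw_jaccard),
    pkf_jaccard = mean(per_video$pkf_jaccard),
    improved_frac = mean(per_video$pkf_accuracy >= per_video$raw_accuracy),
    n_videos = n_videos)
  list(per_video = per_video, summary = summary, priors = priors)
}
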