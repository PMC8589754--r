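# Independent brute-force oracles for the sliding-window and
# segment-merging primitives, plus small fixture builders. These stay
# deliberately naive (explicit loops, repeated passes) so they share no
# code path with the implementation they check.

oracle_smooth <- function(labels, phase, w, mu) {
  n <- length(labels)
  h <- floor(w / 2)
  out <- logical(n)
  for (t in seq_len(n)) {
    win <- max(1, t - h):min(n, t + h)
    out[t] <- sum(labels[win] == phase) > mu * length(win)
  }
  out
}

oracle_track_to_segments <- function(track, l) {
  # runs by explicit scan
  segs <- list()
  t <- 1
  n <- length(track)
  while (t <= n) {
    if (track[t]) {
      s <- t
      while (t <= n && track[t]) t <- t + 1
      segs[[length(segs) + 1]] <- c(s - 1, t - 1)  # 0-based half-open
    } else {
      t <- t + 1
    }
  }
  if (!length(segs)) {
    return(tibble::tibble(start_s = integer(), end_s = integer()))
  }
  # merge to fixpoint
  repeat {
    merged <- FALSE
    k <- 1
    while (k < length(segs)) {
      if (segs[[k + 1]][1] - segs[[k]][2] <= l) {
        segs[[k]] <- c(segs[[k]][1], segs[[k + 1]][2])
        segs[[k + 1]] <- NULL
        merged <- TRUE
      } else {
        k <- k + 1
      }
    }
    if (!merged) break
  }
  tibble::tibble(start_s = as.integer(sapply(segs, `[`, 1)),
                 end_s = as.integer(sapply(segs, `[`, 2)))
}

# Trace whose argmax labels equal `labels`, with probability `conf` on the
# label and the rest spread evenly.
trace_from_labels <- function(labels, vocab, conf = 0.8, video_id = "fix") {
  k <- length(vocab$names)
  probs <- matrix((1 - conf) / (k - 1), length(labels), k)
  probs[cbind(seq_along(labels), labels)] <- conf
  new_trace(probs, vocab, video_id)
}

make_priors <- function(vocab, min_duration_s, max_incidence,
                        order_rules = NULL) {
  phases <- setdiff(vocab$names, vocab$names[vocab$background_index])
  pt <- tibble::tibble(
    phase = phases,
    min_duration_s = rep_len(min_duration_s, length(phases)),
    max_incidence = rep_len(max_incidence, length(phases)))
  rules <- order_rules %||% tibble::tibble(
    phase = character(), start_frac = double(), end_frac = double())
  pkfilter:::new_phase_priors(pt, rules, vocab)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Template used where the scenario needs every phase present once with
# durations comfortably above twice the maximum window size.
long_phase_template <- function() {
  workflow_template(
    phases = tibble::tribble(
      ~phase, ~occurrence_prob, ~dur_min_s, ~dur_max_s, ~max_repeats,
      "Exploration/inspection",            1, 150,  400, 1,
      "Liver retraction",                  1, 150,  400, 1,
      "Gastric band removal",              1, 150,  500, 1,
      "Hiatal hernia repair",              1, 200,  700, 1,
      "Ligation of short gastric vessels", 1, 600, 2000, 1,
      "Bougie",                            1, 150,  400, 1,
      "Gastric transection",               1, 500, 1500, 1,
      "Oversew staple line",               1, 400, 1200, 1),
    gap_range_s = c(30, 300))
}

isolated_flip_noise <- function(flip_prob = 0.1) {
  noise_model(flip_prob = flip_prob, burst_prob = 0, boundary_blur_s = 0,
              conf_true = 0.7, conf_jitter = 0)
}

noiseless <- function() {
  noise_model(flip_prob = 0, burst_prob = 0, boundary_blur_s = 0,
              conf_true = 1, conf_jitter = 0)
}
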