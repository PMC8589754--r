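vocab <- sleeve_gastrectomy_vocab()
P1 <- 2L  # Ligation of short gastric vessels
P2 <- 3L  # Gastric transection
P5 <- 6L  # Exploration/inspection
BG <- 1L

test_that("window, threshold and connection formulas match their closed forms", {
  expect_identical(window_size(100), 20L)
  expect_identical(window_size(1000), 60L)
  expect_identical(window_size(10), 10L)
  expect_error(window_size(0))

  expect_equal(pkf_threshold(20, 0.5), 10)
  expect_equal(pkf_threshold(10, 0.5), 5)
  expect_equal(pkf_threshold(60, 0.3), 18)

  expect_equal(connection_threshold(100), 40)
  expect_equal(connection_threshold(1000), 180)
  expect_equal(connection_threshold(10), 4)
})

test_that("order rules relabel a ruled phase outside its allowed span", {
  labels <- rep(BG, 100)
  labels[91:95] <- P5  # seconds 90..94 (0-based), at the end of the video
  rules <- tibble::tibble(phase = "Exploration/inspection",
                          start_frac = 0, end_frac = 0.1)
  out <- apply_order_rules(labels, rules, vocab)
  expect_true(all(out[91:95] == BG))
  expect_equal(out[-(91:95)], labels[-(91:95)])

  early <- rep(BG, 100)
  early[3:7] <- P5  # seconds 2..6: inside the allowed beginning
  expect_equal(apply_order_rules(early, rules, vocab), early)

  expect_equal(apply_order_rules(labels, NULL, vocab), labels)
})

test_that("sliding-window smoothing absorbs isolated flips and matches the oracle", {
  labels <- rep(P1, 15); labels[8] <- BG
  track <- smooth_phase_track(labels, P1, 5, 0.5)
  expect_equal(track, oracle_smooth(labels, P1, 5, 0.5))
  expect_true(all(track))

  expect_false(any(smooth_phase_track(rep(BG, 20), P1, 5, 0.5)))

  alt <- rep(c(P1, BG), 10)
  expect_equal(smooth_phase_track(alt, P1, 5, 0.5),
               oracle_smooth(alt, P1, 5, 0.5))
})

test_that("track runs merge across gaps up to the threshold, transitively", {
  tr <- function(pairs, n) {
    x <- logical(n)
    for (p in pairs) x[(p[1] + 1):p[2]] <- TRUE
    x
  }
  t1 <- tr(list(c(0, 10), c(14, 20)), 20)
  expect_equal(track_to_segments(t1, 5),
               tibble::tibble(start_s = 0L, end_s = 20L))

  t2 <- tr(list(c(0, 10), c(16, 20)), 20)
  expect_equal(track_to_segments(t2, 5),
               tibble::tibble(start_s = c(0L, 16L), end_s = c(10L, 20L)))

  t3 <- tr(list(c(0, 5), c(8, 12), c(15, 20)), 20)
  expect_equal(track_to_segments(t3, 3),
               tibble::tibble(start_s = 0L, end_s = 20L))
  expect_equal(track_to_segments(t3, 3), oracle_track_to_segments(t3, 3))

  expect_equal(nrow(track_to_segments(logical(10), 5)), 0)
})

test_that("mean confidence is the interval average of the phase probability", {
  own <- c(0.6, 0.7, 0.8)
  probs <- matrix((1 - own) / 8, 3, 9)
  probs[, P1] <- own
  tr <- new_trace(probs, vocab)
  expect_equal(mean_confidence(tr, P1, 0, 3, vocab), 0.7)
  expect_equal(mean_confidence(tr, P1, 1, 2, vocab), 0.7)
  expect_error(mean_confidence(tr, P1, 2, 2, vocab))

  onehot <- matrix(0, 4, 9); onehot[, P2] <- 1
  expect_equal(mean_confidence(new_trace(onehot, vocab), P2, 0, 4, vocab), 1)
})

test_that("overlaps resolve to the more confident phase and pieces re-merge", {
  k <- 9; n <- 14
  probs <- matrix(0.01, n, k)
  probs[1:10, P1] <- 0.7   # P1 strong over [0,10)
  probs[7:14, P2] <- 0.5   # P2 weaker over [6,14)
  tr <- new_trace(probs / rowSums(probs), vocab, "ov")
  segs <- resolve_overlaps(
    list("Ligation of short gastric vessels" = tibble::tibble(start_s = 0L, end_s = 10L),
         "Gastric transection" = tibble::tibble(start_s = 6L, end_s = 14L)),
    tr, vocab)
  expect_equal(segs$phase, c("Ligation of short gastric vessels",
                             "Gastric transection"))
  expect_equal(segs$start_s, c(0L, 10L))
  expect_equal(segs$end_s, c(10L, 14L))
  expect_true(all(segs$mean_conf >= 0 & segs$mean_conf <= 1))

  # disjoint inputs concatenate, sorted
  segs2 <- resolve_overlaps(
    list("Gastric transection" = tibble::tibble(start_s = 8L, end_s = 12L),
         "Ligation of short gastric vessels" = tibble::tibble(start_s = 0L, end_s = 4L)),
    tr, vocab)
  expect_equal(segs2$start_s, c(0L, 8L))

  # identical claim: higher confidence wins outright
  probs3 <- matrix(0.01, 10, k)
  probs3[, P1] <- 0.4; probs3[, P2] <- 0.9
  tr3 <- new_trace(probs3 / rowSums(probs3), vocab)
  segs3 <- resolve_overlaps(
    list("Ligation of short gastric vessels" = tibble::tibble(start_s = 0L, end_s = 10L),
         "Gastric transection" = tibble::tibble(start_s = 0L, end_s = 10L)),
    tr3, vocab)
  expect_equal(segs3$phase, "Gastric transection")
  expect_equal(nrow(segs3), 1)
})

test_that("short segments are dropped strictly below the minimum phase time", {
  pri <- make_priors(vocab, 30, 5)
  seg <- tibble::tibble(video_id = "v",
                        phase = "Ligation of short gastric vessels",
                        start_s = c(0L, 40L), end_s = c(25L, 70L),
                        mean_conf = c(0.9, 0.9))
  out <- drop_short_segments(seg, pri)
  expect_equal(out$start_s, 40L)  # [0,25) dropped, [40,70) kept (length 30)

  expect_equal(nrow(drop_short_segments(seg[0, ], pri)), 0)
})

test_that("incidence capping keeps the most confident segments, earlier on ties", {
  pri <- make_priors(vocab, 10, 1)
  seg <- tibble::tibble(video_id = "v",
                        phase = "Gastric band removal",
                        start_s = c(0L, 100L), end_s = c(50L, 150L),
                        mean_conf = c(0.9, 0.6))
  out <- cap_incidence(seg, pri)
  expect_equal(out$start_s, 0L)

  tie <- seg; tie$mean_conf <- c(0.7, 0.7)
  expect_equal(cap_incidence(tie, pri)$start_s, 0L)

  pri2 <- make_priors(vocab, 10, 2)
  expect_equal(cap_incidence(seg, pri2), dplyr::arrange(seg, start_s))
})
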