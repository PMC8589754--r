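vocab <- sleeve_gastrectomy_vocab()

test_that("focal loss matches its closed form and limits", {
  expect_equal(focal_loss(1), 0)
  expect_equal(focal_loss(0.5), 4 * 0.25 * log(2))
  expect_error(focal_loss(-0.1))
  expect_error(focal_loss(1.1))

  p <- seq(0.01, 0.99, length.out = 100)
  # gamma = 0 reduces to alpha * cross-entropy
  expect_equal(focal_loss(p, alpha = 4, gamma = 0), 4 * (-log(p)))
  # FL / CE equals the down-weighting factor alpha * (1 - p)^gamma
  expect_equal(focal_loss(p, alpha = 4, gamma = 2) / (-log(p)),
               4 * (1 - p)^2)
  # non-negative and strictly decreasing in p
  fl <- focal_loss(p)
  expect_true(all(fl >= 0))
  expect_true(all(diff(fl) < 0))
  expect_equal(focal_loss(c(0.5, 0.5), reduce = "mean"), focal_loss(0.5))
})

make_three_segment_video <- function() {
  # one video, 300 s: P1 [0,100), gap [100,200), P2 [200,300) -> 3 segments
  tibble::tibble(
    video_id = "v1",
    phase = c("Ligation of short gastric vessels", "Gastric transection"),
    start_s = c(0, 200), end_s = c(100, 300))
}

test_that("ASBS yields clips_per_segment clips per segment per epoch", {
  ann <- make_three_segment_video()
  durs <- tibble::tibble(video_id = "v1", duration_s = 300)
  plan <- asbs_plan(ann, vocab, epochs = 2, durations = durs, seed = 3)
  expect_equal(nrow(plan), 2 * 5 * 3)
  counts <- dplyr::count(plan, epoch, segment_id)
  expect_true(all(counts$n == 5))
  # background gap is sampled like any annotated segment
  expect_true("Not a phase" %in% plan$phase)
})

test_that("ASBS clips stay inside their segments with in-bounds frames", {
  ann <- make_three_segment_video()
  durs <- tibble::tibble(video_id = "v1", duration_s = 300)
  plan <- asbs_plan(ann, vocab, durations = durs, seed = 5)
  seg1 <- plan[plan$segment_id == 1, ]  # the 100 s P1 segment
  expect_true(all(seg1$clip_start_s >= 0 & seg1$clip_start_s <= 80))
  frames <- unlist(plan$frame_indices)
  expect_true(all(frames >= 0 & frames < 300 * 30))
  expect_true(all(vapply(plan$frame_indices, length, integer(1)) == 64))
  # full-length clips hold strictly increasing indices at the drawn stride
  full <- plan[!plan$padded, ]
  for (k in seq_len(nrow(full))) {
    d <- diff(full$frame_indices[[k]])
    expect_true(all(d == full$stride_a[k]))
  }
})

test_that("segments shorter than the clip keep the stride capped and pad", {
  ann <- tibble::tibble(video_id = "v1", phase = "Bougie",
                        start_s = 10, end_s = 15)  # 5 s = 150 frames
  durs <- tibble::tibble(video_id = "v1", duration_s = 30)
  plan <- asbs_plan(ann, vocab, durations = durs, seed = 9)
  short <- plan[plan$phase == "Bougie", ]
  expect_true(all(short$padded))
  expect_true(all(short$stride_a == 4))
  for (k in seq_len(nrow(short))) {
    idx <- short$frame_indices[[k]]
    expect_length(idx, 64)
    expect_true(all(idx >= 10 * 30 & idx < 15 * 30))
  }
})

test_that("ASBS plans are seed-deterministic with stable structure", {
  ann <- make_three_segment_video()
  durs <- tibble::tibble(video_id = "v1", duration_s = 300)
  a <- asbs_plan(ann, vocab, durations = durs, seed = 42)
  b <- asbs_plan(ann, vocab, durations = durs, seed = 42)
  expect_identical(a, b)
  c <- asbs_plan(ann, vocab, durations = durs, seed = 43)
  expect_false(identical(a$clip_start_s, c$clip_start_s))
  expect_equal(dplyr::count(a, segment_id)$n, dplyr::count(c, segment_id)$n)
})

test_that("balanced plans split the total evenly with remainder to earliest", {
  ann <- make_three_segment_video()  # classes present: bg, P1, P2
  durs <- tibble::tibble(video_id = "v1", duration_s = 300)
  plan <- suppressWarnings(
    balanced_plan(ann, vocab, total_per_epoch = 10,
                  durations = durs, seed = 2))
  counts <- plan_summary(plan)
  expect_equal(sum(counts$n_clips), 10)
  expect_equal(counts$n_clips[match("Not a phase", counts$phase)], 4)
  expect_true(all(sort(counts$n_clips) == c(3, 3, 4)))

  # two classes only: 5 each
  ann2 <- tibble::tibble(video_id = "v1",
                         phase = "Ligation of short gastric vessels",
                         start_s = 0, end_s = 100)
  plan2 <- suppressWarnings(
    balanced_plan(ann2, vocab, total_per_epoch = 10,
                  durations = tibble::tibble(video_id = "v1",
                                             duration_s = 200), seed = 2))
  expect_equal(sort(plan_summary(plan2)$n_clips), c(5, 5))

  # upsampling with replacement: 50 clips from one 30 s segment
  ann3 <- tibble::tibble(video_id = "v1", phase = "Bougie",
                         start_s = 0, end_s = 30)
  plan3 <- suppressWarnings(
    balanced_plan(ann3, vocab, total_per_epoch = 52,
                  durations = tibble::tibble(video_id = "v1",
                                             duration_s = 60), seed = 2))
  bougie <- plan3[plan3$phase == "Bougie", ]
  expect_equal(nrow(bougie), 26)
  expect_true(all(bougie$clip_start_s >= 0 & bougie$clip_start_s <= 30))

  expect_error(suppressWarnings(
    balanced_plan(ann, vocab, total_per_epoch = 2,
                  durations = durs, seed = 1)),
    "at least")
})

test_that("clip plans export as JSON Lines", {
  ann <- make_three_segment_video()
  durs <- tibble::tibble(video_id = "v1", duration_s = 300)
  plan <- asbs_plan(ann, vocab, durations = durs, seed = 1)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_clip_plan(plan, path)
  lines <- readLines(path)
  expect_length(lines, nrow(plan))
  rec <- jsonlite::fromJSON(lines[1])
  expect_length(rec$frame_indices, 64)
  expect_equal(rec$video_id, "v1")
})
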