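vocab <- sleeve_gastrectomy_vocab()

test_that("annotation CSV round-trips and validates", {
  ann <- tibble::tibble(
    video_id = c("v1", "v1"),
    phase = c("Ligation of short gastric vessels", "Gastric transection"),
    start_s = c(0, 120), end_s = c(100, 200))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  back <- read_annotations(path, vocab)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  expect_gte(max(video_durations(back)$duration_s), 200)

  # header-only file -> zero rows
  writeLines("video_id,phase,start_s,end_s", path)
  expect_equal(nrow(read_annotations(path, vocab)), 0)
})

test_that("unknown phases and overlapping segments are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("video_id,phase,start_s,end_s",
               "v1,Imaginary phase,0,10"), path)
  expect_error(read_annotations(path, vocab), "Imaginary phase",
               class = "pkfilter_parse_error")

  ann <- tibble::tibble(
    video_id = "v1",
    phase = rep("Ligation of short gastric vessels", 2),
    start_s = c(0, 50), end_s = c(100, 150))
  err <- expect_error(validate_annotations(ann, vocab),
                      class = "pkfilter_validation_error")
  expect_match(conditionMessage(err), "v1")
  expect_match(conditionMessage(err), "overlap")
})

test_that("trace CSV round-trips to serialized precision and validates rows", {
  set.seed(42)
  probs <- matrix(runif(5 * 9), 5, 9)
  probs <- probs / rowSums(probs)
  tr <- new_trace(probs, vocab, "v1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path, vocab, video_id = "v1")
  expect_equal(pkfilter:::trace_matrix(back, vocab),
               pkfilter:::trace_matrix(tr, vocab), tolerance = 1e-5)

  onehot <- diag(9)[c(2, 3, 1), ]
  tr1 <- new_trace(onehot, vocab)
  expect_equal(argmax_labels(tr1, vocab), c(2L, 3L, 1L))

  # argmax tie resolves to the lowest class index
  tie <- matrix(0, 1, 9); tie[1, 3] <- 0.5; tie[1, 5] <- 0.5
  expect_equal(argmax_labels(new_trace(tie, vocab), vocab), 3L)

  bad <- matrix(0.1, 1, 9)  # sums to 0.9
  expect_error(new_trace(bad, vocab), class = "pkfilter_validation_error")

  near <- matrix(1 / 9 + 1e-5, 1, 9)  # deviation < 1e-3: renormalized
  expect_equal(rowSums(pkfilter:::trace_matrix(new_trace(near, vocab), vocab)), 1)
})

test_that("labels_from_annotation rasterizes at 1 Hz with background fill", {
  p1 <- "Ligation of short gastric vessels"
  p2 <- "Gastric transection"
  ann <- tibble::tibble(video_id = "v", phase = p1, start_s = 0, end_s = 3)
  expect_equal(labels_from_annotation(ann, 5, vocab), c(2L, 2L, 2L, 1L, 1L))

  none <- ann[0, ]
  expect_equal(labels_from_annotation(none, 4, vocab), rep(1L, 4))

  two <- tibble::tibble(video_id = "v", phase = c(p1, p2),
                        start_s = c(0, 2), end_s = c(2, 4))
  expect_equal(labels_from_annotation(two, 4, vocab), c(2L, 2L, 3L, 3L))
  expect_true(all(labels_from_annotation(two, 4, vocab) %in%
                    seq_along(vocab$names)))
})

test_that("derive_priors computes min duration, max incidence and order rules", {
  p1 <- "Ligation of short gastric vessels"
  ann <- tibble::tibble(
    video_id = c("a", "a", "b", "b", "b"),
    phase = p1,
    start_s = c(0, 100, 0, 100, 200),
    end_s = c(30, 145, 60, 150, 250))
  pri <- suppressWarnings(derive_priors(ann, vocab))
  row <- pri$priors[pri$priors$phase == p1, ]
  expect_equal(row$min_duration_s, 30)
  expect_equal(row$max_incidence, 3)

  # unobserved phases fall back with a warning
  expect_warning(derive_priors(ann, vocab), "fallback")
  bougie <- pri$priors[pri$priors$phase == "Bougie", ]
  expect_equal(bougie$min_duration_s, 10)
  expect_equal(bougie$max_incidence, 1)

  # order rule from a single observed span with margin
  expl <- tibble::tibble(video_id = "c", phase = "Exploration/inspection",
                         start_s = 0, end_s = 40)
  durs <- tibble::tibble(video_id = "c", duration_s = 1000)
  pri2 <- suppressWarnings(derive_priors(
    dplyr::bind_rows(ann, expl), vocab,
    order_phases = "Exploration/inspection", margin_frac = 0.05,
    durations = dplyr::bind_rows(durs, video_durations(ann))))
  rule <- pri2$order_rules
  expect_equal(rule$start_frac, 0)
  expect_equal(rule$end_frac, 0.09)

  expect_error(derive_priors(ann[0, ], vocab), "empty")
})

test_that("derive_priors is invariant to the order of input videos", {
  tmpl <- workflow_template()
  wfs <- lapply(1:4, function(v)
    generate_workflow(tmpl, paste0("v", v), seed = 100 + v))
  ann <- dplyr::bind_rows(lapply(wfs, `[[`, "segments"))
  durs <- tibble::tibble(video_id = sapply(wfs, `[[`, "video_id"),
                         duration_s = sapply(wfs, `[[`, "duration_s"))
  a <- suppressWarnings(derive_priors(ann, vocab, durations = durs))
  shuffled <- ann[rev(seq_len(nrow(ann))), ]
  b <- suppressWarnings(derive_priors(shuffled, vocab, durations = durs))
  expect_equal(a$priors, b$priors)
})

test_that("priors round-trip through YAML", {
  pri <- make_priors(vocab, 30, 2,
                     tibble::tibble(phase = "Exploration/inspection",
                                    start_frac = 0, end_frac = 0.1))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_priors(pri, path)
  back <- read_priors(path)
  expect_equal(back$priors, pri$priors)
  expect_equal(back$order_rules, pri$order_rules)
  expect_equal(back$vocab$names, vocab$names)
})
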