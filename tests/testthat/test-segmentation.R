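test_that("segments span 100 samples before and 150 from the R-peak", {
  rec <- ecg_record(as.numeric(1:1000), 360,
                    annotations = data.frame(sample = 501L, symbol = "N"))
  bs <- segment_beats(rec)
  expect_equal(dim(bs$x), c(1, 250))
  expect_equal(bs$r_offset, 100)
  # sample values equal their index, so the window is read off directly
  expect_equal(bs$x[1, ], as.numeric(401:650))
  expect_equal(bs$x[1, bs$r_offset + 1], 501)
})

test_that("edge beats are skipped and counted, not truncated", {
  rec <- ecg_record(rnorm(1000), 360,
                    annotations = data.frame(sample = c(50L, 500L, 990L),
                                             symbol = c("N", "N", "N")))
  bs <- segment_beats(rec)
  expect_equal(nrow(bs$x), 1)
  expect_equal(bs$skipped, 2)
  expect_equal(nrow(bs$x) + bs$skipped, 3)
  empty <- segment_beats(rec, r_indices = integer(0), labels = character(0))
  expect_equal(nrow(empty$x), 0)
  expect_error(segment_beats(rec, pre = 0, post = 0), "positive")
})

test_that("every emitted beat has length 250 with the R at offset 100", {
  bs <- fx_beat_set()
  expect_equal(ncol(bs$x), 250)
  expect_equal(bs$r_offset, 100)
  expect_equal(length(bs$labels), nrow(bs$x))
})

test_that("label schemes map and drop symbols per convention", {
  m4 <- label_scheme("mitbih4")
  expect_equal(as.character(map_labels(c("N", "L", "R", "V"), m4)),
               c("N", "L", "R", "V"))
  expect_true(is.na(map_labels("A", m4)[1]))
  a4 <- label_scheme("aami4")
  expect_equal(a4$classes, c("N", "S", "V", "F"))
  expect_equal(as.character(map_labels("L", a4)), "N")
  expect_equal(as.character(map_labels(c("A", "a", "J", "S"), a4)),
               rep("S", 4))
  expect_equal(as.character(map_labels(c("V", "E"), a4)), c("V", "V"))
  expect_equal(as.character(map_labels("F", a4)), "F")
  q <- map_labels(c("Q", "/", "f"), a4)
  expect_true(all(is.na(q)))
  expect_equal(attr(q, "dropped"), 3L)
  # total on the full symbol set in play, never emitting Q
  full <- map_labels(c("N", "L", "R", "e", "j", "A", "a", "J", "S", "V",
                       "E", "F"), a4)
  expect_false(anyNA(full))
  expect_false("Q" %in% full)
})

test_that("stratified holdout preserves class proportions", {
  bs <- fx_beat_set()
  sp <- split_beats(bs, split_spec(test_fraction = 0.2, seed = 3))
  expect_equal(length(sp$train) + length(sp$test), length(bs$labels))
  for (cl in unique(bs$labels)) {
    n_cl <- sum(bs$labels == cl)
    n_te <- sum(bs$labels[sp$test] == cl)
    expect_lte(abs(n_te - 0.2 * n_cl), 1)
  }
  sp2 <- split_beats(bs, split_spec(test_fraction = 0.2, seed = 3))
  expect_identical(sp, sp2)
})

test_that("record holdout keeps whole records on one side", {
  bs <- synthetic_beat_set(40, classes = c("N", "V"), seed = 9,
                           records_per_class = 2)
  sp <- split_beats(bs, split_spec("record_holdout", test_fraction = 0.5,
                                   seed = 1))
  expect_equal(length(intersect(unique(bs$record_id[sp$train]),
                                unique(bs$record_id[sp$test]))), 0)
})

test_that("cross-validation folds are stratified and near-equal", {
  bs <- fx_beat_set()
  folds <- split_beats(bs, split_spec("cross_validation", folds = 5,
                                      seed = 2))
  expect_equal(length(folds), length(bs$labels))
  expect_true(all(table(folds) >= floor(length(folds) / 5) - 4))
  for (cl in unique(bs$labels))
    expect_true(all(table(folds[bs$labels == cl]) >= 1))
})

test_that("rebalancing implements the three strategies exactly", {
  labels <- c(rep("A", 90), rep("B", 10))
  ov <- rebalance(labels, "oversample", seed = 1)
  expect_equal(as.vector(table(labels[ov$idx])), c(90, 90))
  un <- rebalance(labels, "undersample", seed = 1)
  expect_equal(as.vector(table(labels[un$idx])), c(10, 10))
  w <- rebalance(labels, "weights")
  expect_identical(w$idx, seq_along(labels))
  expect_equal(unname(w$weights["B"] / w$weights["A"]), 9)
  expect_equal(unname(w$weights["A"]), 100 / (2 * 90))
})

test_that("detected beats inherit the nearest annotation within tolerance", {
  ann <- data.frame(sample = c(100L, 500L), symbol = c("N", "V"))
  got <- assign_labels(c(103L, 495L, 300L), ann, fs = 360, tol = 0.05)
  expect_equal(got[1:2], c("N", "V"))
  expect_true(is.na(got[3]))
})
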