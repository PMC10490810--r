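# build truth/prediction vectors realizing given per-class (n, correct)
counts_to_labels <- function(counts, classes) {
  truth <- character(0); pred <- character(0)
  for (cl in names(counts)) {
    n <- counts[[cl]]["n"]; k <- counts[[cl]]["correct"]
    wrong <- setdiff(classes, cl)[1]
    truth <- c(truth, rep(cl, n))
    pred <- c(pred, rep(cl, k), rep(wrong, n - k))
  }
  list(truth = truth, pred = pred)
}

test_that("per-class accuracy reproduces the published count arithmetic", {
  classes <- c("N", "S", "V", "F")
  lp <- counts_to_labels(list(
    N = c(n = 90081, correct = 89951),
    S = c(n = 2781, correct = 2219),
    V = c(n = 7001, correct = 6866),
    F = c(n = 801, correct = 795)), classes)
  ev <- evaluate_predictions(lp$truth, lp$pred, classes)
  acc <- setNames(ev$per_class$accuracy, ev$per_class$class)
  expect_equal(round(acc[["N"]], 2), 99.86)
  expect_equal(round(acc[["S"]], 2), 79.79)
  expect_equal(round(acc[["F"]], 2), 99.25)
  # the published V row (97.99) disagrees with its own counts: the
  # computed ratio is reported instead
  expect_equal(round(acc[["V"]], 2), 98.07)
})

test_that("perfect predictions give a diagonal confusion matrix", {
  y <- c("a", "b", "c", "a", "b")
  ev <- evaluate_predictions(y, y, c("a", "b", "c"))
  expect_equal(ev$overall, 100)
  expect_true(all(ev$confusion[upper.tri(ev$confusion)] == 0))
  expect_true(all(ev$confusion[lower.tri(ev$confusion)] == 0))
})

test_that("classes absent from truth report NA accuracy, not zero", {
  ev <- evaluate_predictions(c("a", "a"), c("a", "b"), c("a", "b", "c"))
  expect_true(is.na(ev$per_class$accuracy[ev$per_class$class == "c"]))
  expect_error(evaluate_predictions(c("a", "z"), c("a", "a"), c("a", "b")),
               "outside")
  expect_error(evaluate_predictions("a", character(0)), "equal length")
})

test_that("overall accuracy is the count-weighted mean of per-class", {
  set.seed(6)
  for (rep in 1:10) {
    classes <- c("w", "x", "y", "z")
    truth <- sample(classes, 300, TRUE)
    pred <- ifelse(runif(300) < 0.7, truth, sample(classes, 300, TRUE))
    ev <- evaluate_predictions(truth, pred, classes)
    pc <- ev$per_class[ev$per_class$n > 0, ]
    expect_equal(ev$overall, sum(pc$accuracy * pc$n) / sum(pc$n))
    expect_equal(rowSums(ev$confusion), setNames(
      vapply(classes, function(cl) sum(truth == cl), numeric(1)), classes))
  }
})

test_that("evaluation reports round-trip through JSON", {
  set.seed(7)
  truth <- sample(c("N", "V"), 50, TRUE)
  pred <- sample(c("N", "V"), 50, TRUE)
  ev <- evaluate_predictions(truth, pred, c("N", "V", "F"))
  path <- file.path(withr::local_tempdir(), "eval.json")
  write_eval_report(ev, path)
  back <- read_eval_report(path)
  expect_equal(back$confusion, ev$confusion)
  expect_equal(back$overall, ev$overall)
  expect_equal(back$per_class, ev$per_class)
})

test_that("the pipeline runs end to end on a small configuration", {
  cfg <- pipeline_config(seed = 5)
  cfg$simulate <- list(presets = c("normal", "pvc"), duration = 60,
                       noise_sd = 0.05)
  cfg$models <- c("lr", "gbtree")
  cfg$fusion <- list(base = c("lr", "gbtree"), folds = 5)
  out <- run_pipeline(cfg)
  expect_gte(out$detector$sensitivity, 0.99)
  expect_gte(out$detector$ppv, 0.99)
  expect_named(out$reports,
               c("lr", "gbtree", "hard_vote", "soft_vote", "stacking"))
  for (rep in out$reports) expect_gte(rep$overall, 90)
  # omitting fusion yields per-model reports only
  cfg$fusion <- NULL
  cfg$models <- "gbtree"
  out2 <- run_pipeline(cfg)
  expect_named(out2$reports, "gbtree")
})
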