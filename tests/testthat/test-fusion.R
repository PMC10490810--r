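pm <- function(...) {
  m <- rbind(...)
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  m
}

test_that("hard voting takes the majority with ordered tie-breaks", {
  classes <- c("c1", "c2")
  p_a <- pm(c(0.9, 0.1))
  p_b <- pm(c(0.2, 0.8))
  ps <- prediction_set(list(m1 = p_a, m2 = p_a, m3 = p_b))
  expect_equal(as.character(hard_vote(ps)), "c1")
  # unanimity
  ps <- prediction_set(list(m1 = p_b, m2 = p_b))
  expect_equal(as.character(hard_vote(ps)), "c2")
  # 1-1 tie: the first-listed model's vote wins
  ps <- prediction_set(list(m1 = p_a, m2 = p_b))
  expect_equal(as.character(hard_vote(ps)), "c1")
  ps <- prediction_set(list(m1 = p_b, m2 = p_a))
  expect_equal(as.character(hard_vote(ps)), "c2")
})

test_that("soft voting averages probabilities and argmaxes the mean", {
  p1 <- pm(c(0.6, 0.4))
  p2 <- pm(c(0.2, 0.8))
  sv <- soft_vote(prediction_set(list(a = p1, b = p2)))
  expect_equal(unname(sv$probs[1, ]), c(0.4, 0.6))
  expect_equal(as.character(sv$labels), "c2")
  # single model: identity
  one <- soft_vote(prediction_set(list(a = p1)))
  expect_equal(one$probs, p1)
  # averaged rows still sum to one
  set.seed(1)
  r <- matrix(runif(40), 10); r <- r / rowSums(r); colnames(r) <- paste0("c", 1:4)
  s <- matrix(runif(40), 10); s <- s / rowSums(s); colnames(s) <- paste0("c", 1:4)
  sv <- soft_vote(prediction_set(list(a = r, b = s)))
  expect_equal(rowSums(sv$probs), rep(1, 10))
})

test_that("soft and hard voting coincide on one-hot predictions", {
  # an odd model count over two classes always has a strict majority,
  # so the two voting rules must agree exactly
  set.seed(2)
  onehot <- function(idx) {
    m <- matrix(0, length(idx), 2, dimnames = list(NULL, c("c1", "c2")))
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  for (rep in 1:5) {
    ps <- prediction_set(list(m1 = onehot(sample(2, 20, TRUE)),
                              m2 = onehot(sample(2, 20, TRUE)),
                              m3 = onehot(sample(2, 20, TRUE))))
    expect_equal(hard_vote(ps), soft_vote(ps)$labels)
  }
})

test_that("prediction sets validate their shape", {
  p <- pm(c(0.5, 0.5))
  expect_error(prediction_set(list()), "at least one")
  expect_error(prediction_set(list(p, p)), "named")
  expect_error(prediction_set(list(a = p, b = matrix(1, 2, 2))), "shape")
})

test_that("stacking meta-features have width n_models x n_classes", {
  bs <- fx_beat_set()
  f <- fx_features()
  stk <- fit_stacking(list(features = f), bs$labels,
                      base = list(gb = list(model = "gbtree",
                                            input = "features"),
                                  lr = list(model = "lr",
                                            input = "features")),
                      folds = 5, seed = 3)
  expect_equal(stk$meta_width, 2 * 4)
  pred <- predict(stk, list(features = f))
  expect_equal(length(pred), nrow(f))
})

test_that("stacking on perfectly informative base features is perfect", {
  # a degenerate base model: its probabilities are the true one-hot labels
  set.seed(4)
  y <- sample(c("N", "L", "R", "V"), 200, TRUE)
  onehot <- t(vapply(y, function(cl) as.numeric(c("N", "L", "R", "V") == cl),
                     numeric(4)))
  colnames(onehot) <- c("N", "L", "R", "V")
  stk <- fit_stacking(list(features = onehot), y,
                      base = list(lr = list(model = "lr",
                                            input = "features")),
                      folds = 5, seed = 1)
  expect_equal(mean(predict(stk, list(features = onehot)) == y), 1)
})

test_that("stacking is deterministic under a fixed seed", {
  bs <- fx_beat_set()
  f <- fx_features()
  run <- function() {
    stk <- fit_stacking(list(features = f), bs$labels,
                        base = list(gb = list(model = "gbtree",
                                              input = "features")),
                        folds = 5, seed = 11)
    as.character(predict(stk, list(features = f)))
  }
  expect_identical(run(), run())
})

test_that("stacking refuses folds that would lose a class", {
  y <- c(rep("a", 30), rep("b", 3))
  x <- matrix(rnorm(33 * 2), 33)
  expect_error(fit_stacking(list(features = x), y,
                            base = list(lr = list(model = "lr",
                                                  input = "features")),
                            folds = 5, seed = 1),
               "every class")
})

test_that("single-base stacking stays within 2 points of that model", {
  for (seed in 1:3) {
    bs <- synthetic_beat_set(60, seed = seed, noise_sd = 0.15)
    f <- beat_features(bs)
    sp <- split_beats(bs, split_spec(test_fraction = 0.25, seed = seed))
    base <- train_beat_classifier(f[sp$train, ], bs$labels[sp$train],
                                  "gbtree", seed = seed)
    acc_base <- mean(predict(base, f[sp$test, ], type = "class") ==
                       bs$labels[sp$test])
    stk <- fit_stacking(list(features = f[sp$train, ]),
                        bs$labels[sp$train],
                        base = list(gb = list(model = "gbtree",
                                              input = "features")),
                        folds = 5, seed = seed)
    acc_stk <- mean(predict(stk, list(features = f[sp$test, ])) ==
                      bs$labels[sp$test])
    expect_gte(acc_stk, acc_base - 0.02)
  }
})
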