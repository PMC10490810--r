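test_that("lstm_cell reproduces the zero-weight closed forms", {
  h <- 3; d <- 2
  zeros <- list(W_f = matrix(0, h, h + d), W_i = matrix(0, h, h + d),
                W_c = matrix(0, h, h + d), W_o = matrix(0, h, h + d),
                b_f = rep(0, h), b_i = rep(0, h), b_c = rep(0, h),
                b_o = rep(0, h))
  c_prev <- c(0.4, -1, 2)
  out <- lstm_cell(rnorm(d), rnorm(h), c_prev, zeros)
  expect_equal(out$f, rep(0.5, h))
  expect_equal(out$i, rep(0.5, h))
  expect_equal(out$chat, rep(0, h))
  expect_equal(out$c, 0.5 * c_prev)

  # saturated forget gate with silent input gate: perfect retention
  sat <- zeros
  sat$b_f <- rep(30, h)
  sat$b_i <- rep(-30, h)
  out <- lstm_cell(rnorm(d), rnorm(h), c_prev, sat)
  expect_equal(out$f, rep(1, h), tolerance = 1e-10)
  expect_equal(out$c, c_prev, tolerance = 1e-10)

  # scalar case: sigma(0) = 0.5
  sc <- list(W_f = matrix(c(1, 1), 1), W_i = matrix(0, 1, 2),
             W_c = matrix(0, 1, 2), W_o = matrix(0, 1, 2),
             b_f = 0, b_i = 0, b_c = 0, b_o = 0)
  expect_equal(lstm_cell(0, 0, 0, sc)$f, 0.5)
})

test_that("lstm_cell matches an independent gate-equation oracle", {
  sigma <- function(z) 1 / (1 + exp(-z))
  oracle <- function(x, h_prev, c_prev, p) {
    z <- c(h_prev, x)
    f <- sigma(as.vector(p$W_f %*% z) + p$b_f)
    i <- sigma(as.vector(p$W_i %*% z) + p$b_i)
    chat <- tanh(as.vector(p$W_c %*% z) + p$b_c)
    ct <- f * c_prev + i * chat
    o <- sigma(as.vector(p$W_o %*% z) + p$b_o)
    list(h = o * tanh(ct), c = ct, f = f, i = i, chat = chat, o = o)
  }
  set.seed(7)
  for (rep in seq_len(100)) {
    h <- sample(1:6, 1); d <- sample(1:5, 1)
    p <- list(W_f = matrix(rnorm(h * (h + d)), h), b_f = rnorm(h),
              W_i = matrix(rnorm(h * (h + d)), h), b_i = rnorm(h),
              W_c = matrix(rnorm(h * (h + d)), h), b_c = rnorm(h),
              W_o = matrix(rnorm(h * (h + d)), h), b_o = rnorm(h))
    x <- rnorm(d); hp <- rnorm(h); cp <- rnorm(h)
    got <- lstm_cell(x, hp, cp, p)
    want <- oracle(x, hp, cp, p)
    for (nm in c("h", "c", "f", "i", "chat", "o"))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10)
    expect_true(all(got$f > 0 & got$f < 1))
    expect_true(all(got$i > 0 & got$i < 1))
    expect_true(all(got$chat > -1 & got$chat < 1))
  }
  expect_error(lstm_cell(rnorm(3), rnorm(2), rnorm(2),
                         list(W_f = matrix(0, 2, 4))), "width")
})

test_that("probability outputs are normalized, consistent and equivariant", {
  bs <- fx_beat_set()
  f <- fx_features()
  fit <- train_beat_classifier(f, bs$labels, "gbtree", seed = 1)
  p <- predict(fit, f)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_equal(colnames(p), sort(unique(bs$labels)))
  # argmax of each probability row equals the class prediction
  lab <- predict(fit, f, type = "class")
  expect_equal(as.character(lab),
               colnames(p)[max.col(p, ties.method = "first")])
  # permuting input rows permutes output rows identically
  perm <- rev(seq_len(20))
  expect_equal(predict(fit, f[1:20, ][perm, ]), p[1:20, ][perm, ])
  # single input -> single row
  expect_equal(nrow(predict(fit, f[1, , drop = FALSE])), 1)
})

test_that("classical training is deterministic and separates easy data", {
  set.seed(10)
  x <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(200, 6), ncol = 2))
  y <- rep(c("a", "b"), each = 100)
  for (m in c("lr", "svm", "gbtree")) {
    fit <- train_beat_classifier(x, y, m, seed = 5)
    expect_equal(mean(predict(fit, x, type = "class") == y), 1)
    fit2 <- train_beat_classifier(x, y, m, seed = 5)
    expect_identical(predict(fit, x), predict(fit2, x))
  }
  expect_error(train_beat_classifier(x, rep("a", 200), "lr"), "2 classes")
})

test_that("gbtree records its boosting hyperparameters in the fit", {
  bs <- fx_beat_set()
  fit <- train_beat_classifier(fx_features(), bs$labels, "gbtree")
  sp <- fit$fit$spec
  expect_equal(sp$eta, 0.3)
  expect_equal(sp$max_depth, 6)
  expect_equal(sp$lambda, 5)
  expect_equal(sp$alpha, 3)
  expect_equal(sp$colsample_bytree, 0.9)
  expect_equal(sp$colsample_bylevel, 0.9)
  expect_equal(sp$seed, 2020)
})

test_that("class weights shift predictions toward the upweighted class", {
  set.seed(11)
  # overlapping classes so the decision boundary is weight-sensitive
  x <- rbind(matrix(rnorm(300, 0), ncol = 3),
             matrix(rnorm(300, 0.5), ncol = 3))
  y <- rep(c("a", "b"), each = 100)
  base <- train_beat_classifier(x, y, "lr", seed = 1)
  up_b <- train_beat_classifier(x, y, "lr", seed = 1,
                                weights = c(a = 1, b = 10))
  n_b_base <- sum(predict(base, x, type = "class") == "b")
  n_b_up <- sum(predict(up_b, x, type = "class") == "b")
  expect_gt(n_b_up, n_b_base)
})

test_that("the deep models learn an easy two-class problem quickly", {
  bs <- synthetic_beat_set(80, classes = c("N", "V"), seed = 21)
  sp <- split_beats(bs, split_spec(test_fraction = 0.25, seed = 1))
  xtr <- bs$x[sp$train, ]; ytr <- bs$labels[sp$train]
  xte <- bs$x[sp$test, ]; yte <- bs$labels[sp$test]
  cnn <- train_beat_classifier(xtr, ytr, "cnn",
                               spec = cnn_spec(epochs = 6, seed = 2020))
  expect_gte(mean(predict(cnn, xte, type = "class") == yte), 0.9)
  lstm <- train_beat_classifier(xtr, ytr, "lstm",
                                spec = lstm_spec(hidden = 24, seq_len = 25,
                                                 epochs = 6, seed = 2020))
  expect_gte(mean(predict(lstm, xte, type = "class") == yte), 0.9)
  # aami variant instantiates the enlarged kernel ladder
  expect_equal(cnn_spec(variant = "aami")$kernels, c(11, 9, 6, 3))
  expect_error(train_beat_classifier(xtr[, 1:100], ytr, "lstm",
                                     spec = lstm_spec(seq_len = 33)),
               "divide")
})
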