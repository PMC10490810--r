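#' Train a heartbeat classifier
#'
#' One fitting entry point for the five model families. The classical
#' models (`"lr"`, `"svm"`, `"gbtree"`) expect an engineered feature
#' matrix; the deep models (`"cnn"`, `"lstm"`) expect raw 250-sample
#' beats. Inputs are standardized internally (per column for the
#' classical models, globally for the deep models) and the scaling is
#' stored with the fit.
#'
#' Default hyperparameters follow the tuned values for this task:
#' gradient-boosted trees with eta 0.3, max_depth 6, lambda 5, alpha 3,
#' colsample_bytree/bylevel 0.9, seed 2020; the deep models train with
#' Adam at learning rate 0.001, batch size 64, dropout 0.5, seed 2020.
#'
#' @param x numeric matrix (rows = beats).
#' @param y class labels (factor or character).
#' @param model one of `"lr"`, `"svm"`, `"gbtree"`, `"cnn"`, `"lstm"`.
#' @param weights optional named per-class weight vector (see
#'   [rebalance()]); honored by every model family.
#' @param spec optional model-specific specification: a [cnn_spec()] or
#'   [lstm_spec()] for the deep models, or a named list of overrides
#'   (`nrounds` etc.) for the classical ones.
#' @param seed integer seed for model families without a seed in their
#'   spec.
#' @return a `beat_classifier` with [predict()], `print()` and
#'   `summary()` methods.
#' @export
train_beat_classifier <- function(x, y,
                                  model = c("lr", "svm", "gbtree", "cnn",
                                            "lstm"),
                                  weights = NULL, spec = NULL, seed = 2020) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop_invalid("need at least 2 classes, got %d",
                                   nlevels(y))
  if (nrow(x) != length(y)) stop_invalid("rows of `x` must match `y`")
  classes <- levels(y)
  y_idx <- as.integer(y)
  class_w <- if (is.null(weights)) NULL else {
    if (!all(classes %in% names(weights)))
      stop_invalid("`weights` must name every class")
    as.numeric(weights[classes])
  }

  if (model %in% c("lr", "svm", "gbtree")) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl < 1e-12] <- 1
    xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    scaling <- list(kind = "column", center = ctr, scale = scl)
  } else {
    mu <- mean(x); s <- sd(as.numeric(x))
    if (s < 1e-12) s <- 1
    xs <- (x - mu) / s
    scaling <- list(kind = "global", center = mu, scale = s)
  }
  row_w <- if (is.null(class_w)) NULL else class_w[y_idx]

  set.seed(as.integer(seed))
  fit <- switch(model,
    lr = {
      df <- data.frame(.y = y, xs, check.names = FALSE)
      nnet::multinom(
        .y ~ ., data = df, trace = FALSE, maxit = 300,
        MaxNWts = (ncol(xs) + 1L) * nlevels(y) + 4L, decay = 1e-4,
        weights = if (is.null(row_w)) rep(1, nrow(xs)) else row_w)
    },
    svm = {
      e1071::svm(xs, y, probability = TRUE, kernel = "radial", scale = FALSE,
                 class.weights = if (is.null(class_w)) NULL
                                 else setNames(class_w, classes))
    },
    gbtree = {
      sp <- modifyList(list(eta = 0.3, max_depth = 6, lambda = 5, alpha = 3,
                            colsample_bytree = 0.9, colsample_bylevel = 0.9,
                            seed = 2020, nrounds = 60),
                       if (is.list(spec)) spec else list())
      set.seed(sp$seed)
      dtr <- xgboost::xgb.DMatrix(xs, label = y_idx - 1L,
                                  weight = if (is.null(row_w)) NULL else row_w)
      list(booster = xgboost::xgb.train(
             params = list(objective = "multi:softprob",
                           num_class = nlevels(y), eta = sp$eta,
                           max_depth = sp$max_depth, lambda = sp$lambda,
                           alpha = sp$alpha,
                           colsample_bytree = sp$colsample_bytree,
                           colsample_bylevel = sp$colsample_bylevel,
                           nthread = 1),
             data = dtr, nrounds = sp$nrounds, verbose = 0),
           spec = sp)
    },
    cnn = {
      sp <- if (inherits(spec, "cnn_spec")) spec else cnn_spec()
      list(net = train_cnn_impl(xs, y_idx, nlevels(y), sp, class_w),
           spec = sp)
    },
    lstm = {
      sp <- if (inherits(spec, "lstm_spec")) spec else lstm_spec()
      list(net = train_lstm_impl(xs, y_idx, nlevels(y), sp, class_w),
           spec = sp)
    })

  structure(list(model = model, fit = fit, classes = classes,
                 scaling = scaling, n_train = nrow(x), seed = seed),
            class = "beat_classifier")
}

apply_scaling <- function(x, scaling) {
  if (scaling$kind == "column")
    sweep(sweep(x, 2, scaling$center), 2, scaling$scale, "/")
  else (x - scaling$center) / scaling$scale
}

#' Predict from a beat classifier
#'
#' @param object a `beat_classifier`.
#' @param newdata matrix with the same column layout as the training data.
#' @param type `"prob"` for a probability matrix (rows sum to 1, columns
#'   in the model's class order) or `"class"` for labels.
#' @param ... unused.
#' @export
predict.beat_classifier <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  xs <- apply_scaling(x, object$scaling)
  probs <- switch(object$model,
    lr = {
      df <- data.frame(xs, check.names = FALSE)
      p <- predict(object$fit, newdata = df, type = "probs")
      if (is.null(dim(p))) {
        if (length(object$classes) == 2L)
          p <- cbind(1 - p, p)
        else p <- matrix(p, nrow = 1)
      }
      p
    },
    svm = {
      pr <- predict(object$fit, xs, probability = TRUE)
      p <- attr(pr, "probabilities")
      p[, object$classes, drop = FALSE]  # svm permutes columns
    },
    gbtree = {
      p <- predict(object$fit$booster, xgboost::xgb.DMatrix(xs))
      if (is.null(dim(p)))
        p <- matrix(p, ncol = length(object$classes), byrow = TRUE)
      p
    },
    cnn = predict_cnn_impl(object$fit$net, xs, object$fit$spec),
    lstm = predict_lstm_impl(object$fit$net, xs, object$fit$spec))
  probs <- as.matrix(probs)
  colnames(probs) <- object$classes
  rownames(probs) <- NULL
  if (type == "prob") probs
  else factor(object$classes[max.col(probs, ties.method = "first")],
              levels = object$classes)
}

#' @export
print.beat_classifier <- function(x, ...) {
  cat(sprintf("<beat_classifier> model=%s, classes=[%s], trained on %d beats\n",
              x$model, paste(x$classes, collapse = ", "), x$n_train))
  invisible(x)
}

#' @export
summary.beat_classifier <- function(object, ...) {
  print(object)
  if (object$model == "gbtree") {
    cat("hyperparameters:\n")
    utils::str(object$fit$spec, give.attr = FALSE)
  }
  if (object$model %in% c("cnn", "lstm")) {
    ls <- object$fit$net$loss
    cat(sprintf("training loss: first %.4f -> last %.4f over %d epochs\n",
                ls[1], ls[length(ls)], length(ls)))
  }
  invisible(object)
}
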