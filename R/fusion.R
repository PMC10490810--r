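#' Bundle per-model probability predictions
#'
#' @param probs named list of probability matrices over the same inputs,
#'   identical dimensions and column (class) order.
#' @return a `prediction_set`.
#' @export
prediction_set <- function(probs) {
  if (!length(probs)) stop_invalid("need at least one model's predictions")
  if (is.null(names(probs)) || any(!nzchar(names(probs))))
    stop_invalid("`probs` must be a named list")
  dims <- unique(lapply(probs, dim))
  if (length(dims) != 1L)
    stop_invalid("all probability matrices must have identical shape")
  structure(list(probs = probs, models = names(probs),
                 classes = colnames(probs[[1]])),
            class = "prediction_set")
}

#' Hard (majority) voting
#'
#' Each model votes its argmax label; the modal label wins. Ties are
#' broken in favour of the earliest model (in `models` order) whose vote
#' is among the tied labels.
#'
#' @param predictions a [prediction_set()].
#' @return factor of fused labels.
#' @export
hard_vote <- function(predictions) {
  stopifnot(inherits(predictions, "prediction_set"))
  classes <- predictions$classes
  votes <- vapply(predictions$probs,
                  function(p) max.col(p, ties.method = "first"),
                  integer(nrow(predictions$probs[[1]])))
  votes <- matrix(votes, ncol = length(predictions$probs))
  out <- apply(votes, 1, function(v) {
    tab <- tabulate(v, nbins = length(classes))
    tied <- which(tab == max(tab))
    if (length(tied) == 1L) tied else v[v %in% tied][1]
  })
  factor(classes[out], levels = classes)
}

#' Soft (probability-average) voting
#'
#' @param predictions a [prediction_set()].
#' @return list with `labels` (argmax of the mean) and `probs` (the
#'   unweighted mean probability matrix).
#' @export
soft_vote <- function(predictions) {
  stopifnot(inherits(predictions, "prediction_set"))
  mean_p <- Reduce(`+`, predictions$probs) / length(predictions$probs)
  labels <- factor(predictions$classes[max.col(mean_p, ties.method = "first")],
                   levels = predictions$classes)
  list(labels = labels, probs = mean_p)
}

#' Fit a five-fold stacking ensemble
#'
#' Every base model is trained five times on stratified
#' leave-one-fold-out training sets; its out-of-fold class probabilities
#' are concatenated into meta-features for the whole training set, on
#' which the meta-learner (multinomial logistic regression) is trained.
#' At inference each base model's five fold-fits predict the new inputs
#' and their probabilities are averaged before entering the meta-learner.
#'
#' Base models may consume different input representations: each base
#' spec names the element of the `inputs` list it reads.
#'
#' @param inputs named list of training input matrices over the same
#'   beats (e.g. `list(features = ..., beats = ...)`).
#' @param y class labels.
#' @param base named list of base-model declarations
#'   `list(model = <family>, input = <inputs name>, spec = <optional>)`.
#' @param folds fold count (default 5).
#' @param seed integer seed driving the fold assignment and base fits.
#' @return an `ecg_stacking` model with a [predict()] method.
#' @export
fit_stacking <- function(inputs, y,
                         base = list(
                           gbtree = list(model = "gbtree", input = "features"),
                           cnn = list(model = "cnn", input = "beats"),
                           lstm = list(model = "lstm", input = "beats")),
                         folds = 5, seed = 1L) {
  y <- factor(y)
  classes <- levels(y)
  n <- length(y)
  for (b in base)
    if (!b$input %in% names(inputs))
      stop_invalid("base model input '%s' not in `inputs`", b$input)
  if (min(table(y)) < folds)
    stop_invalid("every class must appear in every fold: smallest class has %d < %d members",
                 min(table(y)), folds)
  set.seed(as.integer(seed))
  fold_id <- integer(n)
  for (cl in classes) {
    idx <- which(y == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  meta_x <- matrix(NA_real_, n, length(base) * length(classes))
  fold_fits <- vector("list", length(base))
  names(fold_fits) <- names(base)
  for (m in seq_along(base)) {
    b <- base[[m]]
    xin <- as.matrix(inputs[[b$input]])
    fits <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      fit <- train_beat_classifier(xin[tr, , drop = FALSE], y[tr],
                                   model = b$model, spec = b$spec,
                                   seed = seed + f)
      meta_x[te, (m - 1L) * length(classes) + seq_along(classes)] <-
        predict(fit, xin[te, , drop = FALSE], type = "prob")
      fits[[f]] <- fit
    }
    fold_fits[[m]] <- fits
  }
  colnames(meta_x) <- paste(rep(names(base), each = length(classes)),
                            rep(classes, length(base)), sep = ".")
  meta_df <- data.frame(.y = y, meta_x, check.names = FALSE)
  set.seed(as.integer(seed))
  meta <- nnet::multinom(.y ~ ., data = meta_df, trace = FALSE, maxit = 300,
                         MaxNWts = (ncol(meta_x) + 1L) * nlevels(y) + 4L)
  structure(list(base = base, fold_fits = fold_fits, meta = meta,
                 classes = classes, folds = folds, seed = seed,
                 meta_width = ncol(meta_x)),
            class = "ecg_stacking")
}

#' Predict from a stacking ensemble
#'
#' @param object an `ecg_stacking` model.
#' @param inputs named list of input matrices matching the training
#'   layout.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @export
predict.ecg_stacking <- function(object, inputs, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  classes <- object$classes
  meta_x <- NULL
  for (m in seq_along(object$base)) {
    b <- object$base[[m]]
    xin <- as.matrix(inputs[[b$input]])
    p <- Reduce(`+`, lapply(object$fold_fits[[m]], predict, newdata = xin,
                            type = "prob")) / object$folds
    meta_x <- cbind(meta_x, p)
  }
  colnames(meta_x) <- paste(rep(names(object$base), each = length(classes)),
                            rep(classes, length(object$base)), sep = ".")
  p <- predict(object$meta, newdata = data.frame(meta_x, check.names = FALSE),
               type = "probs")
  if (is.null(dim(p))) {
    # multinom collapses to a vector for two classes or a single row
    p <- if (length(classes) == 2L && length(p) == nrow(meta_x))
      cbind(1 - p, p) else matrix(p, nrow = 1)
  }
  if (type == "prob") { colnames(p) <- classes; p }
  else factor(classes[max.col(as.matrix(p), ties.method = "first")],
              levels = classes)
}

#' @export
print.ecg_stacking <- function(x, ...) {
  cat(sprintf("<ecg_stacking> base=[%s], %d folds, meta=multinomial LR\n",
              paste(names(x$base), collapse = ", "), x$folds))
  invisible(x)
}
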