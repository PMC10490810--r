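#' Score predictions against truth
#'
#' Builds the confusion matrix (true x predicted), the overall accuracy
#' (trace / total, in percent) and per-class accuracy (diagonal /
#' row sum, in percent) -- i.e. per-class recall, the "accuracy" of the
#' clinical per-class tables. A class absent from the truth gets `NA`
#' per-class accuracy, not 0.
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes ordered class list; every label must belong to it.
#' @return an `ecg_eval`: list with `confusion`, `overall` (%),
#'   `per_class` (data.frame class / n / correct / accuracy).
#' @export
evaluate_predictions <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  check_equal_length(truth, predicted, "truth", "predicted")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  outside <- setdiff(unique(c(truth, predicted)), classes)
  if (length(outside))
    stop_invalid("label(s) outside the class list: %s",
                 paste(outside, collapse = ", "))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(classes, classes))
  n <- rowSums(cm)
  correct <- diag(cm)
  per_class <- data.frame(class = classes, n = as.integer(n),
                          correct = as.integer(correct),
                          accuracy = ifelse(n > 0, correct / n * 100, NA_real_),
                          stringsAsFactors = FALSE)
  structure(list(confusion = cm,
                 overall = sum(correct) / length(truth) * 100,
                 per_class = per_class),
            class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, digits = 2, ...) {
  cat(sprintf("Overall accuracy: %.*f%%  (n = %d)\n", digits, x$overall,
              sum(x$per_class$n)))
  tab <- x$per_class
  tab$accuracy <- ifelse(is.na(tab$accuracy), "-",
                         sprintf("%.*f", digits, tab$accuracy))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Default end-to-end pipeline configuration
#'
#' @param seed master seed; every random stage derives from it.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(presets = c("normal", "lbbb", "rbbb", "pvc"),
                    duration = 120, noise_sd = 0.05),
    denoise = list(basis = "bior2.6", level = 8, mode = "soft"),
    detector = list(),
    segmentation = list(pre = 100, post = 150, scheme = "mitbih4",
                        test_fraction = 0.2, label_tol = 0.05),
    features = list(basis = "db4", level = 4),
    models = c("lr", "svm", "gbtree", "cnn", "lstm"),
    cnn = list(epochs = 20),
    lstm = list(epochs = 20, hidden = 32, seq_len = 25),
    fusion = list(base = c("gbtree", "cnn", "lstm"), folds = 5,
                  fold_epochs = 10))
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) annotated records, denoise, detect R-peaks,
#' attach truth labels, segment, engineer features, train the configured
#' models, fuse them, and score everything on a stratified held-out set.
#'
#' @param config a configuration list like [pipeline_config()], or the
#'   path of a YAML file holding one.
#' @return list with `reports` (an `ecg_eval` per model plus the fusion
#'   methods), `detector` (sensitivity / positive predictivity of the
#'   QRS stage), and `counts`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)

  # --- records ---------------------------------------------------------
  records <- list()
  if (!is.null(config$records)) {
    records <- lapply(config$records, read_ecg)
  } else {
    sim <- config$simulate
    for (i in seq_along(sim$presets)) {
      rs <- seed * 100L + i
      rec <- simulate_ecg(sim$presets[[i]], duration = sim$duration,
                          noise = noise_spec(gaussian_sd = sim$noise_sd %||% 0,
                                             seed = rs),
                          seed = rs)
      records[[i]] <- rec
    }
  }

  # --- denoise + detect + segment -------------------------------------
  dn <- config$denoise %||% list()
  det_cfg <- do.call(detector_config, config$detector %||% list())
  seg <- config$segmentation %||% list()
  scheme <- label_scheme(seg$scheme %||% "mitbih4")
  sets <- list()
  tp <- 0L; fp <- 0L; fn <- 0L
  for (rec in records) {
    den <- rec
    den$samples <- wavelet_denoise(rec$samples, rec$fs,
                                   basis = dn$basis %||% "bior2.6",
                                   level = dn$level %||% 8,
                                   mode = dn$mode %||% "soft")
    r_idx <- detect_qrs(den$samples, den$fs, det_cfg)
    truth <- rec$annotations$sample
    tol <- as.integer(round((seg$label_tol %||% 0.05) * rec$fs))
    m <- match_peaks(truth, r_idx, tol)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    labels <- assign_labels(r_idx, rec$annotations, rec$fs,
                            tol = seg$label_tol %||% 0.05)
    bs <- segment_beats(den, r_indices = r_idx, labels = labels,
                        pre = seg$pre %||% 100, post = seg$post %||% 150)
    sets[[length(sets) + 1L]] <- bs
  }
  beats <- bind_beat_sets(sets)
  mapped <- map_labels(beats$labels, scheme)
  keep <- which(!is.na(mapped))
  beats$x <- beats$x[keep, , drop = FALSE]
  for (f in c("labels", "r_indices", "rr_prev", "rr_next", "record_id"))
    beats[[f]] <- beats[[f]][keep]
  beats$labels <- mapped[keep]

  # --- split + features ------------------------------------------------
  sp <- split_beats(beats, split_spec("beat_holdout",
                                      test_fraction = seg$test_fraction %||% 0.2,
                                      seed = seed))
  feats <- beat_features(beats, basis = config$features$basis %||% "db4",
                         level = config$features$level %||% 4)
  y_train <- beats$labels[sp$train]
  y_test <- beats$labels[sp$test]

  deep_spec <- function(model) {
    if (model == "cnn") do.call(cnn_spec, config$cnn %||% list())
    else do.call(lstm_spec, config$lstm %||% list())
  }
  input_of <- function(model, idx) {
    if (model %in% c("cnn", "lstm")) beats$x[idx, , drop = FALSE]
    else feats[idx, , drop = FALSE]
  }

  reports <- list()
  probs <- list()
  for (model in config$models %||% c("gbtree", "cnn", "lstm")) {
    fit <- train_beat_classifier(input_of(model, sp$train), y_train,
                                 model = model,
                                 spec = if (model %in% c("cnn", "lstm"))
                                   deep_spec(model) else NULL,
                                 seed = seed)
    p <- predict(fit, input_of(model, sp$test), type = "prob")
    probs[[model]] <- p
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    reports[[model]] <- evaluate_predictions(y_test, pred, scheme$classes)
  }

  # --- fusion ----------------------------------------------------------
  fu <- config$fusion
  if (!is.null(fu)) {
    avail <- intersect(fu$base %||% names(probs), names(probs))
    if (length(avail) >= 1L) {
      ps <- prediction_set(probs[avail])
      reports$hard_vote <- evaluate_predictions(y_test, hard_vote(ps),
                                                scheme$classes)
      reports$soft_vote <- evaluate_predictions(y_test, soft_vote(ps)$labels,
                                                scheme$classes)
      base <- lapply(avail, function(m) {
        spd <- NULL
        if (m %in% c("cnn", "lstm")) {
          spd <- deep_spec(m)
          if (!is.null(fu$fold_epochs)) spd$epochs <- as.integer(fu$fold_epochs)
        }
        list(model = m, input = if (m %in% c("cnn", "lstm")) "beats"
             else "features", spec = spd)
      })
      names(base) <- avail
      stk <- fit_stacking(list(features = feats[sp$train, , drop = FALSE],
                               beats = beats$x[sp$train, , drop = FALSE]),
                          y_train, base = base, folds = fu$folds %||% 5,
                          seed = seed)
      pred <- predict(stk, list(features = feats[sp$test, , drop = FALSE],
                                beats = beats$x[sp$test, , drop = FALSE]))
      reports$stacking <- evaluate_predictions(y_test, pred, scheme$classes)
    }
  }

  list(reports = reports,
       detector = list(sensitivity = tp / max(tp + fn, 1L),
                       ppv = tp / max(tp + fp, 1L)),
       counts = list(beats = length(beats$labels),
                     train = length(sp$train), test = length(sp$test),
                     skipped = beats$skipped))
}

#' Match detected peaks against reference peaks
#'
#' Greedy one-to-one matching within a sample tolerance; the standard
#' counting behind detector sensitivity (`TP / (TP + FN)`) and positive
#' predictivity (`TP / (TP + FP)`).
#'
#' @param truth,detected integer sample indices.
#' @param tol_samples matching tolerance in samples.
#' @return list with `tp`, `fp`, `fn`.
#' @export
match_peaks <- function(truth, detected, tol_samples) {
  used <- logical(length(detected))
  tp <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- .Machine$integer.max
    if (length(d) && min(d) <= tol_samples) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = sum(!used), fn = length(truth) - tp)
}

#' Write / read an evaluation report as JSON
#'
#' Lossless round-trip of the confusion matrix, overall accuracy and
#' per-class table.
#'
#' @param report an `ecg_eval`.
#' @param path JSON file path.
#' @return `read_eval_report` returns the reconstructed `ecg_eval`.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "ecg_eval"))
  obj <- list(classes = colnames(report$confusion),
              confusion = unname(report$confusion),
              overall = report$overall,
              per_class = report$per_class)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- matrix(as.integer(obj$confusion), nrow = length(obj$classes),
               dimnames = list(obj$classes, obj$classes))
  pc <- as.data.frame(obj$per_class)
  pc$n <- as.integer(pc$n)
  pc$correct <- as.integer(pc$correct)
  pc$accuracy <- as.numeric(pc$accuracy)
  structure(list(confusion = cm, overall = as.numeric(obj$overall),
                 per_class = pc),
            class = "ecg_eval")
}
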