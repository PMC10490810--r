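#' Cut fixed-length beats around R-peaks
#'
#' Each beat keeps `pre` samples before the R sample and `post` samples
#' from the R sample onward (defaults 100/150, i.e. 250-sample beats with
#' the R-peak at offset 100). Beats too close to a record edge are
#' skipped and counted.
#'
#' @param record an [ecg_record()].
#' @param r_indices 1-based R-peak sample indices; defaults to the
#'   record's annotations.
#' @param labels beat symbols aligned with `r_indices`; defaults to the
#'   annotation symbols (or `NA` for detector output).
#' @param pre,post samples kept before / from the R-peak.
#' @return a `beat_set`: list with `x` (matrix, one 250-sample row per
#'   beat), `labels`, `r_offset` (= `pre`), `rr_prev` / `rr_next`
#'   (neighbouring RR intervals in seconds, `NA` at record edges), `fs`,
#'   `record_id`, and `skipped` (edge-truncated beat count).
#' @export
segment_beats <- function(record, r_indices = NULL, labels = NULL,
                          pre = 100, post = 150) {
  stopifnot(inherits(record, "ecg_record"))
  pre <- as.integer(pre); post <- as.integer(post)
  if (pre + post <= 0L) stop_invalid("`pre` + `post` must be positive")
  if (is.null(r_indices)) {
    r_indices <- record$annotations$sample
    if (is.null(labels)) labels <- record$annotations$symbol
  }
  r_indices <- as.integer(r_indices)
  if (is.null(labels)) labels <- rep(NA_character_, length(r_indices))
  if (length(labels) != length(r_indices))
    stop_invalid("`labels` must align with `r_indices`")
  if (is.unsorted(r_indices)) {
    o <- order(r_indices)
    r_indices <- r_indices[o]; labels <- labels[o]
  }
  n <- length(record$samples)
  ok <- r_indices - pre >= 1L & r_indices + post - 1L <= n
  skipped <- sum(!ok)
  r_keep <- r_indices[ok]
  lab_keep <- labels[ok]

  width <- pre + post
  x <- matrix(0, nrow = length(r_keep), ncol = width)
  for (i in seq_along(r_keep))
    x[i, ] <- record$samples[(r_keep[i] - pre):(r_keep[i] + post - 1L)]

  rr <- diff(r_indices) / record$fs
  rr_prev_all <- c(NA_real_, rr)
  rr_next_all <- c(rr, NA_real_)
  structure(list(x = x, labels = lab_keep, r_indices = r_keep,
                 r_offset = pre, fs = record$fs,
                 rr_prev = rr_prev_all[ok], rr_next = rr_next_all[ok],
                 record_id = rep(record$record_id, length(r_keep)),
                 skipped = skipped),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats x %d samples (R at offset %d), %d skipped\n",
              nrow(x$x), ncol(x$x), x$r_offset, x$skipped))
  if (any(!is.na(x$labels))) print(table(x$labels, useNA = "no"))
  invisible(x)
}

#' Concatenate beat sets
#' @param ... `beat_set` objects with identical beat width and offset.
#' @return a combined `beat_set`.
#' @export
bind_beat_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "beat_set"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, logical(1), "beat_set")))
  w <- unique(vapply(sets, function(s) ncol(s$x), integer(1)))
  o <- unique(vapply(sets, function(s) s$r_offset, integer(1)))
  if (length(w) != 1L || length(o) != 1L)
    stop_invalid("beat sets have inconsistent widths or offsets")
  structure(list(
    x = do.call(rbind, lapply(sets, `[[`, "x")),
    labels = unlist(lapply(sets, `[[`, "labels")),
    r_indices = unlist(lapply(sets, `[[`, "r_indices")),
    r_offset = o, fs = sets[[1]]$fs,
    rr_prev = unlist(lapply(sets, `[[`, "rr_prev")),
    rr_next = unlist(lapply(sets, `[[`, "rr_next")),
    record_id = unlist(lapply(sets, `[[`, "record_id")),
    skipped = sum(vapply(sets, `[[`, numeric(1), "skipped"))),
    class = "beat_set")
}

#' Label schemes
#'
#' `mitbih4` keeps the four raw MIT-BIH symbols N, L, R, V and drops
#' everything else. `aami4` groups symbols into the EC57 superclasses:
#' N, L, R, e, j -> N; A, a, J, S -> S; V, E -> V; F -> F; the
#' unclassifiable group (/, f, Q) is excluded.
#'
#' @param name `"mitbih4"` or `"aami4"`.
#' @return a `label_scheme` with `name`, `classes` and `mapping`
#'   (named character vector symbol -> class).
#' @export
label_scheme <- function(name = c("mitbih4", "aami4")) {
  name <- match.arg(name)
  if (name == "mitbih4") {
    mapping <- c(N = "N", L = "L", R = "R", V = "V")
    classes <- c("N", "L", "R", "V")
  } else {
    mapping <- c(N = "N", L = "N", R = "N", e = "N", j = "N",
                 A = "S", a = "S", J = "S", S = "S",
                 V = "V", E = "V",
                 F = "F")
    classes <- c("N", "S", "V", "F")
  }
  structure(list(name = name, classes = classes, mapping = mapping),
            class = "label_scheme")
}

#' Map beat symbols to scheme classes
#'
#' Symbols outside the scheme's domain map to `NA` (dropped); the number
#' of dropped symbols is attached as attribute `dropped`.
#'
#' @param symbols character vector of MIT-BIH beat symbols.
#' @param scheme a [label_scheme()].
#' @return character vector of class identifiers (with `NA` for dropped).
#' @export
map_labels <- function(symbols, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  out <- unname(scheme$mapping[symbols])
  structure(out, dropped = sum(is.na(out)))
}

#' Attach ground-truth labels to detected beats
#'
#' Each detected R index receives the symbol of the nearest annotation
#' within `tol` seconds; unmatched detections get `NA` so they can be
#' excluded from supervised sets.
#'
#' @param detected integer vector of detected R indices (1-based).
#' @param annotations annotation data.frame (`sample`, `symbol`).
#' @param fs sampling rate (Hz).
#' @param tol matching tolerance in seconds.
#' @return character vector of symbols aligned with `detected`.
#' @export
assign_labels <- function(detected, annotations, fs, tol = 0.05) {
  if (!nrow(annotations)) return(rep(NA_character_, length(detected)))
  vapply(detected, function(r) {
    d <- abs(annotations$sample - r)
    i <- which.min(d)
    if (d[i] <= tol * fs) annotations$symbol[i] else NA_character_
  }, character(1))
}

#' Train/test partitioning specification
#'
#' @param method `"beat_holdout"` (stratified by class),
#'   `"record_holdout"` (whole records on one side) or
#'   `"cross_validation"` (stratified folds).
#' @param test_fraction held-out fraction for the holdout methods.
#' @param folds fold count for cross-validation (>= 2).
#' @param seed integer seed; the partition is deterministic given it.
#' @return a `split_spec` list.
#' @export
split_spec <- function(method = c("beat_holdout", "record_holdout",
                                  "cross_validation"),
                       test_fraction = 0.2, folds = 5, seed = 1L) {
  method <- match.arg(method)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_invalid("`test_fraction` must be in (0, 1)")
  if (folds < 2) stop_invalid("`folds` must be >= 2")
  structure(list(method = method, test_fraction = test_fraction,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition beats into train and test sets
#'
#' @param beats a `beat_set` with non-`NA` labels.
#' @param spec a [split_spec()].
#' @return for the holdout methods, `list(train = indices, test = indices)`;
#'   for cross-validation, an integer fold assignment per beat.
#' @export
split_beats <- function(beats, spec = split_spec()) {
  stopifnot(inherits(beats, "beat_set"), inherits(spec, "split_spec"))
  labels <- beats$labels
  if (anyNA(labels)) stop_invalid("all beats must be labelled before splitting")
  n <- length(labels)
  if (n < 2L) stop_invalid("need at least 2 beats")
  set.seed(spec$seed)
  if (spec$method == "beat_holdout") {
    test <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_test <- round(length(idx) * spec$test_fraction)
      if (n_test < 1L || n_test >= length(idx))
        stop_invalid("class '%s' has too few beats (%d) to stratify", cl,
                     length(idx))
      test <- c(test, sample(idx, n_test))
    }
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  } else if (spec$method == "record_holdout") {
    recs <- unique(beats$record_id)
    if (length(recs) < 2L)
      stop_invalid("record holdout needs >= 2 distinct source records")
    n_test <- max(1L, round(length(recs) * spec$test_fraction))
    test_recs <- sample(recs, n_test)
    test <- which(beats$record_id %in% test_recs)
    list(train = setdiff(seq_len(n), test), test = test)
  } else {
    folds <- integer(n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < spec$folds)
        stop_invalid("class '%s' has fewer beats (%d) than folds (%d)", cl,
                     length(idx), spec$folds)
      folds[idx] <- sample(rep_len(seq_len(spec$folds), length(idx)))
    }
    folds
  }
}

#' Rebalance a training set across classes
#'
#' * `weights`: data unchanged; returns inverse-frequency class weights
#'   `total / (n_classes * count)`.
#' * `oversample`: minority classes resampled with replacement up to the
#'   majority count.
#' * `undersample`: majority classes subsampled down to the minority count.
#'
#' @param labels class label per training row.
#' @param strategy one of `"weights"`, `"oversample"`, `"undersample"`.
#' @param seed integer seed for the resampling draws.
#' @return list with `idx` (row indices of the rebalanced set) and
#'   `weights` (named per-class weight vector; all 1 for the resampling
#'   strategies).
#' @export
rebalance <- function(labels, strategy = c("weights", "oversample",
                                           "undersample"), seed = 1L) {
  strategy <- match.arg(strategy)
  counts <- table(labels)
  if (any(counts == 0) || anyNA(labels))
    stop_invalid("every class must have at least one labelled beat")
  classes <- names(counts)
  set.seed(as.integer(seed))
  if (strategy == "weights") {
    w <- length(labels) / (length(counts) * as.numeric(counts))
    return(list(idx = seq_along(labels), weights = setNames(w, classes)))
  }
  target <- if (strategy == "oversample") max(counts) else min(counts)
  idx <- integer(0)
  for (cl in classes) {
    pool <- which(labels == cl)
    idx <- c(idx, if (length(pool) == target) pool
             else if (length(pool) > target) sample(pool, target)
             else c(pool, sample(pool, target - length(pool), replace = TRUE)))
  }
  list(idx = sort(idx), weights = setNames(rep(1, length(classes)), classes))
}
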