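#' Morphological features of one beat
#'
#' Operationalizes the morphology that separates ventricular ectopy from
#' the other classes: QRS width/deformation, ST level, T-vs-QRS polarity,
#' plus standard RR features. The baseline is the mean of the first
#' `baseline_n` samples of the segment; all search windows are clipped to
#' the segment bounds.
#'
#' Emitted values: `r_amp`, `q_amp`, `s_amp` (minima within 0.07 s before
#' / after R), `qrs_dur` (s, extent of the contiguous region around R
#' where `|x - baseline|` exceeds 10% of the R deflection, small
#' sub-threshold gaps tolerated), `qrs_polarity`, `t_amp` and
#' `t_polarity` (extremum in R+0.10..0.35 s), `st_level` (mean of
#' R+0.06..0.10 s minus baseline), `qrs_area` (sum of `|x - baseline|`
#' over the QRS span), `rr_prev`, `rr_next`, `rr_ratio`.
#'
#' @param beat numeric vector (one segmented beat, mV).
#' @param fs sampling rate (Hz).
#' @param r_offset samples before the R-peak in the segment (default 100).
#' @param rr_prev,rr_next neighbouring RR intervals (s); `NA` at record
#'   edges is replaced by the sentinel `0.8` s.
#' @param baseline_n samples averaged for the baseline estimate.
#' @return named numeric vector of 12 features.
#' @export
morphological_features <- function(beat, fs, r_offset = 100,
                                   rr_prev = NA, rr_next = NA,
                                   baseline_n = 20) {
  n <- length(beat)
  r <- r_offset + 1L
  baseline <- mean(beat[seq_len(min(baseline_n, n))])
  clip <- function(i) min(max(i, 1L), n)
  win <- function(a, b) if (a > b) integer(0) else clip(a):clip(b)

  r_amp <- beat[r] - baseline
  w <- as.integer(round(0.07 * fs))
  q_win <- win(r - w, r - 1L)
  s_win <- win(r + 1L, r + w)
  q_amp <- if (length(q_win)) min(beat[q_win]) - baseline else 0
  s_amp <- if (length(s_win)) min(beat[s_win]) - baseline else 0

  # QRS duration: contiguous |x - baseline| >= 10% of |R| around R,
  # tolerating sub-threshold gaps of up to 10 ms (the Q-R / R-S notches)
  thr <- 0.1 * abs(r_amp)
  above <- abs(beat - baseline) >= thr
  gap_max <- max(1L, as.integer(round(0.01 * fs)))
  span_max <- as.integer(round(0.12 * fs))
  lo <- r; gap <- 0L
  while (lo > 1L && r - lo < span_max) {
    if (above[lo - 1L]) { lo <- lo - 1L; gap <- 0L }
    else if (gap < gap_max) { lo <- lo - 1L; gap <- gap + 1L }
    else break
  }
  while (lo < r && !above[lo]) lo <- lo + 1L
  hi <- r; gap <- 0L
  while (hi < n && hi - r < span_max) {
    if (above[hi + 1L]) { hi <- hi + 1L; gap <- 0L }
    else if (gap < gap_max) { hi <- hi + 1L; gap <- gap + 1L }
    else break
  }
  while (hi > r && !above[hi]) hi <- hi - 1L
  qrs_dur <- (hi - lo + 1L) / fs
  qrs_polarity <- sign(r_amp)
  qrs_area <- sum(abs(beat[lo:hi] - baseline)) / fs

  t_win <- win(r + as.integer(round(0.10 * fs)), r + as.integer(round(0.35 * fs)))
  if (length(t_win)) {
    dev <- beat[t_win] - baseline
    t_amp <- dev[which.max(abs(dev))]
  } else t_amp <- 0
  t_polarity <- sign(t_amp)

  st_win <- win(r + as.integer(round(0.06 * fs)), r + as.integer(round(0.10 * fs)))
  st_level <- if (length(st_win)) mean(beat[st_win]) - baseline else 0

  if (is.na(rr_prev) || rr_prev <= 0) rr_prev <- 0.8
  if (is.na(rr_next) || rr_next <= 0) rr_next <- 0.8

  c(r_amp = r_amp, q_amp = q_amp, s_amp = s_amp, qrs_dur = qrs_dur,
    qrs_polarity = qrs_polarity, t_amp = t_amp, t_polarity = t_polarity,
    st_level = st_level, qrs_area = qrs_area,
    rr_prev = rr_prev, rr_next = rr_next, rr_ratio = rr_prev / rr_next)
}

#' Wavelet-coefficient features of one beat
#'
#' Multilevel decomposition of the beat; the feature vector concatenates
#' the approximation coefficients at the final level with the detail
#' coefficients of the two coarsest levels. For a fixed (basis, level)
#' the layout and length are fixed across beats.
#'
#' @param beat numeric vector.
#' @param basis wavelet basis (default db4).
#' @param level decomposition depth (default 4; `2^level` must not exceed
#'   the beat length).
#' @return named numeric vector of coefficients.
#' @export
wavelet_features <- function(beat, basis = "db4", level = 4) {
  if (2^level > length(beat))
    stop_invalid("level %d too deep for a %d-sample beat", level, length(beat))
  dec <- wt_dec(beat, basis, level)
  parts <- list(a = dec$a, d = dec$d[[level]])
  if (level >= 2) parts$d2 <- dec$d[[level - 1]]
  out <- unlist(parts)
  names(out) <- c(sprintf("a%d_%02d", level, seq_along(parts$a)),
                  sprintf("d%d_%02d", level, seq_along(parts$d)),
                  if (level >= 2)
                    sprintf("d%d_%02d", level - 1, seq_along(parts$d2)))
  out
}

#' Feature matrix for a beat set
#'
#' Rows are beats; columns are the morphological features followed by the
#' wavelet-coefficient features. Deterministic and independent of beat
#' order.
#'
#' @param beats a `beat_set`.
#' @param basis,level passed to [wavelet_features()].
#' @return numeric matrix with named columns.
#' @export
beat_features <- function(beats, basis = "db4", level = 4) {
  stopifnot(inherits(beats, "beat_set"))
  n <- nrow(beats$x)
  rows <- lapply(seq_len(n), function(i) {
    c(morphological_features(beats$x[i, ], beats$fs, beats$r_offset,
                             beats$rr_prev[i], beats$rr_next[i]),
      wavelet_features(beats$x[i, ], basis, level))
  })
  do.call(rbind, rows)
}

#' Fit a dimensionality reducer
#'
#' * `pca`: principal components, retaining the smallest count whose
#'   cumulative explained-variance fraction reaches `target`.
#' * `lda`: linear discriminant projection (at most `n_classes - 1`
#'   dimensions). A rank-deficient within-class covariance is handled by
#'   projecting onto the full-rank PCA subspace first.
#' * `pca_then_lda`: explicit two-stage reduction.
#'
#' @param x numeric feature matrix (rows = beats).
#' @param labels class labels (required for the LDA methods).
#' @param method `"pca"`, `"lda"` or `"pca_then_lda"`.
#' @param target explained-variance fraction for PCA (default 0.95).
#' @return an `ecg_reducer` with a [predict()] method.
#' @export
fit_reducer <- function(x, labels = NULL,
                        method = c("pca", "lda", "pca_then_lda"),
                        target = 0.95) {
  method <- match.arg(method)
  x <- as.matrix(x)
  keep <- which(apply(x, 2, sd) > 1e-12)
  if (!length(keep)) stop_invalid("all features are constant")
  xk <- x[, keep, drop = FALSE]
  pca <- NULL; lda <- NULL; k <- NULL
  if (method %in% c("pca", "pca_then_lda")) {
    pca <- prcomp(xk, center = TRUE, scale. = TRUE)
    cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    k <- which(cum >= target)[1]
    if (is.na(k)) k <- length(cum)
  }
  if (method %in% c("lda", "pca_then_lda")) {
    if (is.null(labels)) stop_invalid("LDA requires labels")
    basis_x <- if (method == "pca_then_lda")
      pca$x[, seq_len(k), drop = FALSE] else xk
    # collinear feature blocks are expected (wavelet coefficients); the
    # rank fallback below handles genuine degeneracy
    lda <- tryCatch(
      suppressWarnings(MASS::lda(basis_x, grouping = factor(labels))),
      error = function(e) {
        # degenerate covariance: reduce to the full-rank PCA subspace first
        p <- prcomp(basis_x, center = TRUE, scale. = FALSE)
        r <- sum(p$sdev > 1e-8 * p$sdev[1])
        fit <- MASS::lda(p$x[, seq_len(r), drop = FALSE],
                         grouping = factor(labels))
        attr(fit, "pre_pca") <- list(p = p, r = r)
        fit
      })
  }
  structure(list(method = method, keep = keep, pca = pca, k = k, lda = lda),
            class = "ecg_reducer")
}

#' @export
predict.ecg_reducer <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$keep, drop = FALSE]
  if (object$method == "pca")
    return(predict(object$pca, x)[, seq_len(object$k), drop = FALSE])
  basis_x <- if (object$method == "pca_then_lda")
    predict(object$pca, x)[, seq_len(object$k), drop = FALSE] else x
  pre <- attr(object$lda, "pre_pca")
  if (!is.null(pre))
    basis_x <- predict(pre$p, basis_x)[, seq_len(pre$r), drop = FALSE]
  predict(object$lda, basis_x)$x
}

#' @export
print.ecg_reducer <- function(x, ...) {
  cat(sprintf("<ecg_reducer> method=%s", x$method))
  if (!is.null(x$k)) cat(sprintf(", pca components=%d", x$k))
  if (!is.null(x$lda)) cat(sprintf(", lda dims=%d", ncol(x$lda$scaling)))
  cat("\n")
  invisible(x)
}
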