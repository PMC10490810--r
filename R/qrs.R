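#' QRS detector configuration
#'
#' @param slope_window two-element vector (s): the slope lags examined on
#'   each side of a sample; 0.03-0.05 s spans the peak-to-baseline
#'   duration of a QRS limb.
#' @param integration_window trailing moving-average length in samples
#'   (the classical choice is 10-20; default 15).
#' @param smooth_cutoff low-pass cutoff (Hz) used to merge the double
#'   peaks the two-sided slope transform produces for one QRS (5-10 Hz;
#'   default 8).
#' @param refractory minimum inter-detection gap in seconds. 0.2 s is the
#'   physiological floor for sinus rhythm; detection of extreme
#'   tachyarrhythmias needs a value below the expected minimum RR.
#' @param accept_coeff a candidate peak is accepted only if its height
#'   exceeds `accept_coeff` times the mean of the past (up to 8) accepted
#'   peak heights; 0.4 is the base rule.
#' @param theta0_lim_frac,theta1_lim_frac floors for the adaptive high and
#'   low thresholds, as fractions of the initial height estimate.
#' @param init_frac the initial mean-peak estimate is `init_frac` times
#'   the transform maximum over the first 2 s.
#' @param refine_window half-width (s) of the window in which a detection
#'   is snapped to the largest absolute sample of the original signal.
#' @return a `detector_config` list.
#' @export
detector_config <- function(slope_window = c(0.03, 0.05),
                            integration_window = 15,
                            smooth_cutoff = 8,
                            refractory = 0.2,
                            accept_coeff = 0.4,
                            theta0_lim_frac = 0.1,
                            theta1_lim_frac = 0.05,
                            init_frac = 0.5,
                            refine_window = 0.05) {
  if (length(slope_window) != 2L || slope_window[1] <= 0 ||
      slope_window[1] >= slope_window[2])
    stop_invalid("`slope_window` must be (min, max) with 0 < min < max")
  if (integration_window < 1) stop_invalid("`integration_window` must be >= 1")
  if (smooth_cutoff <= 0) stop_invalid("`smooth_cutoff` must be > 0")
  structure(list(slope_window = slope_window,
                 integration_window = as.integer(integration_window),
                 smooth_cutoff = smooth_cutoff, refractory = refractory,
                 accept_coeff = accept_coeff,
                 theta0_lim_frac = theta0_lim_frac,
                 theta1_lim_frac = theta1_lim_frac,
                 init_frac = init_frac, refine_window = refine_window),
            class = "detector_config")
}

#' Dual-slope statistic from side-slope extrema
#'
#' The per-sample decision statistic of the dual-slope method:
#' `max(S_L,max - S_R,min, S_R,max - S_L,min)`, where the four arguments
#' are the extreme slopes over the left and right windows of the sample.
#'
#' @param s_l_max,s_l_min,s_r_max,s_r_min slope extrema (mV/sample).
#' @return the statistic (vectorized over its arguments).
#' @export
dual_slope_stat <- function(s_l_max, s_l_min, s_r_max, s_r_min) {
  pmax(s_l_max - s_r_min, s_r_max - s_l_min)
}

#' Dual-slope transform of a signal
#'
#' For every interior sample `i`, two-point slopes `(x[i] - x[i -/+ k]) / k`
#' are computed towards each side for all integer lags `k` in the slope
#' window (0.03-0.05 s by default). The output is the dual-slope
#' statistic of the four side extrema; it is large wherever one side
#' rises steeply and the other falls steeply, i.e. at QRS limbs.
#' Boundary samples without a full window are set to 0.
#'
#' @param x numeric signal (mV).
#' @param fs sampling rate (Hz).
#' @param config a [detector_config()].
#' @return numeric vector, same length as `x`.
#' @export
dual_slope_transform <- function(x, fs, config = detector_config()) {
  n <- length(x)
  kmin <- max(1L, ceiling(config$slope_window[1] * fs))
  kmax <- max(kmin, floor(config$slope_window[2] * fs))
  if (n <= 2L * kmax)
    stop_invalid("signal too short (%d samples) for slope window of %d samples",
                 n, kmax)
  core <- (kmax + 1L):(n - kmax)
  sl_max <- sl_min <- sr_max <- sr_min <- NULL
  for (k in kmin:kmax) {
    sl <- (x[core] - x[core - k]) / k
    sr <- (x[core] - x[core + k]) / k
    if (is.null(sl_max)) {
      sl_max <- sl; sl_min <- sl; sr_max <- sr; sr_min <- sr
    } else {
      sl_max <- pmax(sl_max, sl); sl_min <- pmin(sl_min, sl)
      sr_max <- pmax(sr_max, sr); sr_min <- pmin(sr_min, sr)
    }
  }
  out <- numeric(n)
  out[core] <- dual_slope_stat(sl_max, sl_min, sr_max, sr_min)
  out
}

#' Trailing moving average
#'
#' Causal mean over the trailing `window` values (shorter at the start of
#' the signal), used to smooth the slope transform into single wave peaks.
#'
#' @param values numeric vector.
#' @param window integer window length in samples (>= 1).
#' @return numeric vector of the same length.
#' @export
sliding_integrate <- function(values, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop_invalid("`window` must be >= 1")
  n <- length(values)
  cs <- cumsum(values)
  out <- numeric(n)
  head_n <- seq_len(min(window, n))
  out[head_n] <- cs[head_n] / head_n
  if (n > window)
    out[(window + 1L):n] <- (cs[(window + 1L):n] - cs[1:(n - window)]) / window
  out
}

#' Zero-phase low-pass smoothing
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (zero phase). Merges double peaks closer than about `1/(2 cutoff)` s,
#' which resolves the bimodality of the dual-slope transform.
#'
#' @param values numeric vector.
#' @param fs sampling rate (Hz).
#' @param cutoff cutoff frequency, 0 < cutoff < fs/2.
#' @return filtered vector, same length.
#' @export
lowpass_smooth <- function(values, fs, cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    stop_invalid("`cutoff` must satisfy 0 < cutoff < fs/2")
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  n <- length(values)
  pad <- min(n - 1L, as.integer(ceiling(10 * fs / cutoff)))
  ext <- c(2 * values[1] - values[(pad + 1):2],
           values,
           2 * values[n] - values[(n - 1):(n - pad)])
  out <- as.numeric(signal::filtfilt(bf, ext))
  out[(pad + 1):(pad + n)]
}

#' Adaptive threshold state
#'
#' @param theta0,theta1 current high and low thresholds (theta0 > theta1).
#' @param theta0_lim,theta1_lim floors the thresholds may not fall below.
#' @return a `threshold_state` list.
#' @export
threshold_state <- function(theta0, theta1, theta0_lim = 0, theta1_lim = 0) {
  structure(list(theta0 = theta0, theta1 = theta1,
                 theta0_lim = theta0_lim, theta1_lim = theta1_lim),
            class = "threshold_state")
}

#' One adaptive-threshold update
#'
#' Applies the printed update rules exactly:
#' * if `P > theta0`: `theta0 <- H_ave * 0.65`, `theta1 <- H_ave * 0.35`;
#' * else if `theta1 < P < theta0`:
#'   `theta0 <- theta0 - (P - H_ave) * 0.5`, `theta1 <- 0.35 * P`;
#' * floors: each threshold is clamped up to its limit.
#'
#' Afterwards the ordering `theta0 > theta1` is re-asserted by
#' `theta1 <- min(theta1, 0.99 * theta0)`, since the middle rule can
#' otherwise invert the pair when `theta0` shrinks while `theta1`
#' tracks `P`.
#'
#' @param state a [threshold_state()].
#' @param P current peak height (>= 0).
#' @param H_ave mean height of past accepted peaks.
#' @return the updated state.
#' @export
update_thresholds <- function(state, P, H_ave) {
  th0 <- state$theta0
  th1 <- state$theta1
  if (P > th0) {
    th0 <- H_ave * 0.65
    th1 <- H_ave * 0.35
  } else if (P > state$theta1 && P < state$theta0) {
    th0 <- state$theta0 - (P - H_ave) * 0.5
    th1 <- 0.35 * P
  }
  th0 <- max(th0, state$theta0_lim)
  th1 <- max(th1, state$theta1_lim)
  th1 <- min(th1, 0.99 * th0)
  state$theta0 <- th0
  state$theta1 <- th1
  state
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1)
  which(v[i] > v[i - 1] & v[i] >= v[i + 1] & v[i] > 0) + 1L
}

#' Detect R-peaks with the dual-slope method
#'
#' Pipeline: dual-slope transform, trailing integration, zero-phase
#' low-pass smoothing, candidate local maxima, adaptive two-threshold
#' acceptance. A candidate of height `H_cur` is accepted when it exceeds
#' the low threshold `theta1` and `H_cur > H_ave * accept_coeff`, where
#' `H_ave` is the mean of the last up-to-8 accepted peak heights (seeded
#' from the first 2 s of the transform before any peak is accepted).
#' Both thresholds are updated via [update_thresholds()] for every
#' candidate examined outside the refractory period. Accepted detections
#' are snapped to the largest `|x|` within `refine_window` of the
#' transform peak; results are strictly increasing with gaps of at least
#' the refractory period.
#'
#' The caller is expected to pass a denoised signal. All decision
#' quantities are ratios of transform heights, so detections are
#' invariant to positive amplitude scaling.
#'
#' @param x numeric signal (mV), at least 1 s long.
#' @param fs sampling rate (Hz).
#' @param config a [detector_config()].
#' @return integer vector of R-peak sample indices (1-based).
#' @export
detect_qrs <- function(x, fs, config = detector_config()) {
  n <- length(x)
  if (n < fs) stop_invalid("signal shorter than 1 s")
  tr <- dual_slope_transform(x, fs, config)
  tr <- sliding_integrate(tr, config$integration_window)
  tr <- lowpass_smooth(tr, fs, config$smooth_cutoff)
  tr[tr < 0] <- 0

  cand <- local_maxima(tr)
  if (!length(cand)) return(integer(0))

  init_n <- min(n, max(3L, as.integer(2 * fs)))
  seed_h <- max(tr[seq_len(init_n)]) * config$init_frac
  if (seed_h <= 0) return(integer(0))
  state <- threshold_state(theta0 = 0.65 * seed_h, theta1 = 0.35 * seed_h,
                           theta0_lim = config$theta0_lim_frac * seed_h,
                           theta1_lim = config$theta1_lim_frac * seed_h)
  history <- numeric(0)
  refr <- as.integer(round(config$refractory * fs))
  half <- as.integer(round(config$refine_window * fs))
  last_acc <- -Inf
  accepted <- integer(0)

  for (j in cand) {
    if (j - last_acc < refr) next
    h <- tr[j]
    h_ave <- if (length(history)) mean(history) else seed_h
    if (qrs_accept(h, state$theta1, h_ave, config$accept_coeff)) {
      accepted <- c(accepted, j)
      last_acc <- j
      history <- c(history, h)
      if (length(history) > 8L) history <- history[-1L]
    }
    state <- update_thresholds(state, P = h,
                               H_ave = if (length(history)) mean(history) else seed_h)
  }
  if (!length(accepted)) return(integer(0))

  refined <- vapply(accepted, function(j) {
    lo <- max(1L, j - half); hi <- min(n, j + half)
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory gap after refinement (keep the earlier peak)
  keep <- logical(length(refined))
  last <- -Inf
  for (i in seq_along(refined)) {
    if (refined[i] - last >= refr) {
      keep[i] <- TRUE
      last <- refined[i]
    }
  }
  refined[keep]
}

#' Detector configuration scaled to an expected rhythm rate
#'
#' The default configuration assumes cycle lengths of sinus rhythm. When
#' the expected rate is extreme (supraventricular tachycardia, atrial
#' fibrillation at several hundred BPM), three parameters must shrink
#' with the expected minimum RR interval so that per-beat transform
#' responses do not straddle or merge with the neighbouring complex:
#' the slope window is capped at 20-30% of the minimum RR, the
#' integration window drops to the short end of its range, the smoothing
#' cutoff moves to the top of its range, and the refractory period is
#' set to half the minimum RR.
#'
#' @param max_bpm largest expected instantaneous rate (beats per minute).
#' @param ... overrides forwarded to [detector_config()].
#' @return a `detector_config`.
#' @export
detector_config_for_rate <- function(max_bpm, ...) {
  min_rr <- 60 / max_bpm
  fast <- min_rr < 0.25
  args <- list(
    slope_window = c(min(0.03, 0.2 * min_rr), min(0.05, 0.3 * min_rr)),
    integration_window = if (fast) 10 else 15,
    smooth_cutoff = if (fast) 10 else 8,
    refractory = min(0.2, 0.5 * min_rr))
  args <- modifyList(args, list(...))
  do.call(detector_config, args)
}

#' Peak acceptance rule
#'
#' A candidate of height `h_cur` is kept when it exceeds the adaptive low
#' threshold and `h_cur > h_ave * coeff` (the mean-of-past-peaks rule
#' with coefficient 0.4).
#'
#' @param h_cur candidate peak height.
#' @param theta1 current low threshold.
#' @param h_ave mean height of the past accepted peaks.
#' @param coeff acceptance coefficient (default 0.4).
#' @return logical.
#' @export
qrs_accept <- function(h_cur, theta1, h_ave, coeff = 0.4) {
  h_cur > theta1 & h_cur > h_ave * coeff
}
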