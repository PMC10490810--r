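#' Beat morphology templates
#'
#' Each beat is modelled as a sum of Gaussian sub-waves (P, Q, R, S, T),
#' a standard device for synthetic ECG: the R-peak location is analytic
#' and morphology is controlled per sub-wave. Templates:
#'
#' * `N` - narrow QRS (~0.08 s), upright P and T.
#' * `L`, `R` - bundle-branch-block beats: widened QRS (0.12-0.14 s) with a
#'   slurred secondary deflection after (L) or a late secondary R' peak (R);
#'   stylized stand-ins for the clinical morphologies.
#' * `V` - ventricular premature beat: QRS duration >= 0.12 s, no P wave,
#'   T polarity inverted relative to the QRS.
#' * `A` - atrial premature beat: near-normal QRS, flattened early P.
#' * `F` - fusion beat: morphology intermediate between N and V, QRS
#'   moderately widened, damped T.
#'
#' @param label one of "N", "L", "R", "V", "A", "F".
#' @return a `beat_template`: list with `waves` (data.frame of
#'   amplitude mV / center s relative to R / width s), `qrs_duration` (s)
#'   and `label`.
#' @export
beat_template <- function(label = c("N", "L", "R", "V", "A", "F")) {
  label <- match.arg(label)
  w <- function(wave, amp, center, width)
    data.frame(wave = wave, amp = amp, center = center, width = width,
               stringsAsFactors = FALSE)
  waves <- switch(label,
    N = rbind(w("P", 0.12, -0.20, 0.025),
              w("Q", -0.10, -0.035, 0.010),
              w("R", 1.00, 0.00, 0.012),
              w("S", -0.18, 0.035, 0.010),
              w("T", 0.30, 0.27, 0.055)),
    L = rbind(w("P", 0.10, -0.22, 0.025),
              w("Q", -0.05, -0.050, 0.012),
              w("R", 0.95, 0.00, 0.024),
              w("R2", 0.40, 0.055, 0.030),  # slurred, notched terminal force
              w("T", -0.25, 0.30, 0.060)),
    R = rbind(w("P", 0.10, -0.22, 0.025),
              w("Q", -0.12, -0.045, 0.012),
              w("R", 0.90, 0.00, 0.014),
              w("S", -0.35, 0.040, 0.018),
              w("R2", 0.50, 0.075, 0.022),  # late R' of the rsR' pattern
              w("T", 0.22, 0.30, 0.060)),
    V = rbind(w("R", 1.25, 0.00, 0.035),
              w("S", -0.45, 0.060, 0.028),
              w("T", -0.55, 0.32, 0.070)),
    A = rbind(w("P", 0.06, -0.16, 0.035),
              w("Q", -0.09, -0.035, 0.010),
              w("R", 0.92, 0.00, 0.012),
              w("S", -0.16, 0.035, 0.010),
              w("T", 0.26, 0.26, 0.055)),
    F = rbind(w("P", 0.05, -0.20, 0.030),
              w("R", 1.05, 0.00, 0.026),
              w("S", -0.30, 0.050, 0.022),
              w("T", 0.12, 0.30, 0.065)))
  qrs <- switch(label, N = 0.08, L = 0.13, R = 0.14, V = 0.14, A = 0.08,
                F = 0.115)
  structure(list(waves = waves, qrs_duration = qrs, label = label),
            class = "beat_template")
}

#' Rhythm presets
#'
#' Named (rate range, beat class) presets used by [simulate_ecg()].
#' Tachyarrhythmia rate ranges follow the clinical figures: atrial
#' tachycardia 150-200 BPM, supraventricular tachycardia 160-220 BPM,
#' atrial fibrillation 300-600 BPM. The "normal" preset is 60-100 BPM
#' (the resting sinus range). Bundle-branch-block and ectopic presets
#' reuse the sinus range with the corresponding beat template.
#'
#' @param name preset name; `rhythm_presets()` lists all of them.
#' @return a `rhythm_preset`: list with `name`, `rate_range` (BPM) and
#'   `template_label`.
#' @export
rhythm_preset <- function(name) {
  tab <- list(
    normal              = list(rate = c(60, 100),  label = "N"),
    atrial_tachycardia  = list(rate = c(150, 200), label = "N"),
    svt                 = list(rate = c(160, 220), label = "N"),
    afib                = list(rate = c(300, 600), label = "N"),
    lbbb                = list(rate = c(60, 100),  label = "L"),
    rbbb                = list(rate = c(60, 100),  label = "R"),
    pvc                 = list(rate = c(60, 100),  label = "V"),
    apb                 = list(rate = c(60, 100),  label = "A"),
    fusion              = list(rate = c(60, 100),  label = "F"))
  if (!name %in% names(tab))
    stop_invalid("unknown rhythm preset '%s' (see rhythm_presets())", name)
  p <- tab[[name]]
  structure(list(name = name, rate_range = p$rate, template_label = p$label),
            class = "rhythm_preset")
}

#' @rdname rhythm_preset
#' @export
rhythm_presets <- function() {
  c("normal", "atrial_tachycardia", "svt", "afib", "lbbb", "rbbb", "pvc",
    "apb", "fusion")
}

#' Additive-noise specification
#'
#' Describes the three interference sources mixed into a clean trace:
#' broadband Gaussian (EMG-like) noise, a powerline sinusoid, and
#' low-frequency baseline wander.
#'
#' @param gaussian_sd standard deviation of the white noise, mV.
#' @param powerline_amp,powerline_freq amplitude (mV) and frequency (Hz)
#'   of the mains interference sinusoid.
#' @param baseline_amp,baseline_freq amplitude (mV) and frequency (Hz) of
#'   the baseline wander sinusoid.
#' @param seed integer seed making the Gaussian component reproducible.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(gaussian_sd = 0, powerline_amp = 0, powerline_freq = 50,
                       baseline_amp = 0, baseline_freq = 0.3, seed = 1L) {
  amps <- c(gaussian_sd, powerline_amp, baseline_amp)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop_invalid("noise amplitudes must be finite and >= 0")
  structure(list(gaussian_sd = gaussian_sd, powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq, baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq, seed = as.integer(seed)),
            class = "noise_spec")
}

gaussian_wave <- function(t, amp, center, width) {
  amp * exp(-((t - center)^2) / (2 * width^2))
}

#' Simulate an annotated single-lead ECG record
#'
#' Lays beats on a timeline segment by segment. Within a segment the
#' inter-beat (RR) interval of each beat is drawn uniformly from the
#' preset's rate range, independently per beat. Per-beat amplitude and
#' width jitter gives intra-class variability. For short RR intervals the
#' P and T sub-waves are compressed towards the QRS (scale factor
#' `min(1, RR / 0.7)`) so beats do not smear into their neighbours at
#' tachyarrhythmia rates; the QRS itself is never rescaled. The true
#' R-peak sample of every synthesized beat is recorded as an annotation.
#'
#' @param presets either a single preset name, a `rhythm_preset`, or a
#'   list of `list(preset = <name or rhythm_preset>, duration = <s>)`
#'   segments laid end to end.
#' @param duration segment duration in seconds (used when `presets` is a
#'   single preset).
#' @param fs sampling rate, Hz (>= 200; 360 Hz default, the MIT-BIH rate).
#' @param noise a [noise_spec()] added after synthesis (zero by default).
#' @param seed integer seed controlling RR draws, jitter and noise.
#' @param amp_jitter,width_jitter relative s.d. of per-beat lognormal-ish
#'   (multiplicative, clamped) variation of sub-wave amplitudes / widths.
#' @return an [ecg_record()] with ground-truth annotations.
#' @export
simulate_ecg <- function(presets, duration = 30, fs = 360,
                         noise = noise_spec(), seed = 1L,
                         amp_jitter = 0.08, width_jitter = 0.04) {
  if (!is.numeric(fs) || fs < 200)
    stop_invalid("`fs` must be >= 200 Hz")
  segs <- normalize_presets(presets, duration)
  total <- sum(vapply(segs, function(s) s$duration, numeric(1)))
  if (!is.finite(total) || total <= 2)
    stop_invalid("total duration must be > 2 s")
  set.seed(as.integer(seed))

  n <- round(total * fs)
  x <- numeric(n)
  tgrid <- (seq_len(n) - 1) / fs
  ann_sample <- integer(0)
  ann_symbol <- character(0)

  t0 <- 0          # segment start time
  t_beat <- 0.35   # first R-peak time
  for (seg in segs) {
    preset <- seg$preset
    t_end <- t0 + seg$duration
    tmpl <- beat_template(preset$template_label)
    while (t_beat < t_end - 0.05) {
      rr <- 60 / runif(1, preset$rate_range[1], preset$rate_range[2])
      comp <- min(1, rr / 0.7)  # P/T compression at short cycles
      wv <- tmpl$waves
      keep_scale <- wv$wave %in% c("P", "T")
      center <- ifelse(keep_scale, wv$center * comp, wv$center)
      width <- ifelse(keep_scale, wv$width * comp, wv$width)
      amp <- wv$amp * pmax(0.5, 1 + rnorm(nrow(wv), 0, amp_jitter))
      width <- width * pmax(0.5, 1 + rnorm(nrow(wv), 0, width_jitter))
      # keep the R sub-wave dominant despite jitter
      ir <- which(wv$wave == "R")
      amp[ir] <- wv$amp[ir] * pmax(0.8, 1 + rnorm(1, 0, amp_jitter / 2))
      r_idx <- round(t_beat * fs) + 1L
      if (r_idx >= 1L && r_idx <= n) {
        lo <- max(1L, r_idx - as.integer(0.6 * fs))
        hi <- min(n, r_idx + as.integer(0.8 * fs))
        tt <- tgrid[lo:hi] - (r_idx - 1L) / fs
        acc <- numeric(hi - lo + 1L)
        for (j in seq_len(nrow(wv)))
          acc <- acc + gaussian_wave(tt, amp[j], center[j], width[j])
        x[lo:hi] <- x[lo:hi] + acc
        ann_sample <- c(ann_sample, r_idx)
        ann_symbol <- c(ann_symbol, tmpl$label)
      }
      t_beat <- t_beat + rr
    }
    t0 <- t_end
  }
  ord <- order(ann_sample)
  rec <- ecg_record(x, fs,
                    record_id = paste0("sim-", segs[[1]]$preset$name),
                    annotations = data.frame(sample = ann_sample[ord],
                                             symbol = ann_symbol[ord],
                                             stringsAsFactors = FALSE))
  if (noise$gaussian_sd > 0 || noise$powerline_amp > 0 || noise$baseline_amp > 0)
    rec <- add_noise(rec, noise)
  rec
}

normalize_presets <- function(presets, duration) {
  as_preset <- function(p) if (inherits(p, "rhythm_preset")) p else rhythm_preset(p)
  if (is.character(presets) || inherits(presets, "rhythm_preset")) {
    if (!is.numeric(duration) || duration <= 0)
      stop_invalid("`duration` must be a positive number of seconds")
    return(list(list(preset = as_preset(presets), duration = duration)))
  }
  lapply(presets, function(s) {
    if (is.null(s$preset) || is.null(s$duration) || s$duration <= 0)
      stop_invalid("each segment needs a `preset` and a positive `duration`")
    list(preset = as_preset(s$preset), duration = s$duration)
  })
}

#' Add interference to a record
#'
#' Output samples are `clean + gaussian + powerline + baseline wander`;
#' annotations are untouched. The Gaussian draw is governed by
#' `noise$seed`, so a fixed spec yields a byte-identical noise trace.
#'
#' @param record an [ecg_record()].
#' @param noise a [noise_spec()].
#' @return the noisy record.
#' @export
add_noise <- function(record, noise) {
  stopifnot(inherits(record, "ecg_record"), inherits(noise, "noise_spec"))
  n <- length(record$samples)
  t <- (seq_len(n) - 1) / record$fs
  extra <- numeric(n)
  if (noise$gaussian_sd > 0) {
    set.seed(noise$seed)
    extra <- extra + rnorm(n, 0, noise$gaussian_sd)
  }
  if (noise$powerline_amp > 0)
    extra <- extra + noise$powerline_amp * sin(2 * pi * noise$powerline_freq * t)
  if (noise$baseline_amp > 0)
    extra <- extra + noise$baseline_amp * sin(2 * pi * noise$baseline_freq * t)
  record$samples <- record$samples + extra
  record
}

#' Signal-to-noise ratio in decibels
#'
#' `10 log10( sum(reference^2) / sum((reference - test)^2) )`. Identical
#' inputs give `Inf` (zero residual power); a zero-power reference is an
#' error.
#'
#' @param reference,test equal-length numeric vectors.
#' @return SNR in dB.
#' @export
snr_db <- function(reference, test) {
  check_numeric_vector(reference, "reference")
  check_equal_length(reference, test)
  ps <- sum(reference^2)
  if (ps == 0) stop_invalid("reference signal has zero power")
  pn <- sum((reference - test)^2)
  if (pn == 0) return(Inf)
  10 * log10(ps / pn)
}
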