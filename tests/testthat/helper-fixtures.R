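# Shared, lazily built fixtures. Everything is generated in code from
# fixed seeds; heavier objects are cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

fx_beat_set <- function(n = 120, seed = 42, noise = 0.05) {
  fx_cached(sprintf("bs_%d_%d_%g", n, seed, noise),
            function() synthetic_beat_set(n, noise_sd = noise, seed = seed))
}

fx_features <- function(n = 120, seed = 42, noise = 0.05) {
  fx_cached(sprintf("ft_%d_%d_%g", n, seed, noise),
            function() beat_features(fx_beat_set(n, seed, noise)))
}

fx_record <- function(preset = "normal", duration = 30, seed = 1,
                      noise_sd = 0) {
  fx_cached(sprintf("rec_%s_%g_%d_%g", preset, duration, seed, noise_sd),
            function() simulate_ecg(preset, duration = duration, seed = seed,
                                    noise = noise_spec(gaussian_sd = noise_sd,
                                                       seed = seed)))
}

# detector quality against ground truth, with the rate-aware configuration
fx_detector_scores <- function(preset, seed, noise_sd = 0, duration = 30) {
  rec <- simulate_ecg(preset, duration = duration, seed = seed,
                      noise = noise_spec(gaussian_sd = noise_sd, seed = seed))
  x <- if (noise_sd > 0) wavelet_denoise(rec$samples, rec$fs) else rec$samples
  cfg <- detector_config_for_rate(rhythm_preset(preset)$rate_range[2])
  det <- detect_qrs(x, rec$fs, cfg)
  m <- match_peaks(rec$annotations$sample, det, round(0.025 * rec$fs))
  list(se = m$tp / (m$tp + m$fn), ppv = m$tp / (m$tp + m$fp),
       n = nrow(rec$annotations))
}
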