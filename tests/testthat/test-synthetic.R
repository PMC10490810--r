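test_that("a fixed-rate record carries one annotation per synthesized beat", {
  # 60-100 BPM preset collapsed to a fixed rate via a degenerate range
  p <- rhythm_preset("normal")
  p$rate_range <- c(60, 60)
  rec <- simulate_ecg(p, duration = 10, fs = 360, seed = 1)
  # first beat at 0.35 s, then exactly 1-s steps until 10 s
  expect_equal(nrow(rec$annotations), 10)
  expect_equal(length(rec$samples), 3600)
  expect_true(all(diff(rec$annotations$sample) == 360))
})

test_that("atrial fibrillation rates stay inside 300-600 BPM", {
  rec <- simulate_ecg("afib", duration = 10, seed = 7)
  inst <- 60 / (diff(rec$annotations$sample) / rec$fs)
  expect_true(all(inst >= 300 - 1e-6 & inst <= 600 + 1e-6))
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_ecg("pvc", duration = 8, seed = 11,
                    noise = noise_spec(gaussian_sd = 0.05, seed = 3))
  b <- simulate_ecg("pvc", duration = 8, seed = 11,
                    noise = noise_spec(gaussian_sd = 0.05, seed = 3))
  expect_identical(a$samples, b$samples)
  expect_identical(a$annotations, b$annotations)
})

test_that("invalid generator parameters are rejected", {
  expect_error(simulate_ecg("normal", duration = -1), "duration")
  expect_error(simulate_ecg("normal", duration = 10, fs = 100), "fs")
  expect_error(simulate_ecg("normal", duration = 1), "duration")
  expect_error(rhythm_preset("nope"), "unknown")
  expect_error(noise_spec(gaussian_sd = -1), "amplitudes")
})

test_that("every annotated R-peak is a local extremum of the clean trace", {
  for (preset in c("normal", "lbbb", "rbbb", "pvc", "afib")) {
    rec <- simulate_ecg(preset, duration = 15, seed = 5)
    x <- abs(rec$samples)
    n <- length(x)
    for (r in rec$annotations$sample) {
      lo <- max(1, r - 5); hi <- min(n, r + 5)
      peak_at <- lo + which.max(x[lo:hi]) - 1
      expect_lte(abs(peak_at - r), 2)
    }
  }
})

test_that("add_noise with zero amplitudes is the identity", {
  rec <- fx_record("normal", 30, 1)
  out <- add_noise(rec, noise_spec())
  expect_identical(out$samples, rec$samples)
  expect_identical(out$annotations, rec$annotations)
})

test_that("gaussian noise has the requested standard deviation", {
  rec <- fx_record("normal", 30, 1)
  out <- add_noise(rec, noise_spec(gaussian_sd = 0.1, seed = 9))
  d <- out$samples - rec$samples
  expect_equal(sd(d), 0.1, tolerance = 0.1)
})

test_that("powerline noise shows a dominant 50 Hz spectral peak", {
  rec <- fx_record("normal", 30, 1)
  out <- add_noise(rec, noise_spec(powerline_amp = 0.05, powerline_freq = 50))
  d <- out$samples - rec$samples
  spec <- Mod(fft(d))[seq_len(length(d) %/% 2)]
  freq <- (seq_along(spec) - 1) * rec$fs / length(d)
  expect_equal(freq[which.max(spec)], 50, tolerance = 0.5)
})

test_that("snr_db matches hand-evaluated cases and edge contracts", {
  expect_identical(snr_db(c(1, 2, 3), c(1, 2, 3)), Inf)
  expect_equal(snr_db(c(1, 1, 1, 1), c(0, 0, 0, 0)), 0)
  expect_equal(snr_db(c(2, 2), c(1, 1)), 10 * log10(8 / 2))
  expect_error(snr_db(c(0, 0), c(1, 1)), "zero power")
  expect_error(snr_db(1:3, 1:4), "equal length")
})

test_that("snr against the clean record decreases as noise grows", {
  rec <- fx_record("normal", 30, 1)
  snrs <- vapply(c(0.05, 0.1, 0.2), function(s) {
    noisy <- add_noise(rec, noise_spec(gaussian_sd = s, seed = 4))
    snr_db(rec$samples, noisy$samples)
  }, numeric(1))
  expect_true(all(is.finite(snrs)))
  expect_true(all(diff(snrs) < 0))
})

test_that("beat templates satisfy their morphology constraints", {
  for (lab in c("N", "L", "R")) {
    tm <- beat_template(lab)
    ir <- which(tm$waves$wave == "R")
    expect_equal(which.max(abs(tm$waves$amp)), ir)
  }
  v <- beat_template("V")
  expect_gte(v$qrs_duration, 0.12)
  expect_false("P" %in% v$waves$wave)
  r_pol <- sign(v$waves$amp[v$waves$wave == "R"])
  t_pol <- sign(v$waves$amp[v$waves$wave == "T"])
  expect_equal(t_pol, -r_pol)
  expect_true(all(beat_template("F")$waves$width > 0))
})
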