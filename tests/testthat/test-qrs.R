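test_that("the dual-slope statistic matches hand-evaluated cases", {
  expect_equal(dual_slope_stat(2.0, -2.0, 1.5, -1.0),
               max(2.0 - (-1.0), 1.5 - (-2.0)))
  expect_equal(dual_slope_stat(2.0, -2.0, 1.5, -1.0), 3.5)
  # symmetric peak: both sides share extrema, statistic collapses to s - m
  s <- 1.7; m <- -0.4
  expect_equal(dual_slope_stat(s, m, s, m), s - m)
})

test_that("the dual-slope transform is zero on constants and at borders", {
  x <- rep(2, 200)
  out <- dual_slope_transform(x, 360)
  expect_true(all(out == 0))
  y <- rnorm(200)
  out <- dual_slope_transform(y, 360)
  kmax <- floor(0.05 * 360)
  expect_true(all(out[seq_len(kmax)] == 0))
  expect_true(all(out[(200 - kmax + 1):200] == 0))
  expect_error(dual_slope_transform(rnorm(30), 360), "too short")
})

test_that("sliding integration matches the hand-evaluated window means", {
  expect_equal(sliding_integrate(c(0, 0, 3, 0, 0), 3), c(0, 0, 1, 1, 1))
  x <- rnorm(50)
  expect_equal(sliding_integrate(x, 1), x)
  expect_equal(sliding_integrate(rep(4, 20), 7), rep(4, 20))
  expect_error(sliding_integrate(1:5, 0), "window")
})

test_that("low-pass smoothing has unit DC gain, attenuates, and merges", {
  fs <- 360
  expect_equal(lowpass_smooth(rep(1, 400), fs, 8), rep(1, 400),
               tolerance = 1e-6)
  t <- (0:1999) / fs
  s <- sin(2 * pi * 32 * t)  # 4x the 8 Hz cutoff
  out <- lowpass_smooth(s, fs, 8)
  core <- 500:1500
  expect_lt(max(abs(out[core])), 0.1)
  # bimodality merge: two impulses 2 samples apart become one local max
  x <- numeric(400); x[c(200, 202)] <- 1
  sm <- lowpass_smooth(x, fs, 8)
  peaks <- which(diff(sign(diff(sm))) == -2) + 1
  peaks <- peaks[sm[peaks] > 0.5 * max(sm)]
  expect_equal(length(peaks), 1)
  expect_error(lowpass_smooth(rnorm(10), fs, 200), "cutoff")
})

test_that("threshold updates match the printed rules on worked examples", {
  st <- threshold_state(0.5, 0.2, theta0_lim = 0, theta1_lim = 0)
  up <- update_thresholds(st, P = 2.0, H_ave = 1.0)
  expect_equal(up$theta0, 0.65)
  expect_equal(up$theta1, 0.35)

  st <- threshold_state(1.0, 0.2, theta0_lim = 0, theta1_lim = 0)
  up <- update_thresholds(st, P = 0.6, H_ave = 0.8)
  expect_equal(up$theta0, 1.0 - (0.6 - 0.8) * 0.5)  # rule 2 raises theta0
  expect_equal(up$theta1, 0.35 * 0.6)

  st <- threshold_state(0.5, 0.2, theta0_lim = 0.1, theta1_lim = 0.05)
  up <- update_thresholds(st, P = 2.0, H_ave = 0.01)  # drives both below floor
  expect_equal(up$theta0, 0.1)
  expect_equal(up$theta1, 0.05)
})

test_that("threshold updates agree with a literal transcription oracle", {
  # independent, line-by-line transcription of the printed update rules
  oracle <- function(theta0, theta1, lim0, lim1, P, H_ave) {
    if (P > theta0) {
      t0 <- H_ave * 0.65
      t1 <- H_ave * 0.35
    } else if (theta1 < P && P < theta0) {
      t0 <- theta0 - (P - H_ave) * 0.5
      t1 <- 0.35 * P
    } else {
      t0 <- theta0
      t1 <- theta1
    }
    if (t0 < lim0) t0 <- lim0
    if (t1 < lim1) t1 <- lim1
    if (t1 > 0.99 * t0) t1 <- 0.99 * t0
    c(t0, t1)
  }
  set.seed(99)
  for (i in seq_len(1000)) {
    th0 <- runif(1, 0, 2); th1 <- runif(1, 0, th0)
    l0 <- runif(1, 0, 0.3); l1 <- runif(1, 0, l0)
    P <- runif(1, 0, 3); H <- runif(1, 0, 2)
    st <- update_thresholds(threshold_state(th0, th1, l0, l1), P, H)
    expect_equal(c(st$theta0, st$theta1), oracle(th0, th1, l0, l1, P, H),
                 tolerance = 1e-12)
  }
})

test_that("the acceptance rule keeps 0.41x and rejects 0.39x of the mean", {
  h_ave <- mean(rep(1.3, 8))  # eight equal past peaks
  theta1 <- 0.35 * h_ave
  expect_true(qrs_accept(0.41 * h_ave, theta1, h_ave))
  expect_false(qrs_accept(0.39 * h_ave, theta1, h_ave))
})

test_that("all beats of a clean sinus record are found within 25 ms", {
  rec <- fx_record("normal", 30, 1)
  det <- detect_qrs(rec$samples, rec$fs)
  expect_equal(length(det), nrow(rec$annotations))
  expect_true(all(abs(det - rec$annotations$sample) <= 0.025 * rec$fs))
  expect_true(all(diff(det) >= 0.2 * rec$fs))
})

test_that("a flat line yields no detections and short input errors", {
  expect_identical(detect_qrs(rep(0.3, 2000), 360), integer(0))
  expect_error(detect_qrs(rnorm(100), 360), "shorter")
})

test_that("detections are invariant to positive amplitude scaling", {
  rec <- fx_record("normal", 30, 1)
  base <- detect_qrs(rec$samples, rec$fs)
  for (k in c(0.05, 3, 40)) {
    expect_identical(detect_qrs(k * rec$samples, rec$fs), base)
  }
})
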