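# CHROM extraction, detrending, band-pass filtering and BPM estimation.

fps <- 30

test_that("CHROM output is ~zero for constant channel means", {
  n <- 150
  s <- chrom_pulse(rep(120, n), rep(150, n), rep(90, n), fps)
  expect_lt(max(abs(s)), 1e-8)
})

test_that("CHROM matches an independently coded loop-based oracle", {
  set.seed(11)
  n <- 150
  tt <- (seq_len(n) - 1) / fps
  r <- 120 + 0.5 * sin(2 * pi * 1.1 * tt) + rnorm(n, 0, 0.05)
  g <- 150 + 1.2 * sin(2 * pi * 1.1 * tt + 0.3) + rnorm(n, 0, 0.05)
  b <- 90 + 0.3 * cos(2 * pi * 1.1 * tt) + rnorm(n, 0, 0.05)

  # oracle: same definition, written as plain loops
  L <- 48L
  half <- L %/% 2L
  run_std <- function(x) {
    vapply(seq_len(n), function(t) {
      x[t] / mean(x[max(1, t - half):min(n, t + half)])
    }, numeric(1))
  }
  bf <- signal::butter(4, c(0.7, 4) / (fps / 2), "pass")
  xf <- as.numeric(signal::filtfilt(
    bf, 3 * run_std(r) - 2 * run_std(g)))
  yf <- as.numeric(signal::filtfilt(
    bf, 1.5 * run_std(r) + run_std(g) - 1.5 * run_std(b)))
  starts <- seq(1L, n - L + 1L, by = half)
  if (max(starts) + L - 1L < n) starts <- c(starts, n - L + 1L)
  hann <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  num <- numeric(n)
  den <- numeric(n)
  for (s in starts) {
    idx <- s:(s + L - 1L)
    sw <- xf[idx] - (sd(xf[idx]) / sd(yf[idx])) * yf[idx]
    sw <- sw - mean(sw)
    num[idx] <- num[idx] + hann * sw
    den[idx] <- den[idx] + hann
  }
  want <- num / pmax(den, 1e-12)

  got <- chrom_pulse(r, g, b, fps)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("G-channel modulation yields a dominant peak at its frequency", {
  n <- 300
  tt <- (seq_len(n) - 1) / fps
  g <- 150 * (1 + 0.01 * sin(2 * pi * 1.2 * tt))
  s <- chrom_pulse(rep(120, n), g, rep(90, n), fps)
  est <- estimate_bpm(s, fps)
  expect_lt(abs(est$bpm - 72), 1)
})

test_that("smoothness-priors detrending removes trends, keeps oscillations", {
  n <- 300
  tt <- (seq_len(n) - 1) / fps
  ramp <- 5 * tt
  resid <- detrend_normalize(ramp, normalize = FALSE)
  expect_lt(max(abs(resid)) / max(ramp), 0.02)  # trend fully removed

  clean <- sin(2 * pi * 1.2 * tt)
  out <- detrend_normalize(clean + ramp)
  expect_gt(cor(out, clean), 0.99)
  expect_lt(abs(mean(out)), 1e-6 * sd(out) + 1e-12)
  expect_equal(sd(out), 1)

  expect_error(detrend_normalize(rep(3, n)), class = "pg_degenerate_error")
})

test_that("detrending acts only on low frequencies at the default prior", {
  n <- 300
  tt <- (seq_len(n) - 1) / fps
  fast <- sin(2 * pi * 1.2 * tt)       # pulse-band content is preserved
  expect_gt(cor(detrend_normalize(fast), fast), 0.99)
  slow <- sin(2 * pi * 0.05 * tt)      # respiration-scale drift is removed
  resid <- detrend_normalize(slow, normalize = FALSE)
  expect_lt(sd(resid), 0.05 * sd(slow))
})

test_that("band-pass gain matches the analytic Butterworth magnitude", {
  # independent oracle: analog prototype response at prewarped frequencies
  cfg <- bandpass_config()
  oracle <- function(f) {
    wl <- 2 * fps * tan(pi * cfg$low_cut / fps)
    wh <- 2 * fps * tan(pi * cfg$high_cut / fps)
    om <- 2 * fps * tan(pi * f / fps)
    1 / (1 + ((om^2 - wl * wh) / (om * (wh - wl)))^(2 * cfg$order))
  }
  f <- seq(0.05, 14.5, length.out = 100)
  expect_lt(max(abs(bandpass_response(f, fps, cfg) - oracle(f))), 1e-6)
})

test_that("band-pass attenuates DC and out-of-band tones, passes mid-band", {
  n <- 600
  tt <- (seq_len(n) - 1) / fps
  mid <- 150:450
  expect_lt(max(abs(bandpass(rep(5, n), fps))[mid]), 0.01)

  gain_at <- function(f) {
    y <- bandpass(sin(2 * pi * f * tt), fps)
    max(abs(y[mid]))
  }
  expect_gt(gain_at(1.5), 0.95)
  expect_lt(gain_at(1.5), 1.05)
  expect_lt(gain_at(6), 0.2)
  expect_error(bandpass(rnorm(100), fps = 7), class = "pg_config_error")
})

test_that("spectral BPM estimation finds the in-band peak times 60", {
  n <- 900
  tt <- (seq_len(n) - 1) / fps
  x <- sin(2 * pi * 1.2 * tt)
  est <- estimate_bpm(x, fps)
  expect_lt(abs(est$bpm - 72), 0.25)  # 1.2 Hz on the padded grid

  # strong out-of-band 0.5 Hz tone is ignored in favor of the in-band 1.0 Hz
  x2 <- 3 * sin(2 * pi * 0.5 * tt) + sin(2 * pi * 1.0 * tt)
  expect_lt(abs(estimate_bpm(x2, fps)$bpm - 60), 0.5)

  # positive rescaling leaves the estimate untouched
  expect_equal(estimate_bpm(17.3 * x, fps)$bpm, est$bpm)

  expect_error(estimate_bpm(x[1:100], fps), class = "pg_length_error")
})

test_that("BPM estimates never leave [42, 240], even on pure noise", {
  for (s in 1:10) {
    set.seed(s)
    est <- estimate_bpm(rnorm(300), fps)
    expect_gte(est$bpm, 42)
    expect_lte(est$bpm, 240)
  }
})

test_that("BPM trace is frame-aligned and follows frequency changes", {
  n <- 300
  tt <- (seq_len(n) - 1) / fps
  x <- sin(2 * pi * 1.2 * tt)
  tr <- bpm_trace(x, fps)
  expect_length(tr, n)
  expect_lt(max(abs(tr - 72)), 1.5)  # stationary tone: constant trace

  # frequency step 1.0 -> 1.5 Hz: trace moves from 60 toward 90 bpm
  x2 <- c(sin(2 * pi * 1.0 * tt[1:150]),
          sin(2 * pi * 1.5 * tt[151:300]))
  tr2 <- bpm_trace(x2, fps)
  expect_lt(tr2[1], 66)
  expect_gt(tr2[n], 84)
  expect_error(bpm_trace(x[1:50], fps), class = "pg_length_error")
})
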