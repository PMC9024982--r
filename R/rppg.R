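# Pulse extraction: CHROM chrominance projection, smoothness-priors
# detrending, Butterworth band-pass, Hann-windowed spectral BPM estimation.

#' Band-pass filter configuration
#'
#' Defaults bracket the physiological pulse band: 0.7 Hz (42 bpm) to 4.0 Hz
#' (240 bpm), Butterworth of order 4, applied forward-backward (zero phase).
#'
#' @param low_cut,high_cut Cutoff frequencies in Hz.
#' @param order Butterworth order N (per band edge).
#' @param zero_phase Apply forward-backward (`filtfilt`) filtering.
#' @return A list of class `bandpass_config`.
#' @export
bandpass_config <- function(low_cut = 0.7, high_cut = 4.0, order = 4,
                            zero_phase = TRUE) {
  if (!(low_cut > 0 && low_cut < high_cut)) {
    stop_pg("Need 0 < low_cut < high_cut.", "pg_config_error")
  }
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 zero_phase = zero_phase), class = "bandpass_config")
}

butter_coefficients <- function(fps, cfg) {
  if (cfg$high_cut >= fps / 2) {
    stop_pg("high_cut must be below the Nyquist frequency.", "pg_config_error")
  }
  signal::butter(cfg$order, c(cfg$low_cut, cfg$high_cut) / (fps / 2),
                 type = "pass")
}

#' Butterworth band-pass filtering
#'
#' Applies the configured digital Butterworth band-pass; with
#' `zero_phase = TRUE` the filter is run forward and backward so the phase
#' response is zero and the magnitude response is squared.
#'
#' @param x Numeric signal sampled at `fps`.
#' @param fps Sampling rate in Hz.
#' @param cfg A [bandpass_config()].
#' @return The filtered signal (numeric, same length).
#' @export
bandpass <- function(x, fps, cfg = bandpass_config()) {
  bf <- butter_coefficients(fps, cfg)
  if (cfg$zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Magnitude response of the band-pass filter
#'
#' Evaluates `|H(e^{j omega})|^2` (or `|H|`) of the digital filter that
#' [bandpass()] applies, by direct polynomial evaluation of its transfer
#' function on the unit circle. Used to verify the implementation against the
#' analytic Butterworth form.
#'
#' @param freq Frequencies in Hz at which to evaluate.
#' @param fps Sampling rate in Hz.
#' @param cfg A [bandpass_config()].
#' @param squared Return the squared magnitude (single-pass convention).
#' @return Numeric vector of gains.
#' @export
bandpass_response <- function(freq, fps, cfg = bandpass_config(),
                              squared = TRUE) {
  bf <- butter_coefficients(fps, cfg)
  w <- 2 * pi * freq / fps
  H <- vapply(w, function(om) {
    z <- exp(-1i * om * (seq_along(bf$b) - 1))
    num <- sum(bf$b * z)
    den <- sum(bf$a * exp(-1i * om * (seq_along(bf$a) - 1)))
    abs(num / den)
  }, numeric(1))
  if (squared) H^2 else H
}

#' CHROM chrominance pulse extraction
#'
#' Implements the chrominance method on skin-mean RGB traces: each channel is
#' standardized by its running mean over the analysis window length (default
#' 1.6 s), projected onto the chrominance axes `X = 3 R_n - 2 G_n` and
#' `Y = 1.5 R_n + G_n - 1.5 B_n`, and both projections are band-filtered over
#' the full series (filtering whole series rather than 1.6 s snippets avoids
#' IIR edge transients that would attenuate low pulse rates). The adaptive
#' combination `S = X_f - alpha Y_f` with `alpha = sd(X_f) / sd(Y_f)` is then
#' computed per sliding window (50% overlap) and Hann overlap-added.
#'
#' @param r,g,b Numeric per-frame skin-mean channel traces (equal length).
#' @param fps Sampling rate in Hz.
#' @param window_sec Window length in seconds (default 1.6) for the running
#'   standardization and the adaptive alpha.
#' @param cfg Band-pass configuration applied to the projections.
#' @return Numeric pulse signal, same length as the input.
#' @export
chrom_pulse <- function(r, g, b, fps, window_sec = 1.6,
                        cfg = bandpass_config()) {
  n <- length(r)
  stopifnot(length(g) == n, length(b) == n)
  if (n < 2 * fps) {
    stop_pg("Need at least 2 s of samples for CHROM.", "pg_length_error")
  }
  L <- 2L * floor(window_sec * fps / 2)
  L <- min(L, n)
  hop <- L %/% 2L
  runmean <- function(x) {
    half <- L %/% 2L
    cs <- cumsum(c(0, x))
    lo <- pmax(0L, seq_len(n) - 1L - half)
    hi <- pmin(n, seq_len(n) + half)
    (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
  rn <- r / runmean(r)
  gn <- g / runmean(g)
  bn <- b / runmean(b)
  xf <- bandpass(3 * rn - 2 * gn, fps, cfg)
  yf <- bandpass(1.5 * rn + gn - 1.5 * bn, fps, cfg)
  starts <- seq(1L, n - L + 1L, by = hop)
  if (tail(starts, 1) + L - 1L < n) starts <- c(starts, n - L + 1L)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
  out <- numeric(n)
  wsum <- numeric(n)
  for (s in starts) {
    idx <- s:(s + L - 1L)
    sy <- sd(yf[idx])
    if (sy < .Machine$double.eps) {
      stop_pg("Degenerate signal: zero-variance chrominance component.",
              "pg_degenerate_error")
    }
    alpha <- sd(xf[idx]) / sy
    sw <- xf[idx] - alpha * yf[idx]
    sw <- sw - mean(sw)
    out[idx] <- out[idx] + hann * sw
    wsum[idx] <- wsum[idx] + hann
  }
  out / pmax(wsum, 1e-12)
}

#' Smoothness-priors detrending with normalization
#'
#' Removes low-frequency trends (e.g. respiration) with the smoothness-priors
#' method: the trend is `(I + lambda^2 D2' D2)^{-1} z` where `D2` is the
#' second-difference operator, and the detrended signal is the residual,
#' optionally scaled to zero mean and unit variance.
#'
#' @param x Numeric signal.
#' @param lambda Smoothing parameter (default 300, tuned for 30 Hz series).
#' @param normalize Scale the residual to zero mean, unit variance.
#' @return The detrended (and normalized) signal.
#' @export
detrend_normalize <- function(x, lambda = 300, normalize = TRUE) {
  n <- length(x)
  if (n < 3) stop_pg("Signal too short to detrend.", "pg_length_error")
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D2)
  trend <- as.numeric(Matrix::solve(A, x))
  resid <- x - trend
  if (!normalize) return(resid)
  s <- sd(resid)
  if (!is.finite(s) || s < 1e-10 * max(1, sd(x))) {
    stop_pg("Residual has (near-)zero variance; cannot normalize.",
            "pg_degenerate_error")
  }
  (resid - mean(resid)) / s
}

# Core spectral peak estimator; no minimum-length guard.
.bpm_core <- function(x, fps, low = 0.7, high = 4.0, pad_factor = 8) {
  n <- length(x)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  nfft <- 2^ceiling(log2(pad_factor * n))
  X <- fft(c(x * hann, numeric(nfft - n)))
  half <- seq_len(nfft %/% 2 + 1)
  freqs <- (half - 1) * fps / nfft
  psd <- Mod(X[half])^2
  band <- which(freqs >= low & freqs <= high)
  k <- band[which.max(psd[band])]
  list(bpm = freqs[k] * 60, peak_power = psd[k],
       freqs = freqs, psd = psd)
}

#' Estimate heart rate from a pulse signal
#'
#' Hann-windows the signal, computes the power spectral density via a
#' zero-padded FFT (pad factor 8 for sub-bpm peak resolution), restricts the
#' spectrum to the pulse band and returns the frequency of the maximum power
#' peak times 60.
#'
#' @param x Numeric pulse signal.
#' @param fps Sampling rate in Hz.
#' @param low,high Band restriction in Hz (defaults 0.7 and 4.0, i.e.
#'   42-240 bpm).
#' @param min_duration Minimum signal length in seconds (default 5).
#' @param pad_factor FFT zero-padding factor.
#' @return A list of class `bpm_estimate` with `bpm` and `peak_power`.
#' @export
estimate_bpm <- function(x, fps, low = 0.7, high = 4.0, min_duration = 5,
                         pad_factor = 8) {
  if (length(x) < min_duration * fps) {
    stop_pg(sprintf("Need at least %g s of samples.", min_duration),
            "pg_length_error")
  }
  res <- .bpm_core(x, fps, low, high, pad_factor)
  structure(list(bpm = res$bpm, peak_power = res$peak_power),
            class = "bpm_estimate")
}

#' @export
print.bpm_estimate <- function(x, ...) {
  cat(sprintf("<bpm_estimate> %.2f bpm (peak power %.3g)\n",
              x$bpm, x$peak_power), ...)
  invisible(x)
}

#' Hann-windowed power spectrum of a pulse signal
#'
#' @inheritParams estimate_bpm
#' @return A tibble (`frequency` in Hz, `bpm`, `power`) of class
#'   `pg_spectrum`, restricted to \[0, fps/2\].
#' @export
pulse_spectrum <- function(x, fps, pad_factor = 8) {
  res <- .bpm_core(x, fps, low = 0, high = fps / 2, pad_factor = pad_factor)
  out <- tibble(frequency = res$freqs, bpm = res$freqs * 60, power = res$psd)
  class(out) <- c("pg_spectrum", class(out))
  out
}

#' Sliding-window BPM trace aligned to frames
#'
#' Runs the spectral estimator over sliding windows and interpolates the
#' window-center estimates onto every frame index (edge-padded), so the trace
#' aligns sample-for-sample with the other signal channels.
#'
#' @param x Numeric pulse signal.
#' @param fps Sampling rate in Hz.
#' @param window Window length in frames (default 90).
#' @param stride Window stride in frames (default 1).
#' @param low,high Band restriction in Hz.
#' @return Numeric BPM series with `length(x)` samples.
#' @export
bpm_trace <- function(x, fps, window = 90L, stride = 1L,
                      low = 0.7, high = 4.0) {
  n <- length(x)
  if (n < window) {
    stop_pg("Signal shorter than the BPM window.", "pg_length_error")
  }
  starts <- seq(1L, n - window + 1L, by = stride)
  vals <- vapply(starts, function(s) {
    .bpm_core(x[s:(s + window - 1L)], fps, low, high)$bpm
  }, numeric(1))
  centers <- starts + (window - 1) / 2
  if (length(starts) == 1L) return(rep(vals, n))
  approx(centers, vals, xout = seq_len(n), rule = 2)$y
}
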