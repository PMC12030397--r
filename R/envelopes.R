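# Analytic signal via FFT: zero negative frequencies, double positive ones.
analytic_signal <- function(v) {
  n <- length(v)
  X <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert-transform amplitude envelope
#'
#' Magnitude of the analytic signal: the time-varying amplitude of a
#' zero-mean, band-limited input.
#'
#' @param x A `uniform_signal`.
#' @return A non-negative `uniform_signal` of the same length and rate.
#' @export
hilbert_envelope <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  env <- Mod(analytic_signal(x$values))
  uniform_signal(env, x$fs, x$t0, paste0(x$label, " [envelope]"))
}

#' Session-wide unit-variance normalization
#'
#' Subtracts the whole-session mean and divides by the whole-session SD, so
#' that band amplitudes from different subjects and methods share a common
#' dimensionless ("normalized units") scale.  Per-epoch power differences are
#' preserved: only the session-level scale is removed.
#'
#' @param x A `uniform_signal` spanning the session.
#' @return A `uniform_signal` with session variance 1.
#' @export
unit_variance_normalize <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  s <- stats::sd(x$values)
  if (!is.finite(s) || s == 0) stop("signal has zero variance; cannot normalize")
  uniform_signal((x$values - mean(x$values)) / s, x$fs, x$t0,
                 paste0(x$label, " [n.u.]"))
}

#' Welch power spectral density
#'
#' Hann-windowed, overlapping-segment averaged one-sided PSD with density
#' scaling, so that summing `psd * df` over a band recovers the signal power
#' (ms^2 for RR input) in that band.
#'
#' @param v Numeric vector (will be linearly detrended per segment).
#' @param fs Sampling rate in Hz.
#' @param seg_len_s Segment length in seconds (default 120).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(v, fs, seg_len_s = 120, overlap = 0.5) {
  n <- length(v)
  nper <- min(n, round(seg_len_s * fs))
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  acc <- numeric(nper)
  for (s in starts) {
    seg <- v[s:(s + nper - 1L)]
    tt <- seq_len(nper)
    seg <- stats::residuals(stats::lm.fit(cbind(1, tt), seg))
    acc <- acc + Mod(stats::fft(seg * w))^2
  }
  pxx <- acc / (length(starts) * fs * sum(w^2))
  nf <- floor(nper / 2) + 1L
  psd <- pxx[seq_len(nf)]
  # one-sided: double all bins except DC (and Nyquist when present)
  dbl <- 2:(nf - if (nper %% 2 == 0) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_len(nf) - 1L) * fs / nper, psd = psd)
}

# integral of the one-sided PSD over [lo, hi)
band_power <- function(welch, lo, hi) {
  df <- welch$freq[2] - welch$freq[1]
  sum(welch$psd[welch$freq >= lo & welch$freq < hi]) * df
}
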