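# Zero-phase FIR low-pass via a centered, linear-phase filter with
# reflection padding (no phase distortion, designed magnitude preserved).
fir_zero_phase <- function(x, h) {
  n <- length(x); m <- length(h)
  pad <- min(n - 1L, m)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y)[(pad + 1):(pad + n)]
}

anti_alias_fir <- function(fs, target_fs) {
  # pass band to 0.4 * target, deep attenuation by 0.45 * target (stop-band
  # edge); unit DC gain enforced exactly
  trans <- 0.05 * target_fs / fs          # normalized (cycles/sample)
  ntaps <- 2L * ceiling(1.65 / trans) + 1L
  h <- signal::fir1(ntaps - 1L, 0.425 * target_fs / (fs / 2), type = "low")
  h / sum(h)
}

#' Resample a uniform signal to a lower rate
#'
#' Anti-alias low-pass (stop-band edge at 0.45 x target rate) followed by
#' interpolation onto the target grid.  Duration is preserved to within one
#' target-rate sample.  Upsampling is refused.
#'
#' @param x A `uniform_signal`.
#' @param target_fs Target sampling rate in Hz, `<= x$fs`.
#' @return A `uniform_signal` at `target_fs`.
#' @export
resample_uniform <- function(x, target_fs) {
  stopifnot(inherits(x, "uniform_signal"))
  if (target_fs <= 0) stop("target_fs must be positive")
  if (target_fs > x$fs) stop("upsampling not supported (target_fs > fs)")
  if (abs(target_fs - x$fs) < 1e-12) return(x)
  h <- anti_alias_fir(x$fs, target_fs)
  xf <- fir_zero_phase(x$values, h)
  tt <- signal_times(x)
  t_new <- seq(x$t0, tt[length(tt)], by = 1 / target_fs)
  vals <- stats::approx(tt, xf, xout = t_new)$y
  uniform_signal(vals, target_fs, x$t0, x$label)
}

#' Zero-phase high-pass filter for EDA
#'
#' Removes the tonic/DC content below `cutoff` with a forward-backward
#' (zero-phase) Butterworth filter, as required before the
#' complex-demodulation sympathetic index.
#'
#' @param x A `uniform_signal`.
#' @param cutoff High-pass cutoff in Hz (default 0.01).
#' @return A `uniform_signal` with mean approximately 0.
#' @export
highpass_eda <- function(x, cutoff = 0.01) {
  stopifnot(inherits(x, "uniform_signal"))
  if (cutoff >= x$fs / 2) stop("cutoff must be below Nyquist")
  bf <- signal::butter(2, cutoff / (x$fs / 2), type = "high")
  v <- x$values - mean(x$values)
  n <- length(v)
  # odd-reflection padding keeps the forward-backward transient of the very
  # low cutoff out of the record
  pad <- min(n - 1L, ceiling(1.5 / cutoff * x$fs))
  vp <- c(2 * v[1] - rev(v[2:(pad + 1)]), v, 2 * v[n] - rev(v[(n - pad):(n - 1)]))
  vf <- signal::filtfilt(bf, vp)[(pad + 1):(pad + n)]
  uniform_signal(vf, x$fs, x$t0, paste0(x$label, " [hp ", cutoff, " Hz]"))
}

#' Screen EDA quality with slope and range rules
#'
#' Algorithmic stand-in for visual artifact inspection: samples outside the
#' plausible conductance range or with slew rate beyond `slope_limit` (motion
#' artifacts) are flagged.  The record is discarded when strictly more than
#' 2% of samples are flagged.
#'
#' @param x A `uniform_signal` (EDA, uS).
#' @param slope_limit Maximum plausible |slope| in uS/s.
#' @param range_limits Length-2 plausible range in uS.
#' @return A `quality_report`.
#' @export
screen_eda_quality <- function(x, slope_limit = 5, range_limits = c(0.01, 60)) {
  stopifnot(inherits(x, "uniform_signal"))
  if (length(x$values) == 0) stop("empty signal")
  if (slope_limit <= 0 || any(range_limits <= 0)) stop("limits must be positive")
  v <- x$values
  out_range <- v < range_limits[1] | v > range_limits[2]
  slope <- c(0, abs(diff(v)) * x$fs)
  out_slope <- slope > slope_limit
  mask <- out_range | out_slope
  quality_report(mean(mask), mask)
}

#' Detect and correct ectopic beats in an RR series
#'
#' Intervals deviating by more than `deviation_threshold` (proportionally)
#' from the running median of their neighbours are flagged as ectopic.
#' Flagged runs are replaced by a cubic spline fitted through the adjacent
#' valid RR values and evaluated on a 2 Hz grid; each replaced run is
#' rescaled so total elapsed time is preserved.  The record is discarded
#' (flag only) when strictly more than 2% of intervals are flagged.
#'
#' @param beats A `beat_series` with at least 10 intervals.
#' @param deviation_threshold Proportional deviation from the running median
#'   that flags an interval (default 0.2).
#' @return A list with `beats` (corrected `beat_series`) and `report`
#'   (`quality_report`).
#' @export
correct_ectopic_beats <- function(beats, deviation_threshold = 0.2) {
  stopifnot(inherits(beats, "beat_series"))
  rr <- beats$rr_ms
  n <- length(rr)
  if (n < 10) stop("need at least 10 RR intervals")
  med <- stats::runmed(rr, k = 11, endrule = "median")
  flag <- abs(rr - med) / med > deviation_threshold
  if (mean(flag) > 0.5) stop("more than 50% of intervals flagged; series unusable")
  report <- quality_report(mean(flag), flag)
  if (!any(flag)) return(list(beats = beats, report = report))

  bt <- beats$beat_times
  mid <- (bt[-length(bt)] + bt[-1]) / 2
  ok <- which(!flag)
  sf <- stats::splinefun(mid[ok], rr[ok], method = "natural")
  rr2 <- rr
  # walk maximal flagged runs; predictions from the spline sampled on a 2 Hz
  # grid across the gap, then rescaled to preserve elapsed time
  i <- 1
  while (i <= n) {
    if (!flag[i]) { i <- i + 1; next }
    j <- i
    while (j < n && flag[j + 1]) j <- j + 1
    t_lo <- bt[i]; t_hi <- bt[j + 1]
    grid <- seq(t_lo, t_hi, by = 0.5)
    if (length(grid) < 2) grid <- c(t_lo, t_hi)
    pred_grid <- sf(grid)
    pred <- stats::approx(grid, pred_grid, xout = mid[i:j], rule = 2)$y
    pred <- pmax(pred, 200)  # physiological floor
    pred <- pred * ((t_hi - t_lo) * 1000 / sum(pred))
    rr2[i:j] <- pred
    i <- j + 1
  }
  bt2 <- c(bt[1], bt[1] + cumsum(rr2) / 1000)
  list(beats = beat_series(bt2, artifact_flags = flag), report = report)
}

#' Interpolate an RR series onto a uniform grid
#'
#' The RR value at each beat time (the interval closed by that beat) is
#' interpolated by a cubic spline onto a uniform grid, giving the evenly
#' sampled RR tachogram used by spectral analysis.
#'
#' @param beats A `beat_series` with at least 4 beats.
#' @param target_fs Grid rate in Hz (e.g. 4 for classical spectra, 1 for the
#'   time-frequency decompositions).
#' @return A `uniform_signal` in ms.
#' @export
rr_to_uniform <- function(beats, target_fs) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$beat_times) < 4) stop("need at least 4 beats")
  t_anchor <- beats$beat_times[-1]
  sf <- stats::splinefun(t_anchor, beats$rr_ms, method = "fmm")
  t_new <- seq(t_anchor[1], t_anchor[length(t_anchor)], by = 1 / target_fs)
  uniform_signal(sf(t_new), target_fs, t_new[1], "RR (ms)")
}

#' Slice a signal into per-condition epochs
#'
#' Epochs are half-open `[start_s, end_s)` intervals.  With `clip = TRUE`
#' epochs are intersected with the signal support (useful for series that
#' start at the first beat rather than at time zero).
#'
#' @param x A `uniform_signal`.
#' @param schedule An `epoch_schedule`.
#' @param clip Clip epochs to the signal support instead of erroring.
#' @return Named list of `uniform_signal`s, one per epoch.
#' @export
segment_epochs <- function(x, schedule, clip = FALSE) {
  stopifnot(inherits(x, "uniform_signal"), inherits(schedule, "epoch_schedule"))
  tt <- signal_times(x)
  t_lo <- tt[1]; t_hi <- tt[length(tt)] + 1 / x$fs
  out <- list()
  for (i in seq_len(nrow(schedule))) {
    a <- schedule$start_s[i]; b <- schedule$end_s[i]
    if (clip) { a <- max(a, t_lo); b <- min(b, t_hi) }
    if (a < t_lo - 1e-9 || b > t_hi + 1e-9)
      stop(sprintf("epoch %s [%g, %g) outside signal support [%g, %g)",
                   schedule$condition[i], a, b, t_lo, t_hi))
    idx <- which(tt >= a - 1e-9 & tt < b - 1e-9)
    if (length(idx) < 2) stop("epoch contains fewer than 2 samples")
    out[[schedule$condition[i]]] <-
      uniform_signal(x$values[idx], x$fs, tt[idx[1]], x$label)
  }
  out
}
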