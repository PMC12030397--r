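#' Evenly sampled time series
#'
#' Lightweight container for uniformly sampled signals: EDA traces (uS),
#' interpolated RR series (ms), decomposition components and Hilbert
#' envelopes (dimensionless).
#'
#' @param values Numeric vector of samples; all finite, length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds from recording start.
#' @param label Short description of what the signal carries.
#' @return An object of class `uniform_signal`.
#' @export
uniform_signal <- function(values, fs, t0 = 0, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("uniform_signal needs at least 2 samples")
  if (!all(is.finite(values))) stop("uniform_signal values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar (Hz)")
  structure(list(values = values, fs = fs, t0 = t0, label = label),
            class = "uniform_signal")
}

#' Sample times of a uniform signal
#' @param x A `uniform_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  x$t0 + (seq_along(x$values) - 1L) / x$fs
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %s: %d samples @ %g Hz, t0 = %g s, range [%.4g, %.4g]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$fs, x$t0, min(x$values), max(x$values)))
  invisible(x)
}

#' Beat series with RR intervals
#'
#' Beat occurrence times with the derived RR (interbeat) intervals and
#' per-interval artifact flags.  Interval `i` spans
#' `beat_times[i]` to `beat_times[i + 1]`.
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @param rr_ms RR intervals in ms; defaults to `diff(beat_times) * 1000`.
#' @param artifact_flags Logical per-interval flags (default all `FALSE`).
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(beat_times, rr_ms = diff(beat_times) * 1000,
                        artifact_flags = rep(FALSE, length(rr_ms))) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L) stop("beat_series needs at least 2 beats")
  if (any(diff(beat_times) <= 0)) stop("beat_times must be strictly increasing")
  if (length(rr_ms) != length(beat_times) - 1L)
    stop("rr_ms must have length(beat_times) - 1 entries")
  if (any(rr_ms <= 0)) stop("all RR intervals must be positive")
  if (max(abs(rr_ms - diff(beat_times) * 1000)) > 0.5)
    stop("rr_ms inconsistent with beat_times (beyond rounding)")
  structure(list(beat_times = beat_times, rr_ms = as.numeric(rr_ms),
                 artifact_flags = as.logical(artifact_flags)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f s, mean RR %.1f ms, %d flagged\n",
              length(x$beat_times), diff(range(x$beat_times)),
              mean(x$rr_ms), sum(x$artifact_flags)))
  invisible(x)
}

#' Epoch schedule of experimental conditions
#'
#' Ordered, non-overlapping condition epochs.  Intervals are half-open
#' `[start_s, end_s)`, 0-based in time from recording start.
#'
#' @param condition Character vector of condition labels.
#' @param start_s,end_s Epoch bounds in seconds.
#' @return A data.frame of class `epoch_schedule`.
#' @export
epoch_schedule <- function(condition, start_s, end_s) {
  if (length(condition) != length(start_s) || length(start_s) != length(end_s))
    stop("condition, start_s and end_s must have equal length")
  if (any(end_s <= start_s)) stop("each epoch must have positive duration")
  o <- order(start_s)
  condition <- as.character(condition)[o]
  start_s <- as.numeric(start_s)[o]; end_s <- as.numeric(end_s)[o]
  if (length(start_s) > 1L && any(start_s[-1L] < end_s[-length(end_s)] - 1e-9))
    stop("epochs must not overlap")
  structure(data.frame(condition = condition, start_s = start_s, end_s = end_s,
                       stringsAsFactors = FALSE),
            class = c("epoch_schedule", "data.frame"))
}

#' Build a contiguous schedule from labels and a common duration
#' @param epoch_names Ordered condition labels.
#' @param epoch_duration Duration of each epoch in seconds.
#' @return An `epoch_schedule` starting at 0 s.
#' @export
contiguous_schedule <- function(epoch_names = c("Baseline", "EMOT", "COG"),
                                epoch_duration = 600) {
  n <- length(epoch_names)
  epoch_schedule(epoch_names,
                 start_s = (seq_len(n) - 1L) * epoch_duration,
                 end_s = seq_len(n) * epoch_duration)
}

#' Ordered band-limited components of a decomposition
#'
#' @param components List of `uniform_signal`s in ascending frequency order.
#' @param center_freqs Nominal center frequencies (Hz), one per component.
#' @param band_edges Two-column matrix of lower/upper band edges (Hz).
#' @param method Either "VFCDM" or "WPT3".
#' @return An object of class `component_set`.
#' @export
component_set <- function(components, center_freqs, band_edges, method) {
  stopifnot(is.list(components), all(vapply(components, inherits, TRUE, "uniform_signal")))
  if (length(center_freqs) != length(components))
    stop("one center frequency per component required")
  band_edges <- matrix(as.numeric(band_edges), ncol = 2L)
  if (nrow(band_edges) != length(components)) stop("one band-edge pair per component")
  if (is.unsorted(center_freqs)) stop("components must be in ascending frequency order")
  method <- match.arg(method, c("VFCDM", "WPT3"))
  structure(list(components = components, center_freqs = as.numeric(center_freqs),
                 band_edges = band_edges, method = method),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %s, %d components, centers: %s Hz\n", x$method,
              length(x$components), paste(signif(x$center_freqs, 3), collapse = ", ")))
  invisible(x)
}

#' Signal-quality report for artifact screening
#'
#' Records the corrupted fraction, the per-sample (or per-interval) artifact
#' mask, and whether the record is discarded under the strict greater-than-2%
#' corrupted-data rule.
#'
#' @param corrupted_fraction Proportion of flagged samples/intervals.
#' @param mask Logical artifact mask.
#' @param discard_threshold Discard rule threshold (default 0.02, strict `>`).
#' @return An object of class `quality_report`.
#' @export
quality_report <- function(corrupted_fraction, mask,
                           discard_threshold = 0.02) {
  structure(list(corrupted_fraction = corrupted_fraction,
                 mask = as.logical(mask),
                 discarded = corrupted_fraction > discard_threshold,
                 discard_threshold = discard_threshold),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> corrupted %.2f%% -> %s\n",
              100 * x$corrupted_fraction,
              if (x$discarded) "DISCARDED" else "retained"))
  invisible(x)
}
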