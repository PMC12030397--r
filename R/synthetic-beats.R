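# Narrowband unit-variance driver: sqrt(2) * sin(theta) with instantaneous
# frequency performing a reflected random walk inside [f0 - hw, f0 + hw].
narrowband_driver <- function(n, fs, f0, half_width, pure_tone = FALSE,
                              step_sd = 0.002) {
  if (pure_tone) {
    f <- rep(f0, n)
  } else {
    f <- numeric(n)
    f[1] <- stats::runif(1, f0 - half_width, f0 + half_width)
    steps <- stats::rnorm(n - 1, 0, step_sd / sqrt(fs))
    for (i in 2:n) {
      v <- f[i - 1] + steps[i - 1]
      if (v > f0 + half_width) v <- 2 * (f0 + half_width) - v
      if (v < f0 - half_width) v <- 2 * (f0 - half_width) - v
      f[i] <- v
    }
  }
  phase0 <- if (pure_tone) 0 else stats::runif(1, 0, 2 * pi)
  theta <- phase0 + 2 * pi * cumsum(f) / fs
  sqrt(2) * sin(theta)
}

#' Generate a synthetic beat series by integral pulse frequency modulation
#'
#' The instantaneous beat rate is
#' `m(t) = (mean_hr / 60) * (1 + lf_amp * x_LF(t) + hf_amp * x_HF(t))`
#' with `x_LF`, `x_HF` unit-variance narrowband processes centered at 0.1 Hz
#' and 0.25 Hz.  Beats occur where the cumulative integral of `m` crosses
#' successive integers; RR intervals are the successive beat-time differences
#' in ms.
#'
#' @param schedule An `epoch_schedule`.
#' @param params_by_condition Named list of `condition_physio_params`.
#' @param fs_internal Internal integration rate in Hz.
#' @param seed Integer seed.
#' @param pure_tones Use fixed-frequency modulation drivers (see
#'   [session_config()]).
#' @return A list of class `synthetic_beats`: `beats` (a `beat_series`) and
#'   `truth` (per-epoch data.frame of planted `lf_amp`, `hf_amp`, `mean_hr`).
#' @export
generate_beats <- function(schedule, params_by_condition = default_condition_params(),
                           fs_internal = 8, seed = 1L, pure_tones = FALSE) {
  stopifnot(inherits(schedule, "epoch_schedule"))
  miss <- setdiff(schedule$condition, names(params_by_condition))
  if (length(miss)) stop("no parameters for condition(s): ", paste(miss, collapse = ", "))

  set.seed(seed + 1L)
  t_end <- max(schedule$end_s)
  n <- round(t_end * fs_internal) + 1L
  tt <- (seq_len(n) - 1L) / fs_internal
  idx_epoch <- pmin(findInterval(tt, schedule$start_s), nrow(schedule))

  par_of <- function(field)
    vapply(schedule$condition, function(cn) params_by_condition[[cn]][[field]], 0)[idx_epoch]
  hr <- par_of("mean_hr"); lf <- par_of("lf_amp"); hf <- par_of("hf_amp")

  x_lf <- narrowband_driver(n, fs_internal, 0.10, 0.02, pure_tones)
  x_hf <- narrowband_driver(n, fs_internal, 0.25, 0.03, pure_tones)
  m <- (hr / 60) * (1 + lf * x_lf + hf * x_hf)
  if (any(m <= 0))
    stop("modulation depths drive the instantaneous beat rate nonpositive")

  # cumulative integral (trapezoid), then unit crossings
  cm <- c(0, cumsum((m[-1] + m[-n]) / 2 / fs_internal))
  n_beats <- floor(cm[n])
  if (n_beats < 2) stop("schedule too short to contain two beats")
  beat_times <- stats::approx(cm, tt, xout = seq_len(n_beats))$y

  truth <- data.frame(condition = schedule$condition,
                      lf_amp = vapply(schedule$condition, function(cn) params_by_condition[[cn]]$lf_amp, 0),
                      hf_amp = vapply(schedule$condition, function(cn) params_by_condition[[cn]]$hf_amp, 0),
                      mean_hr = vapply(schedule$condition, function(cn) params_by_condition[[cn]]$mean_hr, 0),
                      stringsAsFactors = FALSE)
  structure(list(beats = beat_series(beat_times), truth = truth),
            class = "synthetic_beats")
}

#' Inject ectopic beats (extrasystole plus compensatory pause)
#'
#' A randomly chosen subset of interior beats is shifted early by 40% of the
#' preceding RR interval, which shortens one interval and lengthens the next
#' (the classic extrasystole / compensatory-pause pattern).  Total recording
#' duration is preserved; affected intervals are flagged in the output.
#'
#' @param sb A `synthetic_beats` object or a bare `beat_series`.
#' @param fraction Proportion of beats to corrupt, in `[0, 0.1]`.
#' @param seed Integer seed.
#' @return A `beat_series` with `artifact_flags` marking corrupted intervals
#'   and attribute `ectopic_beats` (indices of the shifted beats).
#' @export
inject_ectopics <- function(sb, fraction, seed = 1L) {
  beats <- if (inherits(sb, "synthetic_beats")) sb$beats else sb
  stopifnot(inherits(beats, "beat_series"))
  if (fraction < 0 || fraction > 0.1)
    stop("fraction must lie in [0, 0.1]")
  bt <- beats$beat_times
  n <- length(bt)
  k <- round(fraction * n)
  if (k == 0) {
    attr(beats, "ectopic_beats") <- integer(0)
    return(beats)
  }
  set.seed(seed + 2L)
  # interior beats, no two adjacent (so each ectopic has clean neighbours)
  cand <- sample(3:(n - 2))
  sel <- integer(0)
  for (i in cand) {
    if (length(sel) >= k) break
    if (!any(abs(sel - i) <= 1)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  bt2 <- bt
  bt2[sel] <- bt[sel] - 0.4 * (bt[sel] - bt[sel - 1])
  flags <- rep(FALSE, n - 1)
  flags[sel - 1] <- TRUE  # shortened interval
  flags[sel] <- TRUE      # compensatory pause
  out <- beat_series(bt2, artifact_flags = flags)
  attr(out, "ectopic_beats") <- sel
  out
}
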