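#' Evaluate the biexponential SCR kernel
#'
#' @param t Times in seconds (>= 0 gives nonzero response).
#' @param kernel An `scr_kernel_params` object.
#' @return Kernel values `exp(-t/tau_decay) - exp(-t/tau_rise)` (0 for t < 0).
#' @export
scr_kernel_eval <- function(t, kernel = scr_kernel_params()) {
  out <- exp(-t / kernel$tau_decay) - exp(-t / kernel$tau_rise)
  out[t < 0] <- 0
  out
}

# Bounded tonic drift: AR(1) around 0 with ~60 s relaxation time, stationary
# SD equal to drift_sd.
tonic_drift <- function(n, fs, drift_sd) {
  if (drift_sd <= 0) return(numeric(n))
  phi <- exp(-1 / (60 * fs))
  innov_sd <- drift_sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, drift_sd)
  e <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in 2:n) x[i] <- phi * x[i - 1] + e[i - 1]
  x
}

#' Generate a synthetic EDA session with ground truth
#'
#' Synthesizes tonic + phasic electrodermal activity over an epoch schedule.
#' The tonic part is a smoothed per-epoch level plus a bounded random walk;
#' the phasic part is a Poisson train of skin-conductance responses (SCRs)
#' convolved with a biexponential kernel with lognormal amplitudes; white
#' measurement noise is added on top.
#'
#' @param schedule An `epoch_schedule` with contiguous, non-overlapping epochs.
#' @param params_by_condition Named list of `condition_physio_params`, one
#'   entry per condition label appearing in `schedule`.
#' @param kernel An `scr_kernel_params` object.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param noise_sd White-noise SD in uS.
#' @param exact_counts If `TRUE`, plant exactly `round(rate * duration / 60)`
#'   SCRs per epoch (uniform times) instead of a Poisson-distributed count;
#'   useful for planted-event recovery experiments.
#' @return A list of class `synthetic_eda` with elements `signal`
#'   (`uniform_signal`, uS), `tonic`, `phasic` (ground-truth parts) and
#'   `events` (data.frame of condition, time_s, amplitude).
#' @export
generate_eda <- function(schedule, params_by_condition = default_condition_params(),
                         kernel = scr_kernel_params(), fs = 32, seed = 1L,
                         noise_sd = 0.01, exact_counts = FALSE) {
  stopifnot(inherits(schedule, "epoch_schedule"))
  miss <- setdiff(schedule$condition, names(params_by_condition))
  if (length(miss)) stop("no parameters for condition(s): ", paste(miss, collapse = ", "))
  if (any(diff(c(0, schedule$start_s)) < 0) ||
      (nrow(schedule) > 1 && any(abs(schedule$start_s[-1] - schedule$end_s[-nrow(schedule)]) > 1e-9)))
    stop("schedule epochs must be contiguous")
  for (p in params_by_condition[unique(schedule$condition)])
    if (p$scr_rate < 0) stop("scr_rate must be >= 0")

  set.seed(seed)
  t_end <- max(schedule$end_s)
  n <- round(t_end * fs)
  tt <- (seq_len(n) - 1L) / fs

  # per-sample condition index
  cond_of <- function(t) schedule$condition[findInterval(t, schedule$start_s)]
  idx_epoch <- findInterval(tt, schedule$start_s)

  # tonic: per-epoch levels smoothed by a 30 s moving average + bounded drift
  levels <- vapply(schedule$condition, function(cn) params_by_condition[[cn]]$tonic_level, 0)
  lev <- levels[idx_epoch]
  w <- max(1L, round(30 * fs)); if (w %% 2 == 0) w <- w + 1L
  lev_s <- stats::filter(c(rep(lev[1], w), lev, rep(lev[n], w)), rep(1 / w, w), sides = 2)
  lev_s <- as.numeric(lev_s)[(w + 1):(w + n)]
  drift_sd <- mean(vapply(schedule$condition,
                          function(cn) params_by_condition[[cn]]$tonic_drift_sd, 0))
  tonic <- lev_s + tonic_drift(n, fs, drift_sd)

  # phasic: Poisson SCR train per epoch
  ev_cond <- character(0); ev_time <- numeric(0)
  for (i in seq_len(nrow(schedule))) {
    p <- params_by_condition[[schedule$condition[i]]]
    dur <- schedule$end_s[i] - schedule$start_s[i]
    k <- if (exact_counts) round(p$scr_rate * dur / 60) else stats::rpois(1, p$scr_rate * dur / 60)
    if (k > 0) {
      times <- sort(stats::runif(k, schedule$start_s[i], schedule$end_s[i]))
      ev_time <- c(ev_time, times)
      ev_cond <- c(ev_cond, rep(schedule$condition[i], k))
    }
  }
  amp <- if (length(ev_time))
    stats::rlnorm(length(ev_time), kernel$amplitude_log_mean, kernel$amplitude_log_sd)
  else numeric(0)

  phasic <- numeric(n)
  if (length(ev_time)) {
    span <- ceiling(10 * kernel$tau_decay * fs)
    kern_t <- (0:span) / fs
    for (j in seq_along(ev_time)) {
      i0 <- floor(ev_time[j] * fs) + 1L
      idx <- i0:min(n, i0 + span)
      phasic[idx] <- phasic[idx] +
        amp[j] * scr_kernel_eval(tt[idx] - ev_time[j], kernel)
    }
  }

  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  structure(list(
    signal = uniform_signal(tonic + phasic + noise, fs, 0, "synthetic EDA (uS)"),
    tonic = uniform_signal(tonic, fs, 0, "true tonic"),
    phasic = uniform_signal(phasic, fs, 0, "true phasic"),
    events = data.frame(condition = ev_cond, time_s = ev_time, amplitude = amp,
                        stringsAsFactors = FALSE)),
    class = "synthetic_eda")
}
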