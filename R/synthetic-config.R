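#' Configuration for a synthetic recording session
#'
#' A session is a sequence of contiguous experimental epochs (by default
#' Baseline, EMOT, COG, 10 min each) during which EDA and beat-to-beat
#' intervals are generated with known ground truth.  EDA is synthesized at
#' 32 Hz: the analysis chain only ever consumes 2 Hz and 1 Hz versions, so a
#' moderate master rate exercises the decimation path while keeping
#' simulation cheap.
#'
#' @param n_subjects Number of subjects to simulate (>= 1).
#' @param epoch_names Ordered condition labels.
#' @param epoch_duration Epoch length in seconds (> 0).
#' @param eda_fs EDA master sampling rate in Hz (>= 4, so that decimation to
#'   2 Hz and 1 Hz stays well-posed).
#' @param eda_noise_sd Standard deviation of additive white measurement noise
#'   on EDA, in uS.
#' @param pure_tones If `TRUE`, the LF/HF heart-rate modulation drivers are
#'   fixed-frequency sinusoids; by default their instantaneous frequency
#'   wanders slowly within the band so spectral leakage looks realistic.
#' @param seed Integer seed driving all generators.
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_subjects = 34,
                           epoch_names = c("Baseline", "EMOT", "COG"),
                           epoch_duration = 600,
                           eda_fs = 32,
                           eda_noise_sd = 0.01,
                           pure_tones = FALSE,
                           seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (epoch_duration <= 0) stop("epoch_duration must be positive")
  if (eda_fs < 4) stop("eda_fs must be >= 4 Hz to support decimation to 2 and 1 Hz")
  structure(list(n_subjects = as.integer(n_subjects), epoch_names = epoch_names,
                 epoch_duration = epoch_duration, eda_fs = eda_fs,
                 eda_noise_sd = eda_noise_sd, pure_tones = isTRUE(pure_tones),
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Biexponential skin-conductance response kernel parameters
#'
#' A single SCR is modelled as `exp(-t / tau_decay) - exp(-t / tau_rise)`
#' scaled by a lognormal amplitude.  The default time constants (rise 0.7 s,
#' decay 2 s) equal the defaults of the convex tonic/phasic decomposition, so
#' that driver-recovery tests are well specified.
#'
#' @param tau_rise,tau_decay Rise and decay time constants in seconds,
#'   `0 < tau_rise < tau_decay`.
#' @param amplitude_log_mean,amplitude_log_sd Lognormal parameters of the SCR
#'   amplitude (uS scale of the unnormalized kernel).
#' @return A list of class `scr_kernel_params`.
#' @export
scr_kernel_params <- function(tau_rise = 0.7, tau_decay = 2,
                              amplitude_log_mean = log(1.5),
                              amplitude_log_sd = 0.4) {
  if (!(tau_rise > 0 && tau_rise < tau_decay))
    stop("need 0 < tau_rise < tau_decay")
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 amplitude_log_mean = amplitude_log_mean,
                 amplitude_log_sd = amplitude_log_sd),
            class = "scr_kernel_params")
}

#' Per-condition physiological generator parameters
#'
#' @param scr_rate Skin-conductance response rate in events/min (>= 0).
#' @param mean_hr Mean heart rate in beats/min (30-220).
#' @param lf_amp,hf_amp Dimensionless modulation depths of the instantaneous
#'   beat rate in the LF (~0.1 Hz) and HF (~0.25 Hz) bands; both >= 0 with
#'   `lf_amp + hf_amp < 1` so the instantaneous rate stays positive.
#' @param tonic_level Mean tonic skin conductance in uS.
#' @param tonic_drift_sd Standard deviation of the bounded tonic drift, uS.
#' @return A list of class `condition_physio_params`.
#' @export
condition_physio_params <- function(scr_rate = 4, mean_hr = 70,
                                    lf_amp = 0.03, hf_amp = 0.04,
                                    tonic_level = 2, tonic_drift_sd = 0.05) {
  if (scr_rate < 0) stop("scr_rate must be >= 0")
  if (mean_hr < 30 || mean_hr > 220) stop("mean_hr must lie in [30, 220] bpm")
  if (lf_amp < 0 || hf_amp < 0 || lf_amp + hf_amp >= 1)
    stop("need lf_amp, hf_amp >= 0 and lf_amp + hf_amp < 1")
  structure(list(scr_rate = scr_rate, mean_hr = mean_hr, lf_amp = lf_amp,
                 hf_amp = hf_amp, tonic_level = tonic_level,
                 tonic_drift_sd = tonic_drift_sd),
            class = "condition_physio_params")
}

#' Default per-condition parameters for the three-epoch protocol
#'
#' Encodes the qualitative autonomic picture of a cognitive-load protocol:
#' the cognitive task (COG) roughly doubles the SCR rate relative to Baseline
#' and the emotional condition (EMOT), and reduces the vagally mediated HF
#' heart-rate modulation; LF modulation and mean heart rate are held equal
#' across conditions.  Magnitudes are the package's own choice (only effect
#' directions are constrained by the protocol), see the methods vignette.
#'
#' @return Named list of `condition_physio_params`, one per condition.
#' @export
default_condition_params <- function() {
  list(
    Baseline = condition_physio_params(scr_rate = 4, mean_hr = 70,
                                       lf_amp = 0.03, hf_amp = 0.04,
                                       tonic_level = 2.0),
    EMOT     = condition_physio_params(scr_rate = 4, mean_hr = 70,
                                       lf_amp = 0.03, hf_amp = 0.04,
                                       tonic_level = 2.1),
    COG      = condition_physio_params(scr_rate = 8, mean_hr = 70,
                                       lf_amp = 0.03, hf_amp = 0.028,
                                       tonic_level = 2.2)
  )
}

#' Ground-truth parameters of the self-report generator
#'
#' Self-report scores follow a random-intercept linear model on standardized
#' physiological markers:
#' `score = intercept + beta_tvsymp * z(EDA_TVSYMP) + beta_hf * z(HF_VFCDM)
#'  + b_subject + eps`, clipped to the instrument range 1-100.
#'
#' @param intercept Score-scale intercept.
#' @param beta_tvsymp,beta_hf Effects in score units per SD of marker.
#' @param subject_sd Between-subject SD of the random intercept (>= 0).
#' @param resid_sd Residual SD (>= 0).
#' @return A list of class `self_report_truth`.
#' @export
self_report_truth <- function(intercept = 48,
                              beta_tvsymp = 13.80, beta_hf = -6.24,
                              subject_sd = sqrt(100.2),
                              resid_sd = sqrt(300.4)) {
  if (subject_sd < 0 || resid_sd < 0) stop("SDs must be >= 0")
  structure(list(intercept = intercept, beta_tvsymp = beta_tvsymp,
                 beta_hf = beta_hf, subject_sd = subject_sd,
                 resid_sd = resid_sd),
            class = "self_report_truth")
}
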