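# shared fixtures, all generated in code

# long marker table from a subjects x conditions matrix of one metric
make_marker_table <- function(Y, metric = "M", conditions = colnames(Y)) {
  if (is.null(conditions)) conditions <- c("Baseline", "EMOT", "COG")[seq_len(ncol(Y))]
  n <- nrow(Y)
  out <- tibble::tibble(
    subject = rep(sprintf("S%02d", seq_len(n)), each = ncol(Y)),
    condition = rep(conditions, n),
    marker = metric,
    value = as.numeric(t(Y)),
    units = "n.u.")
  class(out) <- c("marker_table", class(tibble::tibble()))
  out
}

# unit-variance narrowband Gaussian signal at 1 Hz via band-pass filtering
narrowband_gaussian <- function(n, lo = 0.15, hi = 0.40, fs = 1, seed = 1) {
  set.seed(seed)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2))
  v <- signal::filtfilt(bf, stats::rnorm(4 * n))[n + seq_len(n)]
  v <- (v - mean(v)) / stats::sd(v)
  uniform_signal(v, fs)
}

short_session <- function(n_subjects = 1, epoch_duration = 300, seed = 5, ...) {
  simulate_cohort(session_config(n_subjects = n_subjects,
                                 epoch_duration = epoch_duration,
                                 seed = seed, ...))
}
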