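#' Catalog of marker band definitions
#'
#' Fixed mapping from marker names to decomposition method, component
#' indices and nominal frequency range.  EDA sympathetic indices target the
#' ~0.045-0.25 Hz sudomotor band; HRV indices split into LF (sympathetic +
#' parasympathetic) and HF (predominantly vagal) bands.
#'
#' @return A data.frame with columns name, method, indices, range_lo,
#'   range_hi (Hz).
#' @export
band_catalog <- function() {
  data.frame(
    name = c("EDA_TVSYMP", "EDA_WPT3", "LF_VFCDM", "HF_VFCDM",
             "LF_WPT3", "HF_WPT3"),
    method = c("VFCDM", "WPT3", "VFCDM", "VFCDM", "WPT3", "WPT3"),
    indices = I(list(2:3, 2:4, 2L, 3:5, 2:3, 4:7)),
    range_lo = c(0.08, 0.0625, 0.08, 0.16, 0.0625, 0.1875),
    range_hi = c(0.24, 0.25, 0.16, 0.40, 0.1875, 0.4375),
    stringsAsFactors = FALSE)
}

#' Sympathetic EDA index from the convex decomposition
#'
#' Pipeline: convex tonic/phasic split -> phasic part -> session-wide
#' unit-variance normalization -> Hilbert envelope.
#'
#' @param eda_2hz Screened EDA at 2 Hz (`uniform_signal`).
#' @param params A `cvxeda_params`.
#' @return The envelope as a `uniform_signal` (normalized units).
#' @export
eda_cvx_index <- function(eda_2hz, params = cvxeda_params()) {
  dec <- cvxeda(eda_2hz, params)
  env <- hilbert_envelope(unit_variance_normalize(dec$phasic))
  env$label <- "EDA_CVX"
  env
}

#' Time-varying sympathetic EDA index from complex demodulation
#'
#' Pipeline: VFCDM of high-passed 2 Hz EDA -> sum of the components whose
#' centers lie in 0.08-0.24 Hz (components 2-3 at the default half-bandwidth
#' 0.04 Hz) -> unit-variance normalization -> Hilbert envelope.
#'
#' @param eda_2hz_hp High-passed (0.01 Hz) EDA at 2 Hz.
#' @param params A `vfcdm_params`.
#' @return The envelope as a `uniform_signal` (normalized units).
#' @export
eda_tvsymp <- function(eda_2hz_hp, params = vfcdm_params()) {
  cs <- vfcdm(eda_2hz_hp, params)
  idx <- which(cs$center_freqs > 0.08 & cs$center_freqs < 0.24)
  env <- hilbert_envelope(unit_variance_normalize(sum_components(cs, idx)))
  env$label <- "EDA_TVSYMP"
  env
}

#' Sympathetic EDA index from the level-3 wavelet packet bands
#'
#' Pipeline: level-3 wavelet packet decomposition of 1 Hz EDA -> sum of
#' components 2-4 (0.0625-0.25 Hz) -> unit-variance normalization -> Hilbert
#' envelope.
#'
#' @param eda_1hz EDA resampled to 1 Hz.
#' @return The envelope as a `uniform_signal` (normalized units).
#' @export
eda_wpt3_index <- function(eda_1hz) {
  cs <- wpt3(eda_1hz)
  env <- hilbert_envelope(unit_variance_normalize(sum_components(cs, 2:4)))
  env$label <- "EDA_WPT3"
  env
}

#' Root mean square of successive RR differences
#'
#' @param rr_ms RR intervals in ms (>= 2 intervals).
#' @return RMSSD in ms.
#' @export
hrv_rmssd <- function(rr_ms) {
  if (length(rr_ms) < 2) stop("RMSSD needs at least 2 intervals")
  sqrt(mean(diff(rr_ms)^2))
}

#' Classical spectral HRV indices by Fourier PSD
#'
#' Welch PSD (120 s Hann segments, 50% overlap, per-segment linear detrend)
#' of the 4 Hz interpolated RR series, integrated over the LF (0.04-0.15 Hz)
#' and HF (0.15-0.4 Hz) bands.
#'
#' @param rr_4hz A `uniform_signal` (RR in ms at 4 Hz), >= 100 s long.
#' @return Named list: `lf_ms2`, `hf_ms2`, `lf_hf`.
#' @export
hrv_dft_power <- function(rr_4hz) {
  stopifnot(inherits(rr_4hz, "uniform_signal"))
  if (length(rr_4hz$values) / rr_4hz$fs < 100)
    stop("record shorter than 100 s: LF resolution insufficient")
  w <- welch_psd(rr_4hz$values, rr_4hz$fs, seg_len_s = 120, overlap = 0.5)
  lf <- band_power(w, 0.04, 0.15)
  hf <- band_power(w, 0.15, 0.40)
  list(lf_ms2 = lf, hf_ms2 = hf, lf_hf = lf / hf)
}

#' Time-frequency HRV band envelopes by complex demodulation
#'
#' LF = Hilbert envelope of the normalized VFCDM component 2 (centered
#' 0.12 Hz); HF = envelope of the normalized sum of components 3-5 (centered
#' 0.20, 0.28, 0.36 Hz).
#'
#' @param rr_1hz Detrended 1 Hz interpolated RR series.
#' @param params A `vfcdm_params`.
#' @return List of `uniform_signal`s `lf` and `hf`.
#' @export
hrv_vfcdm_bands <- function(rr_1hz, params = vfcdm_params()) {
  cs <- vfcdm(rr_1hz, params)
  lf <- hilbert_envelope(unit_variance_normalize(sum_components(cs, 2L)))
  hf <- hilbert_envelope(unit_variance_normalize(sum_components(cs, 3:5)))
  lf$label <- "LF_VFCDM"; hf$label <- "HF_VFCDM"
  list(lf = lf, hf = hf)
}

#' Time-frequency HRV band envelopes by wavelet packets
#'
#' LF = envelope of the normalized sum of level-3 components 2-3
#' (0.0625-0.1875 Hz); HF = envelope of the normalized sum of components 4-7
#' (0.1875-0.4375 Hz).
#'
#' @param rr_1hz Detrended 1 Hz interpolated RR series.
#' @return List of `uniform_signal`s `lf` and `hf`.
#' @export
hrv_wpt3_bands <- function(rr_1hz) {
  cs <- wpt3(rr_1hz)
  lf <- hilbert_envelope(unit_variance_normalize(sum_components(cs, 2:3)))
  hf <- hilbert_envelope(unit_variance_normalize(sum_components(cs, 4:7)))
  lf$label <- "LF_WPT3"; hf$label <- "HF_WPT3"
  list(lf = lf, hf = hf)
}

# mean of an envelope inside each epoch, excluding guard_s from both ends of
# every epoch slice (transient guard)
epoch_envelope_means <- function(env, schedule, guard_s = 10) {
  slices <- segment_epochs(env, schedule, clip = TRUE)
  vapply(slices, function(s) {
    tt <- signal_times(s)
    keep <- tt >= tt[1] + guard_s & tt <= tt[length(tt)] - guard_s
    if (!any(keep)) keep <- rep(TRUE, length(tt))
    mean(s$values[keep])
  }, 0)
}

#' Compute all physiological markers for one subject
#'
#' Runs the full per-subject chain on raw EDA and a corrected beat series:
#' EDA quality screening, resampling, the three phasic-EDA envelope indices,
#' RMSSD, Fourier LF/HF, and the four time-frequency HRV band envelopes;
#' envelope markers are averaged over each epoch (10 s edge guard), scalar
#' markers are computed per epoch slice.
#'
#' @param eda Raw EDA `uniform_signal` (any rate >= 4 Hz).
#' @param beats A `beat_series` (artifact-corrected or clean).
#' @param schedule An `epoch_schedule`.
#' @param subject Subject identifier.
#' @param guard_s Envelope edge guard in seconds (default 10).
#' @return A `marker_table` tibble (one row per condition x marker), or
#'   `NULL` with a message if the EDA or RR record fails the 2% quality rule.
#' @export
compute_subject_markers <- function(eda, beats, schedule, subject = "S01",
                                    guard_s = 10) {
  qc <- screen_eda_quality(eda)
  if (qc$discarded) { message(subject, ": EDA discarded (", round(100 * qc$corrupted_fraction, 1), "% corrupted)"); return(NULL) }
  corr <- correct_ectopic_beats(beats)
  if (corr$report$discarded) { message(subject, ": RR discarded (", round(100 * corr$report$corrupted_fraction, 1), "% corrupted)"); return(NULL) }
  beats <- corr$beats

  eda2 <- resample_uniform(eda, 2)
  eda1 <- resample_uniform(eda, 1)
  conds <- schedule$condition

  env_rows <- function(name, env) {
    m <- epoch_envelope_means(env, schedule, guard_s)
    tibble::tibble(subject = subject, condition = conds, marker = name,
                   value = as.numeric(m[conds]), units = "n.u.")
  }

  rows <- list()
  rows$cvx <- env_rows("EDA_CVX", eda_cvx_index(eda2))
  rows$tvs <- env_rows("EDA_TVSYMP", eda_tvsymp(highpass_eda(eda2)))
  rows$wpt <- env_rows("EDA_WPT3", eda_wpt3_index(eda1))

  rr1 <- rr_to_uniform(beats, 1)
  rr1$values <- rr1$values - mean(rr1$values)
  vf <- hrv_vfcdm_bands(rr1)
  wp <- hrv_wpt3_bands(rr1)
  rows$lfv <- env_rows("LF_VFCDM", vf$lf)
  rows$hfv <- env_rows("HF_VFCDM", vf$hf)
  rows$lfw <- env_rows("LF_WPT3", wp$lf)
  rows$hfw <- env_rows("HF_WPT3", wp$hf)

  rr4 <- rr_to_uniform(beats, 4)
  rmssd <- lf <- hf <- lfhf <- numeric(length(conds))
  for (i in seq_along(conds)) {
    a <- schedule$start_s[i]; b <- schedule$end_s[i]
    idx <- which(beats$beat_times[-1] >= a & beats$beat_times[-1] < b)
    if (length(idx) < 10) stop("epoch ", conds[i], " has too few beats")
    rmssd[i] <- hrv_rmssd(beats$rr_ms[idx])
    seg <- segment_epochs(rr4, epoch_schedule(conds[i], a, b), clip = TRUE)[[1]]
    dft <- hrv_dft_power(seg)
    lf[i] <- dft$lf_ms2; hf[i] <- dft$hf_ms2; lfhf[i] <- dft$lf_hf
  }
  scal <- function(name, v, units) tibble::tibble(
    subject = subject, condition = conds, marker = name, value = v, units = units)
  rows$rmssd <- scal("RMSSD", rmssd, "ms")
  rows$lfd <- scal("LF_DFT", lf, "ms2")
  rows$hfd <- scal("HF_DFT", hf, "ms2")
  rows$lfhf <- scal("LFHF_DFT", lfhf, "n.u.")

  out <- do.call(rbind, unname(rows))
  class(out) <- c("marker_table", class(tibble::tibble()))
  out
}

#' Assemble the cohort marker table
#'
#' Computes markers for every subject of a synthetic cohort (or any list of
#' per-subject `eda`/`beats` pairs); subjects failing any stage are excluded
#' with a message (mirroring quality-based participant exclusion).
#'
#' @param cohort A `synthetic_cohort` or the list returned by
#'   [read_cohort()].
#' @param guard_s Envelope edge guard in seconds.
#' @return A `marker_table` covering all retained subjects; attribute
#'   `excluded` lists dropped subject ids.
#' @export
assemble_marker_table <- function(cohort, guard_s = 10) {
  schedule <- cohort$schedule
  tabs <- list(); excluded <- character(0)
  for (id in names(cohort$subjects)) {
    s <- cohort$subjects[[id]]
    eda <- if (inherits(s$eda, "synthetic_eda")) s$eda$signal else s$eda
    tab <- tryCatch(compute_subject_markers(eda, s$beats, schedule, id, guard_s),
                    error = function(e) { message(id, ": ", conditionMessage(e)); NULL })
    if (is.null(tab)) excluded <- c(excluded, id) else tabs[[id]] <- tab
  }
  if (!length(tabs)) stop("no subject survived marker computation")
  out <- do.call(rbind, unname(tabs))
  class(out) <- c("marker_table", class(tibble::tibble()))
  attr(out, "excluded") <- excluded
  out
}

#' Pivot a long marker table to wide format
#'
#' @param marker_table A `marker_table`.
#' @param markers Markers to keep as columns (default: all present).
#' @return A tibble with one row per subject x condition.
#' @export
marker_table_wide <- function(marker_table, markers = NULL) {
  df <- as.data.frame(marker_table)
  if (is.null(markers)) markers <- unique(df$marker)
  df <- df[df$marker %in% markers, c("subject", "condition", "marker", "value")]
  wide <- stats::reshape(df, idvar = c("subject", "condition"),
                         timevar = "marker", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if (anyNA(wide[markers]))
    stop("marker table has missing subject x condition x marker cells")
  tibble::as_tibble(wide)
}

#' Write a marker table as TSV
#' @param marker_table A `marker_table`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_marker_table <- function(marker_table, path) {
  utils::write.table(as.data.frame(marker_table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
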