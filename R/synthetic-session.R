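#' Generate self-report scores from physiological markers
#'
#' Workload and affect scores are generated from a random-intercept linear
#' model on the standardized sympathetic (EDA_TVSYMP) and vagal (HF_VFCDM)
#' markers:
#' `score = intercept + beta_tvsymp * z(EDA_TVSYMP) + beta_hf * z(HF_VFCDM) +
#'  b_subject + eps`, with `b ~ N(0, subject_sd^2)`,
#' `eps ~ N(0, resid_sd^2)`; `z()` standardizes across all
#' subject-by-condition rows.  Scores are clipped to the instrument range
#' `[1, 100]`.  The NASA-TLX subscales and the two visual-analogue scales are
#' noisy companions of the global score (plumbing, not part of the truth
#' model).
#'
#' @param marker_table A `marker_table` containing at least the
#'   `EDA_TVSYMP` and `HF_VFCDM` markers for every subject-condition cell.
#' @param truth A `self_report_truth` object.
#' @param seed Integer seed.
#' @return The input table with additional rows for markers
#'   `NASA_TLX_Global`, `NASA_TLX_MentalDemand`, `NASA_TLX_Effort`,
#'   `VAS_Stress`, `VAS_MentalFatigue` (units "score").
#' @export
generate_self_reports <- function(marker_table, truth = self_report_truth(),
                                  seed = 1L) {
  need <- c("EDA_TVSYMP", "HF_VFCDM")
  have <- unique(marker_table$marker)
  if (!all(need %in% have))
    stop("marker_table must contain markers: ", paste(setdiff(need, have), collapse = ", "))
  wide <- marker_table_wide(marker_table, markers = need)
  z <- function(x) (x - mean(x)) / stats::sd(x)
  z1 <- if (stats::sd(wide$EDA_TVSYMP) > 0) z(wide$EDA_TVSYMP) else wide$EDA_TVSYMP * 0
  z2 <- if (stats::sd(wide$HF_VFCDM) > 0) z(wide$HF_VFCDM) else wide$HF_VFCDM * 0

  set.seed(seed + 3L)
  subjects <- unique(wide$subject)
  b <- stats::rnorm(length(subjects), 0, truth$subject_sd)
  names(b) <- subjects
  lin <- truth$intercept + truth$beta_tvsymp * z1 + truth$beta_hf * z2 + b[wide$subject]
  clip <- function(x) pmin(100, pmax(1, x))
  mk <- function(name, values) tibble::tibble(
    subject = wide$subject, condition = wide$condition,
    marker = name, value = values, units = "score")

  global <- clip(lin + stats::rnorm(nrow(wide), 0, truth$resid_sd))
  extra <- rbind(
    mk("NASA_TLX_Global", global),
    mk("NASA_TLX_MentalDemand", clip(global + stats::rnorm(nrow(wide), 3, 8))),
    mk("NASA_TLX_Effort", clip(global + stats::rnorm(nrow(wide), -3, 8))),
    mk("VAS_Stress", clip(0.4 * lin + stats::rnorm(nrow(wide), 0, 10))),
    mk("VAS_MentalFatigue", clip(0.6 * lin + stats::rnorm(nrow(wide), 5, 12)))
  )
  out <- rbind(tibble::as_tibble(marker_table), extra)
  class(out) <- c("marker_table", class(tibble::tibble()))
  out
}

#' Simulate complete synthetic sessions for a cohort
#'
#' @param config A `session_config`.
#' @param params_by_condition Named list of `condition_physio_params`.
#' @param kernel An `scr_kernel_params`.
#' @param ectopic_fraction Fraction of beats corrupted by ectopics per
#'   subject (default 0, clean recordings).
#' @return A list of class `synthetic_cohort`: `schedule`, and `subjects`, a
#'   list (one element per subject) with `eda` (`synthetic_eda`) and `beats`
#'   (`beat_series` with truth attributes).
#' @export
simulate_cohort <- function(config = session_config(),
                            params_by_condition = default_condition_params(),
                            kernel = scr_kernel_params(),
                            ectopic_fraction = 0) {
  schedule <- contiguous_schedule(config$epoch_names, config$epoch_duration)
  subjects <- vector("list", config$n_subjects)
  names(subjects) <- sprintf("S%02d", seq_len(config$n_subjects))
  for (i in seq_len(config$n_subjects)) {
    sseed <- config$seed + 1000L * i
    eda <- generate_eda(schedule, params_by_condition, kernel,
                        fs = config$eda_fs, seed = sseed,
                        noise_sd = config$eda_noise_sd)
    sb <- generate_beats(schedule, params_by_condition, seed = sseed,
                         pure_tones = config$pure_tones)
    beats <- if (ectopic_fraction > 0)
      inject_ectopics(sb, ectopic_fraction, seed = sseed) else sb$beats
    subjects[[i]] <- list(eda = eda, beats = beats, beat_truth = sb$truth)
  }
  structure(list(schedule = schedule, config = config, subjects = subjects),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk as plain-text files
#'
#' Per subject: `<id>_eda.csv` (`time_s,eda_uS`), `<id>_beats.csv`
#' (`beat_time_s,rr_ms`); plus `schedule.csv` (`condition,start_s,end_s`) and
#' `truth.json` (planted SCR event times and per-epoch band amplitudes).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort$schedule),
                   file.path(dir, "schedule.csv"), row.names = FALSE)
  truth <- list()
  for (id in names(cohort$subjects)) {
    s <- cohort$subjects[[id]]
    tt <- signal_times(s$eda$signal)
    utils::write.csv(data.frame(time_s = tt, eda_uS = s$eda$signal$values),
                     file.path(dir, paste0(id, "_eda.csv")), row.names = FALSE)
    bt <- s$beats$beat_times
    utils::write.csv(data.frame(beat_time_s = bt, rr_ms = c(NA, s$beats$rr_ms)),
                     file.path(dir, paste0(id, "_beats.csv")), row.names = FALSE)
    truth[[id]] <- list(scr_events = s$eda$events$time_s,
                        band_amplitudes = s$beat_truth)
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Accepts the same CSV schemas for real exports; column names can be mapped
#' via `col_map` (names = canonical, values = names in the file).
#'
#' @param dir Directory containing `schedule.csv` and per-subject CSVs.
#' @param col_map Optional column-name mapping.
#' @return A list with `schedule` and `subjects` (each `eda`, `beats`).
#' @export
read_cohort <- function(dir, col_map = NULL) {
  sch <- utils::read.csv(file.path(dir, "schedule.csv"))
  schedule <- epoch_schedule(sch$condition, sch$start_s, sch$end_s)
  files <- list.files(dir, pattern = "_eda\\.csv$")
  ids <- sub("_eda\\.csv$", "", files)
  getcol <- function(df, nm) df[[if (!is.null(col_map) && nm %in% names(col_map)) col_map[[nm]] else nm]]
  subjects <- lapply(ids, function(id) {
    eda <- utils::read.csv(file.path(dir, paste0(id, "_eda.csv")))
    tt <- getcol(eda, "time_s")
    fs <- 1 / stats::median(diff(tt))
    beats <- utils::read.csv(file.path(dir, paste0(id, "_beats.csv")))
    list(eda = uniform_signal(getcol(eda, "eda_uS"), fs = round(fs, 6), t0 = tt[1],
                              label = paste(id, "EDA (uS)")),
         beats = beat_series(getcol(beats, "beat_time_s")))
  })
  names(subjects) <- ids
  list(schedule = schedule, subjects = subjects)
}
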