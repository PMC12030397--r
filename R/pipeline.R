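#' Default end-to-end run configuration
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL` = nothing written).
#' @param cluster_scope "all" or a condition label (e.g. "COG") for the
#'   profiling row scope.
#' @param ectopic_fraction Planted ectopic-beat fraction per subject.
#' @param epoch_duration Epoch length in seconds.
#' @param ... Overrides stored verbatim in the config.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 34, seed = 1L, out_dir = NULL,
                       cluster_scope = "all", ectopic_fraction = 0,
                       epoch_duration = 600, ...) {
  structure(list(n_subjects = n_subjects, seed = seed, out_dir = out_dir,
                 cluster_scope = cluster_scope,
                 ectopic_fraction = ectopic_fraction,
                 epoch_duration = epoch_duration, ...),
            class = "run_config")
}

PHYSIO_MARKERS <- c("EDA_CVX", "EDA_TVSYMP", "EDA_WPT3", "RMSSD",
                    "LF_DFT", "HF_DFT", "LFHF_DFT",
                    "LF_VFCDM", "HF_VFCDM", "LF_WPT3", "HF_WPT3")
SELFREPORT_MARKERS <- c("VAS_MentalFatigue", "VAS_Stress", "NASA_TLX_Global",
                        "NASA_TLX_MentalDemand", "NASA_TLX_Effort")
LMM_PREDICTORS <- c("EDA_CVX", "EDA_TVSYMP", "EDA_WPT3", "HF_VFCDM", "HF_WPT3")

#' Run the full synthetic-session analysis pipeline
#'
#' Generate -> preprocess -> decompose -> mark -> infer: simulates a cohort,
#' computes the marker table (logging every quality-based exclusion),
#' generates self-reports from the truth model, compares all physiological
#' and self-report metrics across conditions, fits the workload mixed model
#' (VIF screen, then stepwise backward selection), and profiles subjects by
#' k-means on the retained markers.
#'
#' @param config A `run_config`.
#' @return A list of class `pipeline_run`: `markers` (long table), `wide`,
#'   `comparisons` (per metric), `lmm_full`, `vif`, `lmm_final`, `clusters`,
#'   `excluded`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  sc <- session_config(n_subjects = config$n_subjects, seed = config$seed,
                       epoch_duration = config$epoch_duration)
  cohort <- simulate_cohort(sc, ectopic_fraction = config$ectopic_fraction)
  markers <- assemble_marker_table(cohort)
  excluded <- attr(markers, "excluded")
  n_kept <- length(unique(markers$subject))
  if (n_kept < 6) stop("fewer than 6 subjects survived preprocessing")
  markers <- generate_self_reports(markers, seed = config$seed)

  comparisons <- list()
  for (m in c(PHYSIO_MARKERS, SELFREPORT_MARKERS))
    comparisons[[m]] <- compare_conditions(markers, m)

  wide <- marker_table_wide(markers)
  lmm_full <- fit_lmm(wide, predictors = LMM_PREDICTORS)
  vif <- vif_screen(wide, LMM_PREDICTORS)
  lmm_screened <- fit_lmm(wide, predictors = vif$retained)
  lmm_final <- stepwise_backward(lmm_screened)
  feat <- lmm_final$predictors
  if (length(feat) < 2) feat <- c("EDA_TVSYMP", "HF_VFCDM")
  clusters <- kmeans_profiles(wide, features = feat, seed = config$seed,
                              scope = config$cluster_scope)

  run <- structure(list(markers = markers, wide = wide,
                        comparisons = comparisons, lmm_full = lmm_full,
                        vif = vif, lmm_final = lmm_final, clusters = clusters,
                        excluded = excluded, config = config),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' Summary tables in publication layout
#'
#' Self-report metrics as median (Q1-Q3) (type-7 quantiles); physiological
#' metrics as mean +/- SD; significance flags from the Bonferroni-adjusted
#' pairwise p-values: `*`/`**`/`***` vs Baseline and `#`/`##`/`###` vs EMOT
#' at p < 0.05 / 0.01 / 0.001.
#'
#' @param run A `pipeline_run`.
#' @return A list of two tibbles: `self_report` and `physiological`.
#' @export
summarize_tables <- function(run) {
  stars <- function(p, sym) {
    if (is.na(p) || p >= 0.05) return("")
    strrep(sym, if (p < 0.001) 3 else if (p < 0.01) 2 else 1)
  }
  fmt_med <- function(v) sprintf("%g (%g-%g)", signif(stats::median(v), 3),
                                 signif(stats::quantile(v, 0.25), 3),
                                 signif(stats::quantile(v, 0.75), 3))
  fmt_msd <- function(v) sprintf("%.3g ± %.2g", mean(v), stats::sd(v))
  conds <- unique(run$markers$condition)
  build <- function(metrics, fmt) {
    rows <- lapply(metrics, function(m) {
      df <- run$markers[run$markers$marker == m, ]
      cmp <- run$comparisons[[m]]$pairwise
      p_of <- function(pair) {
        hit <- cmp$p_adj[cmp$pair == pair]
        if (length(hit)) hit else NA_real_
      }
      vals <- vapply(conds, function(cn) fmt(df$value[df$condition == cn]), "")
      for (cn in setdiff(conds, conds[1])) {
        s <- stars(p_of(paste(conds[1], cn, sep = "-")), "*")
        h <- if (cn != conds[2])
          stars(p_of(paste(conds[2], cn, sep = "-")), "#") else ""
        vals[cn] <- paste0(vals[cn], if (nzchar(s) || nzchar(h)) " " else "", s,
                           if (nzchar(s) && nzchar(h)) "," else "", h)
      }
      tibble::tibble(metric = m, !!!as.list(vals))
    })
    do.call(rbind, rows)
  }
  list(self_report = build(intersect(SELFREPORT_MARKERS, unique(run$markers$marker)), fmt_med),
       physiological = build(intersect(PHYSIO_MARKERS, unique(run$markers$marker)), fmt_msd))
}

#' Write a pipeline run to disk
#'
#' Emits the marker table (TSV), wide CSV, comparison and model summaries
#' (JSON), cluster solution (JSON) and a markdown report with the summary
#' tables.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_marker_table(run$markers, file.path(dir, "markers.tsv"))
  utils::write.csv(as.data.frame(run$wide), file.path(dir, "markers_wide.csv"),
                   row.names = FALSE)
  cmp <- lapply(run$comparisons, function(cr)
    list(path = cr$path, omnibus = cr$omnibus, pairwise = cr$pairwise))
  jsonlite::write_json(cmp, file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(list(
    full = run$lmm_full$fixed, vif = as.list(run$vif$vif),
    vif_dropped = run$vif$dropped,
    final = run$lmm_final$fixed, stepwise_removed = run$lmm_final$removed,
    subject_var = run$lmm_final$subject_var, resid_var = run$lmm_final$resid_var,
    reml = run$lmm_final$reml),
    file.path(dir, "lmm.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  cl <- run$clusters
  jsonlite::write_json(list(k = cl$k, assignments = cl$assignments,
                            centroids = as.data.frame(cl$centroids),
                            wcss = cl$wcss, tot_wcss = cl$tot_wcss,
                            between_ratio = cl$between_ratio,
                            avg_silhouette = cl$avg_silhouette,
                            elbow = cl$elbow),
                       file.path(dir, "clusters.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  tabs <- summarize_tables(run)
  md <- c("# Synthetic cohort report", "",
          sprintf("Subjects retained: %d; excluded: %s",
                  length(unique(run$markers$subject)),
                  if (length(run$excluded)) paste(run$excluded, collapse = ", ") else "none"),
          "", "## Self-report metrics (median, Q1-Q3)", "",
          knit_md_table(tabs$self_report),
          "", "## Physiological metrics (mean ± SD)", "",
          knit_md_table(tabs$physiological),
          "", sprintf("Final workload model predictors: %s",
                      paste(run$lmm_final$predictors, collapse = ", ")),
          sprintf("Cluster solution: k = %d, between_SS/total_SS = %.1f%%",
                  run$clusters$k, 100 * run$clusters$between_ratio))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

# minimal markdown table renderer
knit_md_table <- function(df) {
  df <- as.data.frame(df)
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, body)
}
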