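#' Random-intercept mixed model for workload prediction
#'
#' Fits `response ~ predictors + (1 | subject)` by REML with predictors
#' z-scored across all subject-by-condition rows (so coefficients are in
#' score units per SD of marker).  Fixed-effect p-values use Wald t
#' statistics with residual-based degrees of freedom
#' `n_obs - n_fixed - n_groups + 1`.
#'
#' @param data Wide-format data (one row per subject x condition), e.g. from
#'   [marker_table_wide()].
#' @param response Response column name (default "NASA_TLX_Global").
#' @param predictors Character vector of predictor column names.
#' @param grouping Grouping column for the random intercept (default
#'   "subject").
#' @param standardize Z-score predictors before fitting (default `TRUE`).
#' @return A list of class `lmm_fit`: `fixed` (data.frame of estimate, SE,
#'   t, df, CI, p per fixed effect), `subject_var`, `resid_var`, `reml`,
#'   `singular`, `predictors`, plus the underlying `lme4` model.
#' @export
fit_lmm <- function(data, response = "NASA_TLX_Global", predictors,
                    grouping = "subject", standardize = TRUE) {
  df <- as.data.frame(data)
  if (!response %in% names(df)) stop("response column not found: ", response)
  miss <- setdiff(predictors, names(df))
  if (length(miss)) stop("predictor column(s) not found: ", paste(miss, collapse = ", "))
  n_subj <- length(unique(df[[grouping]]))
  if (n_subj < 10) stop("need at least 10 subjects")
  for (p in predictors) {
    if (standardize) {
      s <- stats::sd(df[[p]])
      if (s == 0) stop("predictor has zero variance: ", p)
      df[[p]] <- (df[[p]] - mean(df[[p]])) / s
    }
  }
  if (length(predictors) >= 2 &&
      qr(as.matrix(df[predictors]))$rank < length(predictors))
    stop("rank-deficient design: predictors are exactly collinear")

  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 |", grouping, ")"))
  fit <- lme4::lmer(fml, data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit, tol = 1e-5)

  beta <- lme4::fixef(fit)
  se <- sqrt(Matrix::diag(as.matrix(stats::vcov(fit))))
  n_obs <- nrow(df)
  dfree <- max(1, n_obs - length(beta) - n_subj + 1)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), dfree)
  tcrit <- stats::qt(0.975, dfree)
  vc <- as.data.frame(lme4::VarCorr(fit))
  subject_var <- vc$vcov[vc$grp == grouping][1]
  resid_var <- vc$vcov[vc$grp == "Residual"][1]
  fixed <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), t = unname(tval), df = dfree,
                      ci_lo = unname(beta - tcrit * se),
                      ci_hi = unname(beta + tcrit * se),
                      p = unname(pval), stringsAsFactors = FALSE)
  structure(list(fixed = fixed, subject_var = subject_var,
                 resid_var = resid_var, reml = as.numeric(lme4::REMLcrit(fit)),
                 singular = singular, predictors = predictors,
                 response = response, grouping = grouping,
                 data = df, model = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s ~ %s + (1 | %s)%s\n", x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
              x$grouping, if (x$singular) " [singular]" else ""))
  print(format(x$fixed, digits = 4), row.names = FALSE)
  cat(sprintf("  subject var %.3f, residual var %.3f, REML %.1f\n",
              x$subject_var, x$resid_var, x$reml))
  invisible(x)
}

#' Variance-inflation-factor screen for multicollinearity
#'
#' Computes `VIF_j = 1 / (1 - R2_j)` from regressing each predictor on the
#' others and iteratively drops the largest-VIF predictor until all VIFs are
#' at or below `threshold`.  Perfectly collinear predictors (infinite VIF)
#' are dropped first.
#'
#' @param data Wide-format data containing the predictor columns.
#' @param predictors Character vector of predictor names (>= 2).
#' @param threshold VIF threshold (default 10).
#' @return A list: `retained` (character vector), `dropped` (in drop order),
#'   and `vif` (final VIF table, plus `history` of each round).
#' @export
vif_screen <- function(data, predictors, threshold = 10) {
  if (length(predictors) < 2) stop("need at least 2 predictors")
  df <- as.data.frame(data)[predictors]
  compute_vif <- function(keep) {
    vapply(keep, function(p) {
      X <- as.matrix(df[setdiff(keep, p)])
      fit <- stats::lm.fit(cbind(1, X), df[[p]])
      r2 <- 1 - sum(fit$residuals^2) / sum((df[[p]] - mean(df[[p]]))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  keep <- predictors; dropped <- character(0); history <- list()
  repeat {
    v <- compute_vif(keep)
    history[[length(history) + 1L]] <- v
    if (all(v <= threshold) || length(keep) <= 1L) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
    if (length(keep) == 1L) { history[[length(history) + 1L]] <- stats::setNames(1, keep); break }
  }
  list(retained = keep, dropped = dropped, vif = history[[length(history)]],
       history = history)
}

#' Stepwise backward selection on a fitted mixed model
#'
#' Iteratively refits after removing the predictor with the largest p-value
#' above `alpha`, until every remaining predictor is significant (may return
#' an intercept-only model).
#'
#' @param fit An `lmm_fit`.
#' @param alpha Retention threshold on the fixed-effect p-value (default
#'   0.05).
#' @return The final `lmm_fit`, with `removed` recording the drop order.
#' @export
stepwise_backward <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lmm_fit"))
  removed <- character(0)
  repeat {
    preds <- fit$predictors
    if (!length(preds)) break
    rows <- fit$fixed[fit$fixed$term %in% preds, ]
    if (all(rows$p <= alpha)) break
    worst <- rows$term[which.max(rows$p)]
    removed <- c(removed, worst)
    fit <- fit_lmm(fit$data, fit$response, setdiff(preds, worst),
                   fit$grouping, standardize = FALSE)
  }
  fit$removed <- removed
  fit
}

#' Simulate markers and workload scores from a random-intercept truth model
#'
#' Generates condition-structured synthetic markers for `n_subjects` over
#' three conditions (two active markers carrying opposite-signed condition
#' effects, optional null markers and an optional near-duplicate of the
#' vagal marker), then draws the workload response from the truth model on
#' the z-scored active markers.  Used for parameter-recovery and selection
#' experiments.
#'
#' @param n_subjects Number of subjects (default 34).
#' @param truth A `self_report_truth`.
#' @param n_null Number of null predictor columns (default 3).
#' @param dup_r If non-`NULL`, adds column `HF_WPT3` correlated with
#'   `HF_VFCDM` at this level (e.g. 0.9987) to exercise the VIF screen.
#' @param seed Integer seed.
#' @return A tibble with columns subject, condition, the marker columns and
#'   `NASA_TLX_Global`.
#' @export
simulate_lmm_dataset <- function(n_subjects = 34, truth = self_report_truth(),
                                 n_null = 3, dup_r = NULL, seed = 1L) {
  set.seed(seed)
  conds <- c("Baseline", "EMOT", "COG")
  n <- n_subjects * 3L
  subject <- rep(sprintf("S%02d", seq_len(n_subjects)), each = 3L)
  condition <- rep(conds, n_subjects)
  cond_fx <- c(Baseline = -0.6, EMOT = -0.2, COG = 0.8)
  draw_marker <- function(direction = 1) {
    subj_fx <- stats::rnorm(n_subjects, 0, 0.5)[rep(seq_len(n_subjects), each = 3L)]
    direction * cond_fx[condition] + subj_fx + stats::rnorm(n, 0, 0.6)
  }
  z <- function(v) (v - mean(v)) / stats::sd(v)
  out <- tibble::tibble(subject = subject, condition = condition)
  out$EDA_TVSYMP <- draw_marker(+1)
  out$HF_VFCDM <- draw_marker(-1)
  if (n_null > 0) {
    null_names <- c("EDA_CVX", "EDA_WPT3", "LF_WPT3", "LF_VFCDM")[seq_len(n_null)]
    for (nm in null_names) out[[nm]] <- draw_marker(sample(c(-1, 1), 1))
  }
  if (!is.null(dup_r)) {
    lambda <- sqrt(1 / dup_r^2 - 1)
    out$HF_WPT3 <- z(z(out$HF_VFCDM) + lambda * stats::rnorm(n))
  }
  b <- stats::rnorm(n_subjects, 0, truth$subject_sd)[rep(seq_len(n_subjects), each = 3L)]
  out$NASA_TLX_Global <- truth$intercept +
    truth$beta_tvsymp * z(out$EDA_TVSYMP) + truth$beta_hf * z(out$HF_VFCDM) +
    b + stats::rnorm(n, 0, truth$resid_sd)
  out
}
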