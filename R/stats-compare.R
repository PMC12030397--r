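# Mauchly's test of sphericity and Greenhouse-Geisser epsilon for a
# subjects x conditions matrix (orthonormal contrast form)
sphericity_check <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  Cmat <- stats::contr.helmert(k)
  Cmat <- qr.Q(qr(Cmat))                       # orthonormal contrasts
  S <- stats::cov(Y)
  V <- t(Cmat) %*% S %*% Cmat
  lam <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  eps_gg <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  W <- det(V) / (sum(diag(V)) / (k - 1))^(k - 1)
  dfm <- k - 1
  d <- 1 - (2 * dfm^2 + dfm + 2) / (6 * dfm * (n - 1))
  chi2 <- -(n - 1) * d * log(max(W, .Machine$double.xmin))
  df <- k * (k - 1) / 2 - 1
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  list(W = W, p = p, eps_gg = eps_gg)
}

# one-way repeated-measures ANOVA on a subjects x conditions matrix
rm_anova <- function(Y, gg_correct = FALSE, eps = 1) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fv <- (ss_cond / df1) / (ss_err / df2)
  if (gg_correct) { df1 <- df1 * eps; df2 <- df2 * eps }
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(statistic = Fv, df1 = df1, df2 = df2, p = p)
}

# pairwise Conover post-hoc tests after Friedman (within-block ranks)
conover_pairwise <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  R <- t(apply(Y, 1, rank))
  Rj <- colSums(R)
  Asum <- sum(R^2)
  Bsum <- sum(Rj^2) / n
  df <- (n - 1) * (k - 1)
  denom <- sqrt(2 * n * (Asum - Bsum) / df)
  pairs <- utils::combn(k, 2)
  out <- data.frame(i = pairs[1, ], j = pairs[2, ])
  out$statistic <- (Rj[out$i] - Rj[out$j]) / denom
  out$p <- 2 * stats::pt(-abs(out$statistic), df)
  out
}

#' Assumption-guarded comparison of a marker across conditions
#'
#' If Shapiro-Wilk normality holds in all conditions (alpha = 0.05), runs a
#' one-way repeated-measures ANOVA (Greenhouse-Geisser corrected when
#' Mauchly's sphericity test fails) followed by pairwise paired t-tests;
#' otherwise runs a Friedman test followed by pairwise Conover tests.  The
#' three pairwise p-values are Bonferroni-adjusted (`p_adj = min(1, 3 p)`).
#'
#' @param marker_table A `marker_table` with complete data for `metric`.
#' @param metric Marker name to compare.
#' @param conditions Condition order (default: order of appearance).
#' @return A list of class `comparison_result`: `metric`, `path`
#'   ("parametric"/"nonparametric"), `normality_p`, `sphericity`, `omnibus`
#'   (statistic, df, p), and `pairwise` (data.frame with raw and adjusted p).
#' @export
compare_conditions <- function(marker_table, metric, conditions = NULL) {
  df <- as.data.frame(marker_table)
  df <- df[df$marker == metric, ]
  if (!nrow(df)) stop("metric not found: ", metric)
  if (is.null(conditions)) conditions <- unique(df$condition)
  wide <- stats::reshape(df[c("subject", "condition", "value")],
                         idvar = "subject", timevar = "condition",
                         direction = "wide")
  Y <- as.matrix(wide[paste0("value.", conditions)])
  if (anyNA(Y)) stop("unbalanced data: missing condition values for some subjects")
  colnames(Y) <- conditions
  n <- nrow(Y); k <- ncol(Y)
  if (n < 6) stop("need at least 6 subjects")

  norm_p <- apply(Y, 2, function(v)
    if (stats::sd(v) == 0) 1 else stats::shapiro.test(v)$p.value)
  parametric <- all(norm_p > 0.05)
  pairs <- utils::combn(k, 2)
  pair_names <- apply(pairs, 2, function(ix) paste(conditions[ix], collapse = "-"))

  if (parametric) {
    sph <- if (all(apply(Y, 2, stats::sd) > 0)) sphericity_check(Y)
           else list(W = 1, p = 1, eps_gg = 1)
    omni <- rm_anova(Y, gg_correct = sph$p < 0.05, eps = sph$eps_gg)
    if (!is.finite(omni$statistic)) omni <- list(statistic = 0, df1 = k - 1,
                                                 df2 = (n - 1) * (k - 1), p = 1)
    pw <- data.frame(pair = pair_names,
                     statistic = NA_real_, p_raw = NA_real_)
    for (c_i in seq_len(ncol(pairs))) {
      a <- Y[, pairs[1, c_i]]; b <- Y[, pairs[2, c_i]]
      if (stats::sd(a - b) == 0) { pw$statistic[c_i] <- 0; pw$p_raw[c_i] <- 1 }
      else {
        tst <- stats::t.test(a, b, paired = TRUE)
        pw$statistic[c_i] <- unname(tst$statistic); pw$p_raw[c_i] <- tst$p.value
      }
    }
  } else {
    fr <- stats::friedman.test(Y)
    omni <- list(statistic = unname(fr$statistic), df1 = unname(fr$parameter),
                 df2 = NA_real_, p = fr$p.value)
    cp <- conover_pairwise(Y)
    pw <- data.frame(pair = pair_names, statistic = cp$statistic, p_raw = cp$p)
  }
  pw$p_adj <- pmin(1, ncol(pairs) * pw$p_raw)
  structure(list(metric = metric, path = if (parametric) "parametric" else "nonparametric",
                 normality_p = norm_p,
                 sphericity = if (parametric) sph else NULL,
                 omnibus = omni, pairwise = pw, n = n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (%s path, n = %d)\n", x$metric, x$path, x$n))
  cat(sprintf("  omnibus: stat %.3f, p = %.4g\n", x$omnibus$statistic, x$omnibus$p))
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %s: p_adj = %.4g\n", x$pairwise$pair[i], x$pairwise$p_adj[i]))
  invisible(x)
}
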