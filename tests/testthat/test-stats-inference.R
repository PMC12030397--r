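test_that("identical condition vectors yield a null comparison", {
  set.seed(1)
  v <- stats::rnorm(12)
  Y <- cbind(v, v, v); colnames(Y) <- c("Baseline", "EMOT", "COG")
  res <- compare_conditions(make_marker_table(Y), "M")
  expect_true(res$omnibus$p == 1 || res$omnibus$statistic == 0)
  expect_true(all(res$pairwise$p_adj == 1))
})

test_that("a planted COG shift is detected only in the COG contrasts", {
  set.seed(2)
  n <- 30
  Y <- cbind(stats::rnorm(n), stats::rnorm(n), stats::rnorm(n) + 1.5)
  colnames(Y) <- c("Baseline", "EMOT", "COG")
  res <- compare_conditions(make_marker_table(Y), "M")
  pw <- res$pairwise
  expect_lt(pw$p_adj[pw$pair == "Baseline-COG"], 0.05)
  expect_lt(pw$p_adj[pw$pair == "EMOT-COG"], 0.05)
  expect_gt(pw$p_adj[pw$pair == "Baseline-EMOT"], 0.05)
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p_raw))
})

test_that("heavy-tailed data take the nonparametric path", {
  set.seed(3)
  n_nonpar <- 0
  for (s in 1:20) {
    Y <- matrix(stats::rt(90, df = 2), 30, 3)
    colnames(Y) <- c("Baseline", "EMOT", "COG")
    r <- compare_conditions(make_marker_table(Y), "M")
    n_nonpar <- n_nonpar + (r$path == "nonparametric")
  }
  expect_gte(n_nonpar / 20, 0.9)
  expect_error(compare_conditions(make_marker_table(matrix(1:12, 4, 3),
    conditions = c("A", "B", "C"))[-1, ], "M"), "unbalanced|6 subjects")
})

test_that("Conover statistics follow the rank-sum formula", {
  Y <- matrix(c(1, 2, 3, 2, 3, 1, 3, 1, 2, 1, 3, 2, 2, 1, 3), 5, 3, byrow = TRUE)
  cp <- cogload:::conover_pairwise(Y)
  # hand-computed oracle on within-row ranks
  R <- t(apply(Y, 1, rank)); Rj <- colSums(R)
  denom <- sqrt(2 * 5 * (sum(R^2) - sum(Rj^2) / 5) / (4 * 2))
  expect_equal(cp$statistic[1], (Rj[1] - Rj[2]) / denom)
  expect_equal(cp$p, 2 * stats::pt(-abs(cp$statistic), 8))
})

test_that("the mixed model recovers exact and simulated effects", {
  d <- simulate_lmm_dataset(n_subjects = 20, n_null = 0, seed = 4)
  # exact linear response, no noise: coefficient recovered to machine level
  d$resp <- 3 + 2 * (d$EDA_TVSYMP - mean(d$EDA_TVSYMP)) / stats::sd(d$EDA_TVSYMP)
  # the noise-free response makes the optimizer grumble about identifiability
  fit <- suppressWarnings(fit_lmm(d, response = "resp", predictors = "EDA_TVSYMP"))
  expect_equal(fit$fixed$estimate[2], 2, tolerance = 1e-6)
  expect_lt(fit$resid_var, 1e-10)

  truth <- self_report_truth()
  fit2 <- fit_lmm(simulate_lmm_dataset(n_subjects = 34, n_null = 0, seed = 5),
                  predictors = c("EDA_TVSYMP", "HF_VFCDM"))
  b <- fit2$fixed
  expect_equal(b$estimate[b$term == "EDA_TVSYMP"], truth$beta_tvsymp,
               tolerance = 3 * b$se[b$term == "EDA_TVSYMP"] / truth$beta_tvsymp)
  expect_equal(sign(b$estimate[b$term == "HF_VFCDM"]), -1)
  expect_true(all(c(fit2$subject_var, fit2$resid_var) >= 0))
  expect_equal(b$ci_hi - b$estimate,
               stats::qt(0.975, b$df) * b$se, tolerance = 1e-9)
  expect_error(fit_lmm(d, response = "resp", predictors = "nope"), "not found")
})

test_that("the VIF screen drops collinear predictors by the 1/(1-R2) rule", {
  set.seed(6)
  d <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  v <- vif_screen(d, c("a", "b", "c"))
  expect_setequal(v$retained, c("a", "b", "c"))
  expect_true(all(v$vif < 1.2))

  d$dup <- d$a
  v2 <- vif_screen(d, c("a", "b", "dup"))
  expect_length(v2$dropped, 1)
  expect_true(v2$dropped %in% c("a", "dup"))

  d$near <- d$a + rnorm(100, 0, sqrt(1 / 0.9987^2 - 1))
  r <- stats::cor(d$a, d$near)
  v3 <- vif_screen(d[c("a", "near")], c("a", "near"))
  expect_equal(max(v3$history[[1]]), 1 / (1 - r^2), tolerance = 1e-6)
  expect_length(v3$retained, 1)
})

test_that("stepwise backward selection keeps active and sheds null predictors", {
  d <- simulate_lmm_dataset(n_subjects = 34, n_null = 3, seed = 7)
  nulls <- setdiff(names(d), c("subject", "condition", "EDA_TVSYMP",
                               "HF_VFCDM", "NASA_TLX_Global"))
  fit <- fit_lmm(d, predictors = c("EDA_TVSYMP", "HF_VFCDM", nulls))
  fin <- stepwise_backward(fit)
  expect_true("EDA_TVSYMP" %in% fin$predictors)
  expect_true(all(fin$fixed$p[fin$fixed$term %in% fin$predictors] <= 0.05))

  # fixed point: a single strongly significant predictor survives unchanged
  fit1 <- fit_lmm(d, predictors = "EDA_TVSYMP")
  fin1 <- stepwise_backward(fit1)
  expect_identical(fin1$predictors, "EDA_TVSYMP")
  expect_length(fin1$removed, 0)
})

test_that("k-means profiling recovers planted clusters and decomposes variance", {
  set.seed(8)
  centers <- rbind(c(-1, 1), c(-1, -2), c(1.5, -0.5))
  X <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(30, centers[i, 1], 0.3), rnorm(30, centers[i, 2], 0.3))))
  d <- data.frame(subject = sprintf("S%03d", 1:90), condition = "COG",
                  EDA_TVSYMP = X[, 1], HF_VFCDM = X[, 2])
  sol <- kmeans_profiles(d, seed = 1)
  expect_identical(sol$k, 3L)
  truth <- rep(1:3, each = 30)
  expect_gte(mclust::adjustedRandIndex(sol$assignments, truth), 0.95)
  expect_equal(sol$between_ss + sol$tot_wcss, sol$total_ss, tolerance = 1e-9)
  expect_equal(sol$between_ratio + sol$tot_wcss / sol$total_ss, 1,
               tolerance = 1e-12)

  # row-order invariance up to relabeling
  perm <- sample(nrow(d))
  sol2 <- kmeans_profiles(d[perm, ], seed = 1)
  expect_gte(mclust::adjustedRandIndex(sol2$assignments, truth[perm]), 0.95)

  d0 <- d; d0$EDA_TVSYMP <- 1; d0$HF_VFCDM <- 1
  expect_error(kmeans_profiles(d0, seed = 1), "degenerate")
  expect_error(kmeans_profiles(d[1:5, ], seed = 1), "at least 10")
})
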