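test_that("zero SCR rate with zero noise yields pure tonic output", {
  sch <- contiguous_schedule(c("Baseline", "COG"), 120)
  pars <- list(Baseline = condition_physio_params(scr_rate = 0),
               COG = condition_physio_params(scr_rate = 0))
  eda <- generate_eda(sch, pars, fs = 8, seed = 1, noise_sd = 0)
  expect_true(all(eda$phasic$values == 0))
  expect_equal(eda$signal$values, eda$tonic$values)
})

test_that("a single planted SCR peaks where the biexponential kernel peaks", {
  k <- scr_kernel_params()          # rise 0.7 s, decay 2 s
  # independent oracle: numeric maximization of the kernel
  t_peak <- stats::optimize(function(t) scr_kernel_eval(t, k),
                            c(0, 10), maximum = TRUE)$maximum
  expect_equal(t_peak, 1.131, tolerance = 1e-3)
  tt <- seq(0, 20, by = 1 / 32)
  resp <- scr_kernel_eval(tt - 5, k)
  expect_equal(tt[which.max(resp)] - 5, t_peak, tolerance = 1 / 32)
})

test_that("planted event counts follow the Poisson law", {
  sch <- contiguous_schedule("COG", 600)
  pars <- list(COG = condition_physio_params(scr_rate = 6))
  counts <- vapply(1:20, function(s)
    nrow(generate_eda(sch, pars, fs = 8, seed = s)$events), 0)
  lam <- 60
  ci <- stats::qpois(c(0.005, 0.995), lam)
  expect_true(all(counts >= ci[1] & counts <= ci[2]))
  expect_equal(mean(counts), lam, tolerance = 0.15)
  # exact_counts plants the rounded expectation
  n_ex <- nrow(generate_eda(sch, pars, fs = 8, seed = 1, exact_counts = TRUE)$events)
  expect_identical(n_ex, 60L)
})

test_that("generators reject unknown conditions and bad rates", {
  sch <- contiguous_schedule(c("Baseline", "COG"), 60)
  expect_error(generate_eda(sch, list(Baseline = condition_physio_params()),
                            fs = 8, seed = 1), "no parameters")
  expect_error(condition_physio_params(scr_rate = -1), "scr_rate")
  expect_error(condition_physio_params(lf_amp = 0.6, hf_amp = 0.5), "lf_amp")
})

test_that("constant-rate beat generation gives exactly 1000 ms intervals", {
  sch <- contiguous_schedule("Baseline", 600)
  pars <- list(Baseline = condition_physio_params(mean_hr = 60, lf_amp = 0,
                                                  hf_amp = 0))
  sb <- generate_beats(sch, pars, seed = 1)
  expect_equal(sb$beats$rr_ms, rep(1000, length(sb$beats$rr_ms)),
               tolerance = 1e-6)
  # beat count oracle: integral of a constant rate over 600 s
  expect_true(abs(length(sb$beats$beat_times) - 600) <= 2)
})

test_that("halving HF modulation in one epoch lowers its HF spectral power", {
  sch <- contiguous_schedule(c("Baseline", "COG"), 600)
  pars <- list(Baseline = condition_physio_params(hf_amp = 0.04),
               COG = condition_physio_params(hf_amp = 0.02))
  sb <- generate_beats(sch, pars, seed = 4)
  rr <- rr_to_uniform(sb$beats, 4)
  sl <- segment_epochs(rr, sch, clip = TRUE)
  hf_of <- function(s) band_power(welch_psd(s$values, s$fs), 0.15, 0.40)
  expect_gt(hf_of(sl$Baseline), 2 * hf_of(sl$COG))
})

test_that("beat generation rejects rate-nonpositive modulation", {
  sch <- contiguous_schedule("Baseline", 120)
  p <- condition_physio_params(lf_amp = 0.45, hf_amp = 0.45)
  expect_error(generate_beats(sch, list(Baseline = p), seed = 1),
               "nonpositive")
})

test_that("ectopic injection flags the extrasystole and compensatory pause", {
  sch <- contiguous_schedule("Baseline", 600)
  sb <- generate_beats(sch, list(Baseline = condition_physio_params()), seed = 2)
  same <- inject_ectopics(sb, 0, seed = 1)
  expect_equal(same$beat_times, sb$beats$beat_times)

  ect <- inject_ectopics(sb, 0.01, seed = 1)
  sel <- attr(ect, "ectopic_beats")
  expect_equal(length(sel), round(0.01 * length(sb$beats$beat_times)))
  expect_equal(sum(ect$artifact_flags), 2 * length(sel))
  for (i in sel) {
    # pause after the early beat exceeds both pre-injection neighbours
    expect_gt(ect$rr_ms[i], sb$beats$rr_ms[i])
    expect_gt(ect$rr_ms[i], sb$beats$rr_ms[i - 1])
  }
  # duration preserved
  expect_equal(max(ect$beat_times), max(sb$beats$beat_times))
})

test_that("detector-estimated corruption matches the injected fraction", {
  sch <- contiguous_schedule("Baseline", 600)
  sb <- generate_beats(sch, list(Baseline = condition_physio_params()), seed = 3)
  ect <- inject_ectopics(sb, 0.02, seed = 2)
  rep <- correct_ectopic_beats(ect)$report
  # each injected ectopic corrupts two intervals, so truth-level flagging
  # sits near 2 x 0.02, plus sporadic detector false alarms
  expect_gte(rep$corrupted_fraction, 0.01)
  expect_lte(rep$corrupted_fraction, 0.045)
  expect_error(inject_ectopics(sb, 0.2, seed = 1), "fraction")
})

test_that("degenerate self-report truth returns the bare intercept", {
  Y <- matrix(rnorm(15), 5, 3)
  mt <- rbind(make_marker_table(Y, "EDA_TVSYMP"),
              make_marker_table(matrix(rnorm(15), 5, 3), "HF_VFCDM"))
  class(mt) <- c("marker_table", class(tibble::tibble()))
  truth <- self_report_truth(intercept = 42, beta_tvsymp = 0, beta_hf = 0,
                             subject_sd = 0, resid_sd = 0)
  out <- generate_self_reports(mt, truth, seed = 1)
  sc <- out$value[out$marker == "NASA_TLX_Global"]
  expect_equal(sc, rep(42, length(sc)))
  expect_error(generate_self_reports(make_marker_table(Y, "EDA_TVSYMP")),
               "must contain")
})

test_that("self-report scores carry the signed marker effects", {
  set.seed(11)
  n <- 40
  Y1 <- matrix(rnorm(3 * n), n, 3); Y2 <- matrix(rnorm(3 * n), n, 3)
  mt <- rbind(make_marker_table(Y1, "EDA_TVSYMP"), make_marker_table(Y2, "HF_VFCDM"))
  class(mt) <- c("marker_table", class(tibble::tibble()))
  out <- generate_self_reports(mt, self_report_truth(), seed = 2)
  w <- marker_table_wide(out, c("EDA_TVSYMP", "HF_VFCDM", "NASA_TLX_Global"))
  expect_gt(stats::cor(w$NASA_TLX_Global, w$EDA_TVSYMP), 0)
  expect_lt(stats::cor(w$NASA_TLX_Global, w$HF_VFCDM), 0)
})

test_that("intraclass correlation converges to the planted variance ratio", {
  # betas silenced so the ICC isolates the variance components
  set.seed(12)
  n <- 200
  mt <- rbind(make_marker_table(matrix(rnorm(3 * n), n, 3), "EDA_TVSYMP"),
              make_marker_table(matrix(rnorm(3 * n), n, 3), "HF_VFCDM"))
  class(mt) <- c("marker_table", class(tibble::tibble()))
  truth <- self_report_truth(intercept = 50, beta_tvsymp = 0, beta_hf = 0)
  out <- generate_self_reports(mt, truth, seed = 9)
  w <- marker_table_wide(out, "NASA_TLX_Global")
  fit <- lme4::lmer(NASA_TLX_Global ~ 1 + (1 | subject), data = w, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc <- vc$vcov[1] / sum(vc$vcov)
  expect_equal(icc, 100.2 / (100.2 + 300.4), tolerance = 0.2)
})

test_that("generation is bit-reproducible under a fixed seed", {
  sch <- contiguous_schedule(c("Baseline", "COG"), 120)
  pars <- list(Baseline = condition_physio_params(),
               COG = condition_physio_params(scr_rate = 8))
  e1 <- generate_eda(sch, pars, fs = 8, seed = 42)
  e2 <- generate_eda(sch, pars, fs = 8, seed = 42)
  expect_identical(e1$signal$values, e2$signal$values)
  b1 <- generate_beats(sch, pars, seed = 42)
  b2 <- generate_beats(sch, pars, seed = 42)
  expect_identical(b1$beats$beat_times, b2$beats$beat_times)
  expect_true(all(b1$beats$rr_ms > 0))
})
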