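test_that("resampling preserves DC and pass-band amplitude, kills stop band", {
  n <- 600 * 32
  const <- uniform_signal(rep(2.5, n), 32)
  out <- resample_uniform(const, 2)
  expect_equal(out$fs, 2)
  expect_equal(out$values, rep(2.5, length(out$values)), tolerance = 1e-9)

  tt <- (0:(n - 1)) / 32
  slow <- uniform_signal(sin(2 * pi * 0.05 * tt), 32)
  amp <- function(s) (max(s$values) - min(s$values)) / 2
  expect_equal(amp(resample_uniform(slow, 2)), 1, tolerance = 0.01)

  fast <- uniform_signal(sin(2 * pi * 0.9 * tt), 32)
  out_f <- resample_uniform(fast, 2)$values
  interior <- out_f[80:(length(out_f) - 80)]   # clear of filter edge bursts
  expect_lt((max(interior) - min(interior)) / 2, 0.1)

  expect_error(resample_uniform(out, 8), "upsampling")
  expect_error(resample_uniform(out, 0), "positive")
})

test_that("high-pass removes DC and trends but keeps the sudomotor band", {
  n <- 2400; fs <- 2; tt <- (0:(n - 1)) / fs
  expect_lt(max(abs(highpass_eda(uniform_signal(rep(3, n), fs))$values)), 1e-6)
  v <- sin(2 * pi * 0.2 * tt)
  tone <- highpass_eda(uniform_signal(v, fs))
  i <- 400:(n - 400)                  # the 0.01 Hz transient decays over ~100 s
  expect_lt(sqrt(mean((tone$values[i] - v[i])^2)) / sqrt(mean(v[i]^2)), 0.02)
  ramp <- highpass_eda(uniform_signal(seq(0, 5, length.out = n), fs))
  expect_lt(abs(mean(ramp$values)), 0.01 * 5)
})

test_that("EDA quality screening applies the strict 2% discard rule", {
  cohort <- short_session(epoch_duration = 120)
  clean <- cohort$subjects[[1]]$eda$signal
  qc <- screen_eda_quality(clean)
  expect_lt(qc$corrupted_fraction, 0.02)
  expect_false(qc$discarded)

  v <- clean$values
  n <- length(v)
  idx <- seq(10, n - 10, length.out = round(0.05 * n))
  v[idx] <- 80                                # out-of-range spikes
  expect_true(screen_eda_quality(uniform_signal(v, clean$fs))$discarded)

  # exactly 2% flagged is retained ("more than 2%" is strict)
  r <- quality_report(0.02, rep(FALSE, 100))
  expect_false(r$discarded)
  expect_true(quality_report(0.020001, rep(FALSE, 100))$discarded)
})

test_that("ectopic correction restores injected beats and is idempotent", {
  sch <- contiguous_schedule("Baseline", 600)
  sb <- generate_beats(sch, list(Baseline = condition_physio_params()), seed = 6)
  clean <- correct_ectopic_beats(sb$beats)
  expect_equal(clean$report$corrupted_fraction, 0)
  expect_equal(clean$beats$rr_ms, sb$beats$rr_ms)

  ect <- inject_ectopics(sb, 1 / length(sb$beats$beat_times) * 1.5, seed = 3)
  sel <- attr(ect, "ectopic_beats")
  expect_gte(length(sel), 1)
  corr <- correct_ectopic_beats(ect)
  flagged <- which(corr$report$mask)
  expect_true(all(c(sel - 1, sel) %in% flagged))
  # corrected values near the pre-injection truth
  err <- abs(corr$beats$rr_ms[flagged] - sb$beats$rr_ms[flagged])
  expect_lt(max(err), 50)
  # idempotent on its own output
  again <- correct_ectopic_beats(corr$beats)
  expect_equal(again$beats$rr_ms, corr$beats$rr_ms, tolerance = 1e-9)
})

test_that("3% injected ectopics trigger the RR discard rule", {
  sch <- contiguous_schedule("Baseline", 600)
  sb <- generate_beats(sch, list(Baseline = condition_physio_params()), seed = 7)
  ect <- inject_ectopics(sb, 0.03, seed = 4)
  expect_true(correct_ectopic_beats(ect)$report$discarded)
})

test_that("RR interpolation preserves constants and modulation frequency", {
  bt <- cumsum(rep(1, 300))
  const <- rr_to_uniform(beat_series(bt), 4)
  expect_equal(const$values, rep(1000, length(const$values)), tolerance = 1e-9)

  sch <- contiguous_schedule("Baseline", 600)
  sb <- generate_beats(sch, list(Baseline = condition_physio_params(
    lf_amp = 0.05, hf_amp = 0)), seed = 8, pure_tones = TRUE)
  rr <- rr_to_uniform(sb$beats, 4)
  w <- welch_psd(rr$values - mean(rr$values), 4, seg_len_s = 150)
  expect_equal(w$freq[which.max(w$psd)], 0.10, tolerance = 0.02)

  # 4 Hz then decimation to 1 Hz agrees with direct 1 Hz interpolation
  rr1a <- resample_uniform(rr, 1)
  rr1b <- rr_to_uniform(sb$beats, 1)
  m <- min(length(rr1a$values), length(rr1b$values))
  i <- 10:(m - 10)
  expect_lt(sqrt(mean((rr1a$values[i] - rr1b$values[i])^2)), 1)
  expect_error(rr_to_uniform(beat_series(c(0, 1, 2)), 4), "at least 4")
})

test_that("epoch segmentation slices half-open intervals exactly", {
  x <- uniform_signal(rep(c(1, 2, 3), each = 600), 1)
  sch <- contiguous_schedule(c("A", "B", "C"), 600)
  sl <- segment_epochs(x, sch)
  expect_equal(vapply(sl, function(s) length(s$values), 0L),
               c(A = 600L, B = 600L, C = 600L))
  expect_equal(vapply(sl, function(s) mean(s$values), 0), c(A = 1, B = 2, C = 3))
  expect_error(epoch_schedule(c("A", "B"), c(0, 500), c(600, 1100)), "overlap")
  expect_error(segment_epochs(x, contiguous_schedule("A", 2000)), "support")
})

test_that("decimation and segmentation commute", {
  cohort <- short_session(epoch_duration = 120, seed = 9)
  x <- cohort$subjects[[1]]$eda$signal
  sch <- cohort$schedule
  a <- segment_epochs(resample_uniform(x, 2), sch, clip = TRUE)
  b <- lapply(segment_epochs(x, sch), resample_uniform, target_fs = 2)
  for (cn in names(a)) {
    m <- min(length(a[[cn]]$values), length(b[[cn]]$values))
    i <- 30:(m - 30)   # away from the per-slice filter edges
    expect_equal(a[[cn]]$values[i], b[[cn]]$values[i], tolerance = 0.02)
  }
})
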