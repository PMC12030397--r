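test_that("image selection equals an independent brute-force filter", {
  rt <- synthetic_ratings_table(1000, seed = 2)
  sel <- select_affective_images(rt, seed = 3)
  r <- as.data.frame(rt)
  s1 <- r[abs(r$valence_female - r$valence_male) < 1 &
          abs(r$arousal_female - r$arousal_male) < 0.8, ]
  ok <- s1$valence_sd < 2 & s1$arousal_sd < 2.23 &
    !s1$explicit_violence & !s1$sexually_explicit
  oracle <- list(
    PVHA = s1$image_id[ok & s1$valence_mean > 6 & s1$arousal_mean > 6],
    PVLA = s1$image_id[ok & s1$valence_mean > 6 & s1$arousal_mean < 4],
    NVHA = s1$image_id[ok & s1$valence_mean < 4.3 & s1$arousal_mean > 6],
    NVLA = s1$image_id[ok & s1$valence_mean < 4.3 & s1$arousal_mean < 4])
  pools <- attr(sel, "pools")
  for (g in names(oracle)) {
    expect_setequal(pools[[g]], oracle[[g]])
    expect_length(sel[[g]], 10)
    expect_true(all(sel[[g]] %in% oracle[[g]]))
  }
  # groups are disjoint
  expect_identical(anyDuplicated(unlist(sel)), 0L)
})

test_that("candidate pools are seed-invariant, only the draw changes", {
  rt <- synthetic_ratings_table(1000, seed = 2)
  a <- select_affective_images(rt, seed = 1)
  b <- select_affective_images(rt, seed = 99)
  expect_identical(attr(a, "pools"), attr(b, "pools"))
  expect_false(identical(a$PVHA, b$PVHA))
})

test_that("boundary images fall outside the strict inequalities", {
  rt <- synthetic_ratings_table(400, seed = 4)
  rt$valence_female[1] <- 5; rt$valence_male[1] <- 4   # difference exactly 1
  rt$arousal_female[1] <- rt$arousal_male[1]
  sel <- tryCatch(select_affective_images(rt, seed = 1),
                  error = function(e) NULL)
  if (!is.null(sel))
    expect_false(rt$image_id[1] %in% unlist(attr(sel, "pools")))
  expect_error(select_affective_images(rt[0, ], seed = 1), "empty")
})

test_that("the slideshow has 40 stimuli over 10 min in the printed block order", {
  groups <- structure(lapply(c(PVHA = 1, PVLA = 2, NVHA = 3, NVLA = 4),
                             function(i) sprintf("g%d_%02d", i, 1:10)),
                      class = "stimulus_groups")
  show <- build_slideshow(groups, seed = 5)
  expect_equal(nrow(show), 40)
  expect_equal(max(show$offset_s) + 10 - min(show$onset_s), 600)
  expect_equal(unique(show$block),
               c("PVHA-1", "PVLA-1", "NVHA-1", "NVLA-1",
                 "PVHA-2", "PVLA-2", "NVHA-2", "NVLA-2"))
  expect_true(all(show$offset_s - show$onset_s == 5))
  expect_true(all(diff(show$onset_s) == 15))
  # gap consistency: next onset follows 10 s after each offset
  expect_true(all(show$onset_s[-1] - show$offset_s[-40] == 10))
  short <- groups; short$PVHA <- short$PVHA[1:9]
  expect_error(build_slideshow(short), "exactly 10")
})

test_that("2-back streams honor the target rate and the letter set", {
  log0 <- generate_nback_sequence(60, 0, seed = 6)
  expect_false(any(log0$is_target))
  expect_true(all(log0$letter %in% NBACK_LETTERS))

  log <- generate_nback_sequence(120, 0.25, seed = 7)
  brute <- c(FALSE, FALSE, log$letter[3:120] == log$letter[1:118])
  expect_identical(log$is_target, brute)
  expect_equal(sum(log$is_target), round(0.25 * 118))
  expect_equal(diff(log$onset_s), rep(3, 119))
  expect_error(generate_nback_sequence(5, 0.2), ">= 10")
  expect_error(generate_nback_sequence(60, 0.7), "target_rate")
})

test_that("scoring matches hand-computed oracles", {
  log <- generate_nback_sequence(30, 0.25, seed = 8)
  # perfect responder at exactly 500 ms
  log$pressed <- log$is_target
  log$rt_ms <- ifelse(log$is_target, 500, NA_real_)
  s <- score_nback(log)
  expect_equal(s$accuracy_pct, 100)
  expect_equal(s$mean_rt_ms, 500)
  expect_equal(s$omissions, 0)
  expect_equal(s$false_alarms, 0)

  # silent responder
  log$pressed <- FALSE; log$rt_ms <- NA_real_
  s0 <- score_nback(log)
  expect_equal(s0$hits, 0)
  expect_equal(s0$omissions, sum(log$is_target))
  expect_equal(s0$accuracy_pct, 100 * mean(!log$is_target))

  # mixed constructed log against a brute-force oracle
  set.seed(9)
  log$pressed <- stats::runif(30) < 0.5
  log$rt_ms <- ifelse(log$pressed, stats::runif(30, 300, 3000), NA_real_)
  s2 <- score_nback(log, response_window = 2500)
  hit <- log$is_target & log$pressed & log$rt_ms <= 2500
  expect_equal(s2$hits, sum(hit, na.rm = TRUE))
  expect_equal(s2$false_alarms, sum(!log$is_target & log$pressed))
  expect_equal(s2$omissions, sum(log$is_target) - s2$hits)
  expect_equal(s2$accuracy_pct,
               100 * (s2$hits + sum(!log$is_target & !log$pressed)) / 30)
  expect_equal(s2$mean_rt_ms, mean(log$rt_ms[which(hit)]))
  expect_error(score_nback(log[0, ]), "empty")
})
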