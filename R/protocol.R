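#' The 15-letter stimulus set of the 2-back task
#' @export
NBACK_LETTERS <- c("A", "B", "C", "D", "E", "H", "I", "K", "L", "M",
                   "O", "P", "R", "S", "T")

#' Published valence-arousal image selections by category
#'
#' Identifiers of normatively rated affective images (IAPS bank) grouped
#' into the four valence-arousal categories, for users who hold an IAPS
#' license; the package never ships images or ratings.
#' @export
IAPS_IMAGE_SETS <- list(
  PVHA = c(1650, 4608, 4643, 4660, 5621, 5629, 8030, 8158, 8191, 8206),
  PVLA = c(1333, 1419, 1670, 1812, 2035, 2358, 2392, 2500, 2515, 2598),
  NVHA = c(1300, 1930, 3500, 3530, 6231, 6260, 6563, 8485, 9910, 9630),
  NVLA = c(2039, 2271, 2280, 2312, 2410, 2491, 2520, 2752, 7013, 7078))

#' Generate a synthetic normative-ratings table
#'
#' Stand-in for a licensed affective-image ratings bank: uniform valence and
#' arousal means in [1, 9], gender-specific means jittered around the
#' overall mean, rating SDs spanning the filter thresholds, and rare content
#' flags.  Synthetic by construction; only its schema matches real banks.
#'
#' @param n Number of images (default 1000).
#' @param seed Integer seed.
#' @return A tibble of class `ratings_table`.
#' @export
synthetic_ratings_table <- function(n = 1000, seed = 1L) {
  set.seed(seed)
  val <- stats::runif(n, 1, 9); aro <- stats::runif(n, 1, 9)
  out <- tibble::tibble(
    image_id = sprintf("img%04d", seq_len(n)),
    valence_mean = val,
    valence_female = val + stats::rnorm(n, 0, 0.45),
    valence_male = val + stats::rnorm(n, 0, 0.45),
    arousal_mean = aro,
    arousal_female = aro + stats::rnorm(n, 0, 0.35),
    arousal_male = aro + stats::rnorm(n, 0, 0.35),
    valence_sd = stats::runif(n, 0.8, 2.6),
    arousal_sd = stats::runif(n, 0.8, 2.8),
    explicit_violence = stats::runif(n) < 0.02,
    sexually_explicit = stats::runif(n) < 0.02)
  clip9 <- function(v) pmin(9, pmax(1, v))
  for (cl in c("valence_female", "valence_male", "arousal_female", "arousal_male"))
    out[[cl]] <- clip9(out[[cl]])
  class(out) <- c("ratings_table", class(out))
  out
}

#' Four-step affective image selection
#'
#' Step 1 minimizes gender effects: images with a female-male difference in
#' mean valence below 1 and in mean arousal below 0.8 (strict inequalities).
#' Step 2 builds four valence-arousal groups with rating-consistency filters
#' (valence SD < 2 and arousal SD < 2.23, both required):
#' PVHA valence > 6 and arousal > 6; PVLA valence > 6 and arousal < 4;
#' NVHA valence < 4.3 and arousal > 6; NVLA valence < 4.3 and arousal < 4.
#' Step 3 removes explicit-violence and sexually explicit content, then 10
#' images are drawn uniformly at random per group.
#'
#' @param ratings A `ratings_table`.
#' @param seed Integer seed for the final draw.
#' @param n_per_group Images per group (default 10).
#' @return A list of class `stimulus_groups` with the four id vectors;
#'   attribute `counts` holds per-step surviving counts per group.
#' @export
select_affective_images <- function(ratings, seed = 1L, n_per_group = 10) {
  if (!nrow(ratings)) stop("empty ratings table")
  need <- c("image_id", "valence_mean", "valence_female", "valence_male",
            "arousal_mean", "arousal_female", "arousal_male",
            "valence_sd", "arousal_sd", "explicit_violence", "sexually_explicit")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) stop("ratings table lacks column(s): ", paste(miss, collapse = ", "))
  r <- as.data.frame(ratings)

  step1 <- r[abs(r$valence_female - r$valence_male) < 1 &
             abs(r$arousal_female - r$arousal_male) < 0.8, ]
  sd_ok <- step1$valence_sd < 2 & step1$arousal_sd < 2.23
  crit <- list(
    PVHA = step1$valence_mean > 6 & step1$arousal_mean > 6,
    PVLA = step1$valence_mean > 6 & step1$arousal_mean < 4,
    NVHA = step1$valence_mean < 4.3 & step1$arousal_mean > 6,
    NVLA = step1$valence_mean < 4.3 & step1$arousal_mean < 4)
  counts <- list(step1 = nrow(step1))
  pools <- list()
  for (g in names(crit)) {
    pre <- step1[crit[[g]], ]
    post <- step1[crit[[g]] & sd_ok, ]
    post <- post[!post$explicit_violence & !post$sexually_explicit, ]
    counts[[g]] <- c(value_filter = nrow(pre), sd_content_filter = nrow(post))
    if (nrow(post) < n_per_group)
      stop(sprintf("group %s has only %d candidates (< %d)", g, nrow(post), n_per_group))
    pools[[g]] <- post$image_id
  }
  set.seed(seed)
  groups <- lapply(pools, function(p) sort(sample(p, n_per_group)))
  structure(groups, class = "stimulus_groups", counts = counts, pools = pools)
}

#' Assemble the emotional slideshow schedule
#'
#' Each 10-image group is split into two blocks of 5; the 8 blocks follow
#' the order PVHA-1, PVLA-1, NVHA-1, NVLA-1, PVHA-2, PVLA-2, NVHA-2, NVLA-2.
#' Each stimulus is displayed for 5 s followed by a 10 s inter-stimulus
#' interval, giving a 40-stimulus, 600 s (10 min) schedule.
#'
#' @param groups A `stimulus_groups` (10 ids per group).
#' @param seed Seed for the within-group ordering.
#' @return A tibble (`image_id`, `group`, `block`, `onset_s`, `offset_s`).
#' @export
build_slideshow <- function(groups, seed = 1L) {
  gnames <- c("PVHA", "PVLA", "NVHA", "NVLA")
  if (!all(gnames %in% names(groups))) stop("groups must contain PVHA, PVLA, NVHA, NVLA")
  if (any(vapply(groups[gnames], length, 0L) != 10))
    stop("each group must contain exactly 10 images")
  set.seed(seed)
  shuffled <- lapply(groups[gnames], sample)
  blocks <- list()
  for (half in 1:2)
    for (g in gnames)
      blocks[[paste0(g, "-", half)]] <-
        shuffled[[g]][(5 * (half - 1) + 1):(5 * half)]
  ids <- unlist(blocks, use.names = FALSE)
  block_lab <- rep(names(blocks), each = 5)
  onset <- (seq_along(ids) - 1) * 15
  tibble::tibble(image_id = ids,
                 group = sub("-.*", "", block_lab), block = block_lab,
                 onset_s = onset, offset_s = onset + 5)
}

#' Generate a 2-back letter stream with controlled target rate
#'
#' Letters are drawn from the 15-letter stimulus set; target positions
#' (letter identical to the one two positions earlier) are planted so the
#' realized 2-back-match count equals `round(target_rate * (length - 2))`.
#' Trials are spaced 3 s apart (500 ms display + 2500 ms inter-trial
#' interval).
#'
#' @param length Number of trials (>= 10).
#' @param target_rate Desired fraction of 2-back targets, in (0, 0.5); 0 is
#'   allowed and yields a match-free stream.
#' @param seed Integer seed.
#' @return A tibble of class `nback_log` (`trial`, `letter`, `onset_s`,
#'   `is_target`).
#' @export
generate_nback_sequence <- function(length, target_rate = 0.25, seed = 1L) {
  if (length < 10) stop("length must be >= 10")
  if (target_rate < 0 || target_rate >= 0.5)
    stop("target_rate must lie in [0, 0.5)")
  set.seed(seed)
  n_targets <- round(target_rate * (length - 2))
  targets <- sort(sample(3:length, n_targets))
  letters_out <- character(length)
  letters_out[1:2] <- sample(NBACK_LETTERS, 2, replace = TRUE)
  for (i in 3:length) {
    if (i %in% targets) letters_out[i] <- letters_out[i - 2]
    else letters_out[i] <- sample(setdiff(NBACK_LETTERS, letters_out[i - 2]), 1)
  }
  is_target <- c(FALSE, FALSE,
                 letters_out[3:length] == letters_out[1:(length - 2)])
  out <- tibble::tibble(trial = seq_len(length), letter = letters_out,
                        onset_s = (seq_len(length) - 1) * 3,
                        is_target = is_target)
  class(out) <- c("nback_log", class(out))
  out
}

#' Score a completed 2-back log
#'
#' A hit is a press within `response_window` after a target onset; a target
#' without a press (or with a press outside the window) is an omission; a
#' press on a non-target is a false alarm.  Accuracy is
#' `(hits + correct rejections) / trials` in percent; reaction times are
#' summarized over hits only.
#'
#' @param log An `nback_log` augmented with `pressed` (logical) and `rt_ms`
#'   (reaction time in ms, `NA` when no press).
#' @param response_window Response window in ms (default 2500, the
#'   inter-trial interval).
#' @return A list: `n_trials`, `n_targets`, `hits`, `omissions`,
#'   `false_alarms`, `accuracy_pct`, `mean_rt_ms`, `sd_rt_ms`.
#' @export
score_nback <- function(log, response_window = 2500) {
  if (!nrow(log)) stop("empty log")
  need <- c("is_target", "pressed", "rt_ms")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("log lacks column(s): ", paste(miss, collapse = ", "))
  hit <- log$is_target & log$pressed & !is.na(log$rt_ms) & log$rt_ms <= response_window
  omission <- log$is_target & !hit
  fa <- !log$is_target & log$pressed
  cr <- !log$is_target & !log$pressed
  rts <- log$rt_ms[hit]
  list(n_trials = nrow(log), n_targets = sum(log$is_target),
       hits = sum(hit), omissions = sum(omission), false_alarms = sum(fa),
       accuracy_pct = 100 * (sum(hit) + sum(cr)) / nrow(log),
       mean_rt_ms = if (length(rts)) mean(rts) else NA_real_,
       sd_rt_ms = if (length(rts) > 1) stats::sd(rts) else NA_real_)
}
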