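test_that("p_low_mean and p_high_info count eligible first choices", {
  fc <- make_fc(10, info_condition = "22", chose_low_mean = FALSE)
  expect_equal(p_low_mean(fc, 6), 0)
  fc$chose_low_mean[1:3] <- TRUE
  expect_equal(p_low_mean(fc, 6), 0.3)
  # ties only -> undefined
  fc$chose_low_mean <- NA
  expect_true(is.na(p_low_mean(fc, 6)))

  hi <- make_fc(10, info_condition = "13", delta_I = 1L,
                chose_high_info = FALSE, chose_low_mean = NA)
  expect_equal(p_high_info(hi, 6), 0)
  hi$chose_high_info[1:6] <- TRUE
  expect_equal(p_high_info(hi, 6), 0.6)
  expect_true(is.na(p_high_info(make_fc(5, info_condition = "22"), 6)))
})

test_that("p_inconsistent counts disagreeing pairs", {
  fc <- make_fc(32, pair_id = rep(1:16, each = 2), chose_right = TRUE)
  expect_equal(p_inconsistent(fc, 6, "22"), 0)
  # flip one member of 4 of the 16 pairs
  fc$chose_right[c(1, 3, 5, 7)] <- FALSE
  expect_equal(p_inconsistent(fc, 6, "22"), 0.25)
  expect_true(is.na(p_inconsistent(fc, 1, "22")))
  expect_true(is.na(p_inconsistent(make_fc(4), 6, "22")))
})

test_that("independent fair-coin choices give about half inconsistency", {
  set.seed(31)
  n_pairs <- 4000
  fc <- make_fc(2 * n_pairs, pair_id = rep(seq_len(n_pairs), each = 2))
  fc$chose_right <- runif(nrow(fc)) < 0.5
  expect_lt(abs(p_inconsistent(fc, 6, "22") - 0.5),
            3 * sqrt(0.25 / n_pairs))
})

test_that("pure-random prediction maps stratum probabilities through 2p(1-p)", {
  base <- make_fc(20, delta_R = 5, pair_id = rep(1:10, each = 2))
  # p = 0.5 in the single stratum
  fc <- base; fc$chose_low_mean <- rep(c(TRUE, FALSE), 10)
  expect_equal(pure_random_prediction(fc, 6, "22"), 0.5)
  # p = 0 -> prediction 0
  fc$chose_low_mean <- FALSE
  expect_equal(pure_random_prediction(fc, 6, "22"), 0)
  # single stratum with p = 0.2: two independent choices disagree
  # with probability 2 * 0.2 * 0.8 (enumerating LL, LH, HL, HH)
  fc$chose_low_mean <- rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 4)
  expect_equal(pure_random_prediction(fc, 6, "22"), 2 * 0.2 * 0.8)
  expect_lte(pure_random_prediction(fc, 6, "22"), 0.5)
})

test_that("pure-random prediction is invariant to merging equal-p strata", {
  # two |delta_R| strata with identical p: prediction equals single-stratum value
  fc <- make_fc(40, delta_R = rep(c(2, 10), each = 20),
                pair_id = rep(1:20, each = 2))
  fc$chose_low_mean <- rep(c(TRUE, FALSE, FALSE, FALSE), 10)
  p <- 0.25
  expect_equal(pure_random_prediction(fc, 6, "22", n_bins = 2),
               2 * p * (1 - p), tolerance = 1e-12)
  expect_equal(pure_random_prediction(fc, 6, "22", n_bins = 1),
               2 * p * (1 - p), tolerance = 1e-12)
})

test_that("model_free_stats assembles per-subject rows with predictions", {
  set.seed(32)
  cfg <- mini_cfg(n_games = 48, repeat_fraction = 5 / 6)
  pars <- lapply(1:3, function(i) flat_params(sigma_det = 2, sigma_ran = 5))
  fc <- first_free_choices(simulate_cohort(pars, cfg))
  mf <- model_free_stats(fc)
  expect_equal(nrow(mf), 6L)
  expect_true(all(mf$pred_deterministic == 0))
  ok <- !is.na(mf$pred_random_22)
  expect_true(any(ok))
  expect_true(all(mf$pred_random_22[ok] <= 0.5))
  probs <- c(mf$p_low_mean, mf$p_high_info, mf$p_inconsistent_13,
             mf$p_inconsistent_22)
  expect_true(all(probs >= 0 & probs <= 1, na.rm = TRUE))
})

test_that("horizon_contrast is a two-sided paired t-test", {
  df <- data.frame(subject_id = rep(sprintf("s%d", 1:10), 2),
                   horizon = rep(c(1, 6), each = 10),
                   p_low_mean = c(seq(0.1, 0.3, length.out = 10),
                                  seq(0.1, 0.3, length.out = 10)))
  hc <- horizon_contrast(df)
  expect_equal(hc$t, 0)
  expect_equal(hc$df, 9)
  # cross-check against t.test on the differences
  set.seed(33)
  df$p_low_mean[11:20] <- df$p_low_mean[11:20] + rnorm(10, 0.1, 0.05)
  hc2 <- horizon_contrast(df)
  ref <- t.test(df$p_low_mean[11:20] - df$p_low_mean[1:10])
  expect_equal(hc2$t, unname(ref$statistic))
  expect_equal(hc2$p_value, ref$p.value)
  # constant nonzero difference: degenerate, flagged
  df$p_low_mean[11:20] <- df$p_low_mean[1:10] + 0.2
  hc3 <- horizon_contrast(df)
  expect_true(hc3$degenerate)
  expect_equal(hc3$t, Inf)
  expect_error(horizon_contrast(df[c(1, 11), ]), "2 subjects")
})

test_that("paired horizon contrast detects a known shift at closed-form power", {
  set.seed(34)
  n <- 20; d <- 0.1; s <- 0.15; reps <- 200
  rej <- mean(replicate(reps, {
    diffs <- rnorm(n, d, s)
    df <- data.frame(subject_id = rep(sprintf("s%d", 1:n), 2),
                     horizon = rep(c(1, 6), each = n),
                     p_low_mean = c(rep(0.2, n), 0.2 + diffs))
    horizon_contrast(df)$p_value < 0.05
  }))
  pow <- power.t.test(n = n, delta = d, sd = s, type = "paired")$power
  expect_gt(rej, pow - 3 * sqrt(pow * (1 - pow) / reps))
})

test_that("exclusion rule applies the exact binomial criterion", {
  set.seed(35)
  make_subject <- function(id, n_correct, n = 60) {
    correct <- c(rep(TRUE, n_correct), rep(FALSE, n - n_correct))
    games <- lapply(seq_len(n), function(g) {
      make_game_trials(subject_id = id, game_id = g, horizon = 6L,
                       forced_rewards = c(60, 60, 40, 40),
                       free_sides = c(rep("left", 5),
                                      ifelse(correct[g], "left", "right")),
                       free_rewards = rep(50, 6))
    })
    do.call(bind_trials, games)
  }
  # generative means via games table: left is better in every game
  games_truth <- data.frame(game_id = 1:60, mean_left = 60, mean_right = 40)
  trials <- bind_trials(make_subject("hit", 60), make_subject("chance", 30),
                        make_subject("edge", 41))
  res <- exclude_subjects(trials, games = games_truth)
  s <- res$summary
  expect_true(s$kept[s$subject_id == "hit"])
  expect_false(s$kept[s$subject_id == "chance"])
  edge_p <- s$p_value[s$subject_id == "edge"]
  expect_equal(edge_p, pbinom(40, 60, 0.5, lower.tail = FALSE))
  expect_false(s$kept[s$subject_id == "edge"]) # p ~ 0.0034 >= 0.001
  # subject with no horizon-6 games is excluded with a reason
  h1 <- make_game_trials(subject_id = "noh6", horizon = 1L)
  res2 <- exclude_subjects(bind_trials(trials, h1), games = games_truth)
  expect_match(res2$summary$reason[res2$summary$subject_id == "noh6"],
               "no horizon-6")
})
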