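test_that("task_config validates its invariants", {
  expect_s3_class(task_config(), "horizon_task_config")
  expect_equal(task_config()$n_pairs, 65L)
  expect_error(task_config(reward_sd = 0), "reward_sd")
  expect_error(task_config(n_games = 1), "n_games")
  expect_error(task_config(min_pair_separation = 0), "min_pair_separation")
  expect_error(task_config(horizons = c(1, 3)), "horizons")
  expect_error(task_config(repeat_fraction = 1.2), "repeat_fraction")
})

test_that("generated games respect the payoff design", {
  set.seed(11)
  cfg <- task_config()
  for (i in 1:50) {
    g <- generate_game(cfg, horizon = sample(c(1, 6), 1),
                       info_condition = sample(c("13", "22"), 1))
    expect_true(abs(g$mean_left - g$mean_right) %in% c(4, 8, 12, 20))
    expect_true(g$mean_left %in% c(40, 60) || g$mean_right %in% c(40, 60))
    fs <- g$forced_sides[[1]]
    fr <- g$forced_rewards[[1]]
    expect_length(fs, 4L)
    if (g$info_condition == "22") {
      expect_equal(sum(fs == "right"), 2L)
    } else {
      expect_true(sum(fs == "right") %in% c(1L, 3L))
    }
    expect_true(all(fr >= 1 & fr <= 100))
    expect_true(all(fr == round(fr)))
  }
  expect_error(generate_game(cfg, horizon = 3, info_condition = "22"),
               "horizon")
  expect_error(generate_game(cfg, horizon = 1, info_condition = "31"),
               "info condition")
})

test_that("degenerate mean-difference config gives equal means", {
  set.seed(12)
  cfg <- task_config(mean_diffs = 0)
  g <- generate_game(cfg, 1, "22")
  expect_equal(g$mean_left, g$mean_right)
})

test_that("forced rewards follow the bandit Gaussian (Monte-Carlo moments)", {
  set.seed(13)
  cfg <- task_config(mean_anchors = 60, mean_diffs = 0)
  rewards <- unlist(lapply(1:2500, function(i) {
    generate_game(cfg, 1, "22")$forced_rewards[[1]]
  }))
  expect_length(rewards, 10000L)
  se <- 8 / sqrt(length(rewards))
  expect_lt(abs(mean(rewards) - 60), 3 * se)
})

test_that("sessions duplicate pairs exactly and respect separation", {
  set.seed(14)
  cfg <- task_config()
  games <- generate_session(cfg)
  expect_equal(nrow(games), 156L)
  pairs <- unique(na.omit(games$pair_id))
  expect_length(pairs, 65L)
  expect_equal(sum(is.na(games$pair_id)), 26L)
  for (p in pairs) {
    two <- games[which(games$pair_id == p), ]
    expect_equal(two$repeat_index, c(1L, 2L))
    expect_equal(two$mean_left[1], two$mean_left[2])
    expect_equal(two$mean_right[1], two$mean_right[2])
    expect_identical(two$forced_sides[[1]], two$forced_sides[[2]])
    expect_identical(two$forced_rewards[[1]], two$forced_rewards[[2]])
    expect_equal(two$horizon[1], two$horizon[2])
    expect_equal(two$info_condition[1], two$info_condition[2])
    expect_gte(abs(diff(which(games$pair_id == p))) - 1L, 10L)
  }
})

test_that("session composition is counterbalanced when divisibility permits", {
  set.seed(15)
  # 64 pairs + 32 unpaired = 160 games spread over 16 design cells exactly
  cfg <- task_config(n_games = 160, repeat_fraction = 0.8)
  games <- generate_session(cfg)
  tab <- table(games$horizon, games$info_condition)
  expect_true(all(tab == 40L))
})

test_that("infeasible separation constraints raise a generation error", {
  set.seed(16)
  cfg <- task_config(n_games = 4, repeat_fraction = 1,
                     min_pair_separation = 50)
  expect_error(generate_session(cfg), "separation")
})

test_that("first free choices encode delta_R, delta_I and the choice flags", {
  # left forced mean 50, right forced mean 40, trial-5 choice right
  tr <- make_game_trials(forced_sides = c("left", "left", "right", "right"),
                         forced_rewards = c(50, 50, 40, 40),
                         free_sides = "right")
  fc <- first_free_choices(tr)
  expect_equal(fc$delta_R, -10)
  expect_equal(fc$delta_I, 0L)
  expect_true(fc$chose_low_mean)
  expect_true(is.na(fc$chose_high_info))

  # [1 3] game: left played once, trial-5 choice left -> high info, dI = -1
  tr13 <- make_game_trials(info_condition = "13",
                           forced_sides = c("left", "right", "right", "right"),
                           forced_rewards = c(42, 55, 60, 50),
                           free_sides = "left")
  fc13 <- first_free_choices(tr13)
  expect_equal(fc13$delta_I, -1L)
  expect_true(fc13$chose_high_info)
  expect_equal(fc13$delta_R, 55 - 42)

  # tied forced means -> chose_low_mean undefined
  tie <- make_game_trials(forced_rewards = c(50, 50, 50, 50))
  expect_true(is.na(first_free_choices(tie)$chose_low_mean))

  # deterministic: identical input, identical output
  expect_identical(first_free_choices(tr), first_free_choices(tr))
})

test_that("first_free_choices requires trial 5", {
  tr <- make_game_trials()
  tr <- tr[tr$trial_index <= 4L, ]
  class(tr) <- c("horizon_trials", "data.frame")
  expect_error(first_free_choices(tr), "horizon")
})

test_that("trial-table CSV round-trips and rejects malformed input", {
  set.seed(17)
  cfg <- mini_cfg()
  trials <- play_session(generate_session(cfg),
                         flat_params(sigma_ran = 4), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(back$reward, trials$reward)
  expect_equal(back$side, trials$side)
  expect_equal(back$pair_id, trials$pair_id)

  bad <- trials
  bad$horizon[7] <- 3L
  path2 <- withr::local_tempfile(fileext = ".csv")
  out <- bad; out$is_forced <- as.integer(out$is_forced)
  utils::write.csv(out, path2, row.names = FALSE, na = "", quote = FALSE)
  expect_error(read_trials(path2), "horizon")

  hdr <- readLines(path)
  hdr[1] <- sub("subject_id", "subject", hdr[1])
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(hdr, path3)
  expect_error(read_trials(path3), "header")
})

test_that("a default session yields the expected trial-table shape", {
  set.seed(18)
  cfg <- task_config()
  trials <- play_session(generate_session(cfg),
                         flat_params(sigma_ran = 5), cfg)
  games <- unique(trials[, c("game_id", "horizon", "pair_id")])
  expect_equal(nrow(games), 156L)
  expect_equal(nrow(trials), sum(games$horizon + 4L))
  expect_equal(sum(table(na.omit(games$pair_id)) == 2L), 65L)
  expect_true(all(trials$reward >= 1 & trials$reward <= 100))
})
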