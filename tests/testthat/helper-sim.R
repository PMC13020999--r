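# Shared fixtures, built in code.

# Small but structurally complete session config.
mini_cfg <- function(n_games = 24L, repeat_fraction = 2 / 3,
                     min_pair_separation = 2L, ...) {
  task_config(n_games = n_games, repeat_fraction = repeat_fraction,
              min_pair_separation = min_pair_separation, ...)
}

# Identical subject parameters for both horizons.
flat_params <- function(A = 0, b = 0, sigma_det = 0, sigma_ran = 0) {
  p <- subject_params(A = A, b = b, sigma_det = sigma_det,
                      sigma_ran = sigma_ran)
  list(h1 = p, h6 = p)
}

# Hand-built first-choices table for counting tests.
make_fc <- function(n, horizon = 6, info_condition = "22", delta_R = 5,
                    delta_I = 0L, chose_right = TRUE, chose_low_mean = FALSE,
                    chose_high_info = NA, pair_id = NA_integer_,
                    subject_id = "s1") {
  out <- data.frame(
    subject_id = rep(subject_id, length.out = n),
    game_id = seq_len(n),
    pair_id = rep(pair_id, length.out = n),
    repeat_index = NA_integer_,
    horizon = rep(horizon, length.out = n),
    info_condition = rep(info_condition, length.out = n),
    delta_R = rep(delta_R, length.out = n),
    delta_I = rep(delta_I, length.out = n),
    chose_right = rep(chose_right, length.out = n),
    chose_low_mean = rep(chose_low_mean, length.out = n),
    chose_high_info = rep(chose_high_info, length.out = n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("first_choices", "data.frame")
  out
}

# Minimal hand-built trial table: one game.
make_game_trials <- function(subject_id = "s1", game_id = 1L, horizon = 1L,
                             info_condition = "22",
                             forced_sides = c("left", "left", "right", "right"),
                             forced_rewards = c(50, 50, 40, 40),
                             free_sides = "right", free_rewards = 45,
                             pair_id = NA_integer_, repeat_index = NA_integer_) {
  n <- 4L + horizon
  stopifnot(length(free_sides) == horizon)
  out <- data.frame(
    subject_id = subject_id, game_id = game_id, pair_id = pair_id,
    repeat_index = repeat_index, horizon = horizon,
    info_condition = info_condition, trial_index = seq_len(n),
    is_forced = seq_len(n) <= 4L,
    side = c(forced_sides, free_sides),
    reward = c(forced_rewards, free_rewards),
    stringsAsFactors = FALSE
  )
  class(out) <- c("horizon_trials", "data.frame")
  out
}

bind_trials <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("horizon_trials", "data.frame")
  out
}

# Deterministic truth table for recovery tests (one row per subject x horizon).
draw_recovery_truth_for_test <- function(design, seed) {
  set.seed(seed)
  grid <- expand.grid(subject_id = sprintf("s%03d", seq_len(design$n_subjects)),
                      horizon = design$cfg$horizons,
                      stringsAsFactors = FALSE)
  grid$A <- rnorm(nrow(grid), 1, 1)
  grid$b <- rnorm(nrow(grid), 0, 1)
  grid$sigma_det <- sample(design$sigma_grid, nrow(grid), replace = TRUE)
  grid$sigma_ran <- sample(design$sigma_grid, nrow(grid), replace = TRUE)
  grid[order(grid$subject_id, grid$horizon), ]
}
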