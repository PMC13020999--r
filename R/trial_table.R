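#' Validate a trial table
#'
#' Checks the invariants of the long-format trial record: trials 1-4 of
#' every game forced, 5 rows for horizon-1 games and 10 for horizon-6 games,
#' horizon in {1, 6}, information condition in {"13", "22"}, forced-side
#' counts consistent with the information condition, and numeric rewards.
#'
#' @param trials A `horizon_trials` data.frame (see [play_session()]).
#' @param reward_min,reward_max Optional payout bounds to enforce.
#' @return `trials`, invisibly, or an error naming the first offending row.
#' @export
validate_trials <- function(trials, reward_min = NULL, reward_max = NULL) {
  req <- c("subject_id", "game_id", "pair_id", "repeat_index", "horizon",
           "info_condition", "trial_index", "is_forced", "side", "reward")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_row <- function(cond, msg) {
    if (any(cond)) stop(sprintf("trial table row %d: %s", which(cond)[1], msg),
                        call. = FALSE)
  }
  bad_row(!trials$horizon %in% c(1L, 6L), "horizon not in {1, 6}")
  bad_row(!trials$info_condition %in% c("13", "22"),
          "info_condition not in {\"13\", \"22\"}")
  bad_row(!trials$side %in% c("left", "right"), "side not left/right")
  bad_row(!is.finite(trials$reward), "non-numeric reward")
  bad_row(xor(trials$trial_index <= 4L, as.logical(trials$is_forced)),
          "is_forced must mark exactly trials 1-4")
  if (!is.null(reward_min))
    bad_row(trials$reward < reward_min | trials$reward > reward_max,
            "reward outside configured bounds")
  key <- interaction(trials$subject_id, trials$game_id, drop = TRUE)
  n_per_game <- tapply(trials$trial_index, key, length)
  hor <- tapply(trials$horizon, key, `[`, 1L)
  wrong <- n_per_game != hor + 4L
  if (any(wrong))
    stop("game ", names(n_per_game)[wrong][1],
         ": row count inconsistent with horizon", call. = FALSE)
  for_key <- trials$trial_index <= 4L
  n_right <- tapply(trials$side[for_key] == "right", key[for_key], sum)
  info <- tapply(trials$info_condition, key, `[`, 1L)
  bad <- (info == "22" & n_right != 2L) | (info == "13" & !n_right %in% c(1L, 3L))
  if (any(bad))
    stop("game ", names(n_right)[bad][1],
         ": forced-side counts inconsistent with info condition",
         call. = FALSE)
  invisible(trials)
}

#' Extract the first free choice of every game
#'
#' Reduces a trial table to the analysis unit of the task: one row per game
#' holding the stimulus summary of the four forced trials and the side of
#' the first free choice (trial 5). `delta_R` is the difference in the
#' forced-trial mean rewards (right minus left); `delta_I` is +1 when the
#' right option was forced once, -1 when the left was, and 0 in the "22"
#' condition; `chose_low_mean` is `TRUE` when the chosen side had the
#' strictly lower forced-trial mean (`NA` on ties); `chose_high_info` is
#' `TRUE` when the chosen side was the one forced once (`NA` outside the
#' "13" condition).
#'
#' @param trials A validated `horizon_trials` data.frame.
#' @return A `first_choices` data.frame, one row per subject x game.
#' @examples
#' set.seed(1)
#' cfg <- task_config(n_games = 8, repeat_fraction = 0.5, min_pair_separation = 1)
#' trials <- play_session(generate_session(cfg),
#'                        list(h1 = subject_params(sigma_ran = 3),
#'                             h6 = subject_params(sigma_ran = 6)), cfg)
#' first_free_choices(trials)
#' @export
first_free_choices <- function(trials) {
  validate_trials(trials)
  key <- interaction(trials$subject_id, trials$game_id, drop = TRUE)
  split_rows <- split(seq_len(nrow(trials)), key)
  rows <- lapply(split_rows, function(idx) {
    g <- trials[idx, ]
    g <- g[order(g$trial_index), ]
    if (!5L %in% g$trial_index)
      stop("game ", g$game_id[1], " of subject ", g$subject_id[1],
           " is missing trial 5", call. = FALSE)
    forced <- g[g$trial_index <= 4L, ]
    free <- g[g$trial_index == 5L, ]
    m_r <- mean(forced$reward[forced$side == "right"])
    m_l <- mean(forced$reward[forced$side == "left"])
    n_right <- sum(forced$side == "right")
    delta_I <- if (n_right == 2L) 0L else if (n_right == 1L) 1L else -1L
    chose_right <- free$side == "right"
    chose_low_mean <- if (m_r == m_l) NA else {
      if (chose_right) m_r < m_l else m_l < m_r
    }
    chose_high_info <- if (delta_I == 0L) NA else {
      (delta_I == 1L) == chose_right
    }
    data.frame(
      subject_id = g$subject_id[1], game_id = g$game_id[1],
      pair_id = g$pair_id[1], repeat_index = g$repeat_index[1],
      horizon = g$horizon[1], info_condition = g$info_condition[1],
      delta_R = m_r - m_l, delta_I = delta_I, chose_right = chose_right,
      chose_low_mean = chose_low_mean, chose_high_info = chose_high_info,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$game_id), ]
  rownames(out) <- NULL
  class(out) <- c("first_choices", "data.frame")
  out
}

#' Read / write the trial-table CSV
#'
#' The on-disk dialect is a UTF-8 comma-separated file with header exactly
#' `subject_id, game_id, pair_id, repeat_index, horizon, info_condition,
#' trial_index, is_forced, side, reward` (plus an optional trailing
#' `analysis` column), `pair_id`/`repeat_index` empty for unpaired games,
#' `info_condition` encoded `"13"`/`"22"`, `is_forced` in {0, 1}, and no
#' index column.
#'
#' @param path CSV file path.
#' @param trials A `horizon_trials` data.frame.
#' @return `read_trials` returns a validated `horizon_trials` data.frame;
#'   `write_trials` returns `path` invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  req <- c("subject_id", "game_id", "pair_id", "repeat_index", "horizon",
           "info_condition", "trial_index", "is_forced", "side", "reward")
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (ncol(trials) < length(req) ||
      !identical(names(trials)[seq_along(req)], req))
    stop("trial-table header mismatch: expected ",
         paste(req, collapse = ", "), call. = FALSE)
  to_num <- function(col) {
    v <- suppressWarnings(as.numeric(trials[[col]]))
    bad <- which(is.na(v) & nzchar(trials[[col]]))
    if (length(bad))
      stop(sprintf("trial table row %d: non-numeric %s", bad[1], col),
           call. = FALSE)
    v
  }
  for (col in c("game_id", "horizon", "trial_index", "reward"))
    trials[[col]] <- to_num(col)
  trials$pair_id <- suppressWarnings(as.integer(trials$pair_id))
  trials$repeat_index <- suppressWarnings(as.integer(trials$repeat_index))
  trials$is_forced <- as.logical(as.integer(trials$is_forced))
  if ("analysis" %in% names(trials)) trials$analysis <- to_num("analysis")
  class(trials) <- c("horizon_trials", "data.frame")
  validate_trials(trials)
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  out <- trials
  out$is_forced <- as.integer(out$is_forced)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @export
print.horizon_trials <- function(x, ...) {
  cat(sprintf("Horizon task trials: %d rows, %d subject(s), %d game(s)\n",
              nrow(x), length(unique(x$subject_id)),
              length(unique(interaction(x$subject_id, x$game_id)))))
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Simulate a cohort of subjects playing fresh sessions
#'
#' Convenience wrapper used by the validation and pipeline stages: for each
#' subject, generates a session from `cfg` and plays it with that subject's
#' parameters.
#'
#' @param params_list Named list (one element per subject) of named lists of
#'   [subject_params()] per horizon (as in [play_session()]).
#' @param cfg A [task_config()].
#' @param shared_session If `TRUE`, all subjects play the same session
#'   (generated once); otherwise each subject gets a fresh session.
#' @return A `horizon_trials` data.frame covering all subjects.
#' @export
simulate_cohort <- function(params_list, cfg, shared_session = FALSE) {
  ids <- names(params_list)
  if (is.null(ids))
    ids <- sprintf("s%03d", seq_along(params_list))
  games <- if (shared_session) generate_session(cfg) else NULL
  trials <- lapply(seq_along(params_list), function(i) {
    g <- if (shared_session) games else generate_session(cfg)
    play_session(g, params_list[[i]], cfg, subject_id = ids[i])
  })
  out <- do.call(rbind, trials)
  class(out) <- c("horizon_trials", "data.frame")
  out
}
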