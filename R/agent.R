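#' Subject-level parameters of the two-noise logistic choice model
#'
#' One parameter set per horizon condition: the information bonus `A`
#' (points added to the utility of the less-sampled option), the spatial
#' bias `b` (points added to the right option), and the spreads of the two
#' decision-noise components. `sigma_det` is the spread of the
#' stimulus-frozen deterministic noise, drawn once per repeated game pair;
#' `sigma_ran` is the spread of the per-play random noise, drawn
#' independently on every game.
#'
#' Both noise components follow logistic distributions with mean 0. The
#' spreads are interpreted as logistic *scale* parameters, the convention of
#' the Horizon Task model family, in which the choice rule is
#' `P(right) = 1 / (1 + exp(-drive / sigma_ran))`. To supply true standard
#' deviations instead, set `sigma_is_sd = TRUE` and the values are converted
#' via `scale = sd * sqrt(3) / pi` (for a logistic distribution,
#' `sd = scale * pi / sqrt(3)`).
#'
#' @param A Information bonus, points.
#' @param b Spatial bias toward the right option, points.
#' @param sigma_det Deterministic-noise spread, points; `>= 0`.
#' @param sigma_ran Random-noise spread, points; `>= 0`.
#' @param sigma_is_sd If `TRUE`, `sigma_det`/`sigma_ran` are standard
#'   deviations and are converted to logistic scales.
#' @return An object of class `subject_params`.
#' @examples
#' subject_params(A = 2, b = 0.5, sigma_det = 1, sigma_ran = 4)
#' @export
subject_params <- function(A = 0, b = 0, sigma_det = 0, sigma_ran = 0,
                           sigma_is_sd = FALSE) {
  stopifnot(is.finite(A), is.finite(b), is.finite(sigma_det) || sigma_det == Inf,
            is.finite(sigma_ran) || sigma_ran == Inf)
  if (sigma_det < 0 || sigma_ran < 0)
    stop("noise spreads must be non-negative", call. = FALSE)
  if (sigma_is_sd) {
    sigma_det <- sigma_det * sqrt(3) / pi
    sigma_ran <- sigma_ran * sqrt(3) / pi
  }
  structure(list(A = A, b = b, sigma_det = sigma_det, sigma_ran = sigma_ran),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf(
    "subject_params: A=%g, b=%g, sigma_det=%g, sigma_ran=%g (logistic scales)\n",
    x$A, x$b, x$sigma_det, x$sigma_ran))
  invisible(x)
}

#' Utility difference between right and left options
#'
#' The decision variable of the choice model:
#' `delta_Q = delta_R + A * delta_I + b + n_det + n_ran`. The agent chooses
#' right when `delta_Q > 0`.
#'
#' @param params A [subject_params()].
#' @param delta_R Difference in forced-trial mean rewards (right minus
#'   left), points.
#' @param delta_I Information difference: +1 if the right option was forced
#'   once (and the left three times), -1 for the reverse, 0 in the "22"
#'   condition.
#' @param n_det,n_ran Realised noise values, points.
#' @return The utility difference in points.
#' @examples
#' delta_q(subject_params(A = 2, b = 1), delta_R = -4, delta_I = 1,
#'         n_det = 0.5, n_ran = -0.5)
#' @export
delta_q <- function(params, delta_R, delta_I, n_det = 0, n_ran = 0) {
  stopifnot(inherits(params, "subject_params"))
  delta_R + params$A * delta_I + params$b + n_det + n_ran
}

#' Probability of choosing the right option, given the frozen noise
#'
#' Marginalises the per-play logistic random noise analytically: with net
#' drive `d = delta_R + A*delta_I + b + n_det`, the probability that
#' `d + n_ran > 0` is the logistic CDF `1 / (1 + exp(-d / sigma_ran))`. With
#' `sigma_ran = 0` the choice is a hard threshold: 0, 1/2 (tie) or 1.
#'
#' @inheritParams delta_q
#' @return Probability in `[0, 1]`.
#' @examples
#' choice_prob_right(subject_params(sigma_ran = 1), delta_R = 1, delta_I = 0)
#' @export
choice_prob_right <- function(params, delta_R, delta_I, n_det = 0) {
  stopifnot(inherits(params, "subject_params"))
  d <- delta_R + params$A * delta_I + params$b + n_det
  if (params$sigma_ran == 0) {
    return(ifelse(d > 0, 1, ifelse(d < 0, 0, 0.5)))
  }
  stats::plogis(d / params$sigma_ran)
}

#' Reward-scaling equivalence transform
#'
#' Scaling the reward signal by `beta` while dividing `A`, `b` and both
#' noise spreads by `beta` leaves choice behavior unchanged, because the
#' choice depends only on the sign of the utility difference. This transform
#' returns the rescaled parameters; pairing it with `beta * delta_R`
#' reproduces the original choice probabilities exactly.
#'
#' @param params A [subject_params()].
#' @param beta Positive scaling factor.
#' @return A rescaled [subject_params()].
#' @examples
#' reward_scaling_transform(subject_params(A = 4, b = 2, sigma_det = 1,
#'                                         sigma_ran = 3), beta = 2)
#' @export
reward_scaling_transform <- function(params, beta) {
  stopifnot(inherits(params, "subject_params"))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a positive number", call. = FALSE)
  subject_params(A = params$A / beta, b = params$b / beta,
                 sigma_det = params$sigma_det / beta,
                 sigma_ran = params$sigma_ran / beta)
}

#' Play a session with the two-noise generative agent
#'
#' Reproduces the forced trials of each game verbatim, then samples the
#' first free choice from the two-noise logistic model: one deterministic
#' noise value is drawn per repeated pair (or per unpaired game) and reused
#' on the pair's second presentation, while random noise is fresh on every
#' game. Later free choices of horizon-6 games (trials 6-10) are generated
#' by a declared placeholder policy -- greedy on the running sample means
#' with the same logistic random noise -- and are flagged `analysis = 0`
#' because the model neither describes nor analyses them.
#'
#' Deterministic-noise values are drawn lazily, at the first encounter of
#' each `pair_id`, so presentation order cannot change pair-level draws. A
#' utility tie (`delta_Q == 0`, possible only when `sigma_ran = 0`) is
#' resolved by a fair coin.
#'
#' @param games A `horizon_games` session from [generate_session()].
#' @param params_by_horizon Named list of [subject_params()], one element
#'   per horizon, names `"h<horizon>"` (e.g. `h1`, `h6`).
#' @param cfg The [task_config()] used to generate the session (supplies the
#'   payoff distribution for free-trial rewards).
#' @param subject_id Subject identifier stored in the output.
#' @return A `horizon_trials` data.frame (the trial table): columns
#'   `subject_id`, `game_id`, `pair_id`, `repeat_index`, `horizon`,
#'   `info_condition`, `trial_index`, `is_forced`, `side`, `reward`,
#'   `analysis`.
#' @examples
#' set.seed(1)
#' cfg <- task_config(n_games = 8, repeat_fraction = 0.5, min_pair_separation = 1)
#' games <- generate_session(cfg)
#' pars <- list(h1 = subject_params(sigma_ran = 2),
#'              h6 = subject_params(A = 3, sigma_ran = 5))
#' trials <- play_session(games, pars, cfg)
#' head(trials)
#' @export
play_session <- function(games, params_by_horizon, cfg,
                         subject_id = "s01") {
  stopifnot(inherits(games, "horizon_games"))
  needed <- paste0("h", sort(unique(games$horizon)))
  missing <- setdiff(needed, names(params_by_horizon))
  if (length(missing))
    stop("missing subject_params for horizon(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  n_det_pool <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(games))
  for (gi in seq_len(nrow(games))) {
    g <- games[gi, ]
    pars <- params_by_horizon[[paste0("h", g$horizon)]]
    stopifnot(inherits(pars, "subject_params"))
    key <- if (is.na(g$pair_id)) paste0("g", g$game_id) else paste0("p", g$pair_id)
    if (!exists(key, envir = n_det_pool, inherits = FALSE)) {
      nd <- if (pars$sigma_det > 0) stats::rlogis(1L, 0, pars$sigma_det) else 0
      assign(key, nd, envir = n_det_pool)
    }
    n_det <- get(key, envir = n_det_pool, inherits = FALSE)
    fs <- g$forced_sides[[1]]
    fr <- g$forced_rewards[[1]]
    n_trials <- 4L + g$horizon
    side <- character(n_trials)
    reward <- numeric(n_trials)
    side[1:4] <- fs
    reward[1:4] <- fr
    dR <- mean(fr[fs == "right"]) - mean(fr[fs == "left"])
    dI <- info_difference(fs)
    p_right <- choice_prob_right(pars, dR, dI, n_det)
    if (pars$sigma_ran == 0 && p_right == 0.5) p_right <- stats::runif(1) # coin
    chose_right <- stats::runif(1) < p_right
    side[5L] <- if (chose_right) "right" else "left"
    reward[5L] <- draw_reward(g, side[5L], cfg)
    if (n_trials > 5L) {
      for (tt in 6:n_trials) {
        seen <- seq_len(tt - 1L)
        m_r <- mean(reward[seen][side[seen] == "right"])
        m_l <- mean(reward[seen][side[seen] == "left"])
        drive <- m_r - m_l
        p <- if (pars$sigma_ran == 0) {
          if (drive > 0) 1 else if (drive < 0) 0 else stats::runif(1)
        } else stats::plogis(drive / pars$sigma_ran)
        side[tt] <- if (stats::runif(1) < p) "right" else "left"
        reward[tt] <- draw_reward(g, side[tt], cfg)
      }
    }
    rows[[gi]] <- data.frame(
      subject_id = subject_id, game_id = g$game_id, pair_id = g$pair_id,
      repeat_index = g$repeat_index, horizon = g$horizon,
      info_condition = g$info_condition, trial_index = seq_len(n_trials),
      is_forced = seq_len(n_trials) <= 4L, side = side, reward = reward,
      analysis = as.integer(seq_len(n_trials) <= 5L),
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, rows)
  class(trials) <- c("horizon_trials", "data.frame")
  trials
}

draw_reward <- function(g, side, cfg) {
  mu <- if (side == "right") g$mean_right else g$mean_left
  bound_rewards(stats::rnorm(1L, mu, cfg$reward_sd), cfg)
}

# +1 if right forced once, -1 if left forced once, 0 in the "22" condition
info_difference <- function(forced_sides) {
  n_right <- sum(forced_sides == "right")
  if (n_right == 2L) 0L else if (n_right == 1L) 1L else -1L
}
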