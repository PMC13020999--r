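#' Model-free exploration statistics
#'
#' Simple choice probabilities computed on the first free choice of each
#' game. `p_low_mean` measures behavioral variability: the probability of
#' choosing the option with the lower forced-trial mean, in the equal
#' ("22") information condition. `p_high_info` measures directed
#' exploration: the probability of choosing the less-sampled (once-forced)
#' option, in the unequal ("13") condition. Games whose forced-trial means
#' are tied carry no "low mean" event and are excluded.
#'
#' @param rows A `first_choices` data.frame (possibly one subject's rows).
#' @param horizon Horizon condition to restrict to.
#' @return A probability, or `NA_real_` (undefined statistic) when no
#'   eligible games exist.
#' @examples
#' set.seed(1)
#' cfg <- task_config(n_games = 40, repeat_fraction = 0.5, min_pair_separation = 2)
#' trials <- play_session(generate_session(cfg),
#'                        list(h1 = subject_params(sigma_ran = 4),
#'                             h6 = subject_params(sigma_ran = 8)), cfg)
#' fc <- first_free_choices(trials)
#' p_low_mean(fc, horizon = 6)
#' @export
p_low_mean <- function(rows, horizon) {
  el <- rows$horizon == horizon & rows$info_condition == "22" &
    !is.na(rows$chose_low_mean)
  if (!any(el)) return(NA_real_)
  mean(rows$chose_low_mean[el])
}

#' @rdname p_low_mean
#' @export
p_high_info <- function(rows, horizon) {
  el <- rows$horizon == horizon & rows$info_condition == "13" &
    !is.na(rows$chose_high_info)
  if (!any(el)) return(NA_real_)
  mean(rows$chose_high_info[el])
}

#' Within-pair choice inconsistency
#'
#' Fraction of complete repeated pairs (both presentations observed) whose
#' two first free choices landed on different sides. Purely
#' stimulus-deterministic behavior gives 0; independent fair-coin behavior
#' gives 0.5 in expectation.
#'
#' @inheritParams p_low_mean
#' @param info_condition `"13"` or `"22"`.
#' @return A probability, or `NA_real_` when no complete pairs exist.
#' @export
p_inconsistent <- function(rows, horizon, info_condition) {
  el <- rows[rows$horizon == horizon &
               rows$info_condition == info_condition &
               !is.na(rows$pair_id), , drop = FALSE]
  if (!nrow(el)) return(NA_real_)
  per_pair <- tapply(el$chose_right,
                     interaction(el$subject_id, el$pair_id, drop = TRUE),
                     function(v) if (length(v) == 2L) v[1] != v[2] else NA)
  per_pair <- per_pair[!is.na(per_pair)]
  if (!length(per_pair)) return(NA_real_)
  mean(per_pair)
}

#' Pure-random-noise prediction of choice inconsistency
#'
#' If decision noise were entirely random (independent across the two
#' presentations of a pair), the chance that two first free choices differ,
#' conditional on the stimulus, is `2p(1-p)` with `p = p(low mean |
#' stimulus)`. Because `p(low mean)` depends on the reward difference and
#' the information condition, the prediction is a mixture over stimulus
#' strata: `p(inconsistent) = sum_s rho_s * 2 p_s (1 - p_s)`, with stratum
#' weights `rho_s` estimated from how often each stratum occurs among the
#' pairs.
#'
#' Strata are bins of `|delta_R|` (quartile bins by default) within the
#' information condition; signs are pooled because "low mean" is
#' sign-agnostic. Stratum-level `p_s` is estimated from all eligible
#' (untied) first choices in the stratum; `rho_s` from the pair frequencies.
#'
#' @inheritParams p_inconsistent
#' @param n_bins Number of `|delta_R|` quantile bins.
#' @return The predicted inconsistency probability (`<= 0.5`), or
#'   `NA_real_` when a required stratum estimate is unavailable.
#' @export
pure_random_prediction <- function(rows, horizon, info_condition,
                                   n_bins = 4L) {
  el <- rows[rows$horizon == horizon &
               rows$info_condition == info_condition &
               !is.na(rows$chose_low_mean), , drop = FALSE]
  if (!nrow(el)) return(NA_real_)
  abs_dr <- abs(el$delta_R)
  breaks <- unique(stats::quantile(abs_dr, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1e-9)
  stratum <- cut(abs_dr, breaks = breaks, include.lowest = TRUE)
  p_s <- tapply(el$chose_low_mean, stratum, mean)
  paired <- el[!is.na(el$pair_id), , drop = FALSE]
  if (!nrow(paired)) return(NA_real_)
  pair_stratum <- cut(abs(paired$delta_R), breaks = breaks, include.lowest = TRUE)
  pair_one <- !duplicated(interaction(paired$subject_id, paired$pair_id))
  rho <- table(pair_stratum[pair_one])
  rho <- rho / sum(rho)
  occupied <- names(rho)[rho > 0]
  if (anyNA(p_s[occupied])) return(NA_real_)
  sum(rho[occupied] * 2 * p_s[occupied] * (1 - p_s[occupied]))
}

#' Per-subject model-free statistics table
#'
#' Computes, per subject and horizon, the exploration statistics
#' `p_low_mean` and `p_high_info`, the within-pair inconsistencies
#' `p_inconsistent_13` / `p_inconsistent_22`, their pure-random-noise
#' predictions, the pure-deterministic prediction (identically 0), and the
#' contributing game/pair counts.
#'
#' @param fc A `first_choices` data.frame (all subjects).
#' @param n_bins Bins for [pure_random_prediction()].
#' @param pooled If `TRUE` (default), stratum probabilities for the
#'   pure-random prediction are estimated from all subjects pooled, which
#'   makes the plug-in `2p(1-p)` estimator effectively unbiased;
#'   `pooled = FALSE` estimates them per subject (matching per-subject
#'   error bars, at the cost of a small-sample downward bias of order
#'   `2p(1-p)/n` per stratum).
#' @return A data.frame, one row per subject x horizon.
#' @export
model_free_stats <- function(fc, n_bins = 4L, pooled = TRUE) {
  subjects <- unique(fc$subject_id)
  horizons <- sort(unique(fc$horizon))
  grid <- expand.grid(subject_id = subjects, horizon = horizons,
                      stringsAsFactors = FALSE)
  pred_fun <- function(rows, h, ic) {
    if (pooled) pure_random_prediction(fc, h, ic, n_bins)
    else pure_random_prediction(rows, h, ic, n_bins)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$subject_id[i]; h <- grid$horizon[i]
    rows <- fc[fc$subject_id == s, , drop = FALSE]
    complete_pairs <- function(ic) {
      el <- rows[rows$horizon == h & rows$info_condition == ic &
                   !is.na(rows$pair_id), , drop = FALSE]
      if (!nrow(el)) return(0L)
      sum(table(el$pair_id) == 2L)
    }
    data.frame(
      subject_id = s, horizon = h,
      p_low_mean = p_low_mean(rows, h),
      p_high_info = p_high_info(rows, h),
      p_inconsistent_13 = p_inconsistent(rows, h, "13"),
      p_inconsistent_22 = p_inconsistent(rows, h, "22"),
      pred_random_13 = pred_fun(rows, h, "13"),
      pred_random_22 = pred_fun(rows, h, "22"),
      pred_deterministic = 0,
      n_games_13 = sum(rows$horizon == h & rows$info_condition == "13"),
      n_games_22 = sum(rows$horizon == h & rows$info_condition == "22"),
      n_pairs_13 = complete_pairs("13"),
      n_pairs_22 = complete_pairs("22"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Paired t-test contrast of a statistic between horizons
#'
#' Two-sided paired t-test of the horizon-6 minus horizon-1 values of a
#' per-subject statistic (e.g. `p_low_mean`).
#'
#' @param stats_df Output of [model_free_stats()].
#' @param stat Column name of the statistic to contrast.
#' @param horizons Length-2 vector, contrast is `horizons[2] - horizons[1]`.
#' @return A list with `t`, `df`, `p_value`, `mean_diff` and a `degenerate`
#'   flag (set when the paired differences have zero variance, in which case
#'   `t` is `Inf`/`-Inf`/`NaN` and `p_value` is `NA`).
#' @export
horizon_contrast <- function(stats_df, stat = "p_low_mean",
                             horizons = c(1, 6)) {
  a <- stats_df[stats_df$horizon == horizons[1],
                c("subject_id", stat), drop = FALSE]
  b <- stats_df[stats_df$horizon == horizons[2],
                c("subject_id", stat), drop = FALSE]
  m <- merge(a, b, by = "subject_id", suffixes = c("_1", "_2"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L)
    stop("horizon_contrast needs at least 2 subjects with the statistic at both horizons",
         call. = FALSE)
  d <- m[[paste0(stat, "_2")]] - m[[paste0(stat, "_1")]]
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-10)
      return(list(t = 0, df = length(d) - 1L, p_value = 1,
                  mean_diff = 0, degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L,
                p_value = NA_real_, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Performance-based subject exclusion
#'
#' Reproduces the task's exclusion rule: a subject's accuracy is the
#' fraction of last (10th) choices in horizon-6 games that landed on the
#' bandit with the higher generative mean; subjects whose accuracy is not
#' significantly above chance (one-sided exact binomial test against 0.5,
#' p >= 0.001) are excluded.
#'
#' The generative means are read from `games` when provided (a
#' `horizon_games` session per subject, or a single shared session);
#' otherwise the higher-mean side is estimated per game from the sample mean
#' of all observed rewards on each side, which is a noisy surrogate noted in
#' the output.
#'
#' @param trials A `horizon_trials` data.frame.
#' @param games Optional `horizon_games` (shared session) or named list of
#'   them per subject, supplying generative means.
#' @return A list with `kept`, `excluded` (subject id vectors) and a
#'   per-subject data.frame `summary` (`n`, `n_correct`, `accuracy`,
#'   `p_value`, `kept`, `reason`).
#' @export
exclude_subjects <- function(trials, games = NULL) {
  validate_trials(trials)
  last <- trials[trials$horizon == 6L & trials$trial_index == 10L, , drop = FALSE]
  subjects <- unique(trials$subject_id)
  res <- lapply(subjects, function(s) {
    rows <- last[last$subject_id == s, , drop = FALSE]
    if (!nrow(rows))
      return(data.frame(subject_id = s, n = 0L, n_correct = 0L,
                        accuracy = NA_real_, p_value = NA_real_, kept = FALSE,
                        reason = "no horizon-6 games", stringsAsFactors = FALSE))
    better <- vapply(seq_len(nrow(rows)), function(i) {
      higher_mean_side(trials, games, s, rows$game_id[i])
    }, character(1))
    ok <- better != "tie"
    n <- sum(ok)
    k <- sum(rows$side[ok] == better[ok])
    pv <- stats::binom.test(k, n, p = 0.5, alternative = "greater")$p.value
    data.frame(subject_id = s, n = n, n_correct = k, accuracy = k / n,
               p_value = pv, kept = pv < 0.001, reason = ifelse(pv < 0.001, "",
               "accuracy not above chance at p < 0.001"),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, res)
  list(kept = summary$subject_id[summary$kept],
       excluded = summary$subject_id[!summary$kept],
       summary = summary)
}

higher_mean_side <- function(trials, games, subject, game_id) {
  g <- NULL
  if (!is.null(games)) {
    gt <- if (is.data.frame(games)) games else games[[subject]]
    if (!is.null(gt)) g <- gt[gt$game_id == game_id, , drop = FALSE]
  }
  if (!is.null(g) && nrow(g) == 1L) {
    if (g$mean_right > g$mean_left) return("right")
    if (g$mean_right < g$mean_left) return("left")
    return("tie")
  }
  rows <- trials[trials$subject_id == subject & trials$game_id == game_id &
                   trials$trial_index < 10L, , drop = FALSE]
  m_r <- mean(rows$reward[rows$side == "right"])
  m_l <- mean(rows$reward[rows$side == "left"])
  if (is.nan(m_r) || is.nan(m_l) || m_r == m_l) return("tie")
  if (m_r > m_l) "right" else "left"
}
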