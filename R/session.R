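#' Generate a single Horizon Task game
#'
#' Draws the generative bandit means (one equals a uniformly chosen anchor,
#' the other differs by a mean difference drawn uniformly from
#' `cfg$mean_diffs`, with the sign and side randomised), a forced-trial side
#' schedule consistent with the information condition, and the four
#' forced-trial outcomes sampled from the owning bandit's Gaussian, rounded
#' to integers and clamped into `[reward_min, reward_max]`.
#'
#' @param cfg A [task_config()].
#' @param horizon Horizon condition (number of free choices), in
#'   `cfg$horizons`.
#' @param info_condition `"13"` or `"22"`, in `cfg$info_conditions`.
#' @param mean_diff Optional fixed mean difference (must be in
#'   `cfg$mean_diffs`); by default drawn uniformly.
#' @return A one-row data.frame of class `horizon_games` (see
#'   [generate_session()] for the columns).
#' @examples
#' set.seed(1)
#' generate_game(task_config(), horizon = 6, info_condition = "13")
#' @export
generate_game <- function(cfg, horizon, info_condition, mean_diff = NULL) {
  validate_task_config(cfg)
  horizon <- as.integer(horizon)
  if (!horizon %in% cfg$horizons)
    stop("unknown horizon: ", horizon, call. = FALSE)
  if (!info_condition %in% cfg$info_conditions)
    stop("unknown info condition: ", info_condition, call. = FALSE)
  if (is.null(mean_diff)) {
    mean_diff <- cfg$mean_diffs[sample.int(length(cfg$mean_diffs), 1L)]
  } else if (!mean_diff %in% cfg$mean_diffs) {
    stop("mean_diff not in configured mean_diffs", call. = FALSE)
  }
  anchor <- cfg$mean_anchors[sample.int(length(cfg$mean_anchors), 1L)]
  other <- anchor + sample(c(-1, 1), 1L) * mean_diff
  if (stats::runif(1) < 0.5) {
    mean_left <- anchor; mean_right <- other
  } else {
    mean_left <- other; mean_right <- anchor
  }
  forced_sides <- forced_schedule(info_condition)
  mu <- ifelse(forced_sides == "left", mean_left, mean_right)
  forced_rewards <- bound_rewards(stats::rnorm(4L, mu, cfg$reward_sd), cfg)
  g <- data.frame(
    game_id = 1L, pair_id = NA_integer_, repeat_index = NA_integer_,
    horizon = horizon, info_condition = info_condition,
    mean_left = mean_left, mean_right = mean_right,
    stringsAsFactors = FALSE
  )
  g$forced_sides <- list(forced_sides)
  g$forced_rewards <- list(forced_rewards)
  class(g) <- c("horizon_games", "data.frame")
  g
}

forced_schedule <- function(info_condition) {
  sides <- if (info_condition == "22") {
    c("left", "left", "right", "right")
  } else {
    once <- sample(c("left", "right"), 1L)
    c(once, rep(setdiff(c("left", "right"), once), 3L))
  }
  sample(sides)
}

bound_rewards <- function(x, cfg) {
  pmin(pmax(round(x), cfg$reward_min), cfg$reward_max)
}

#' Generate a full session of games with repeated pairs
#'
#' Allocates games to the horizon x information-condition x mean-difference
#' design cells as evenly as divisibility allows (separately for repeated
#' pairs and unpaired fill games), duplicates each paired game so that the
#' two members share the generative means, the forced-trial schedule and the
#' exact forced outcomes, and randomises presentation order subject to the
#' constraint that at least `cfg$min_pair_separation` games intervene
#' between the two members of every pair.
#'
#' @param cfg A [task_config()].
#' @return A data.frame of class `horizon_games`, one row per presented game
#'   in presentation order, with columns `game_id`, `pair_id` (`NA` for
#'   unpaired), `repeat_index` (1 for the first presentation, 2 for the
#'   second, `NA` unpaired), `horizon`, `info_condition`, `mean_left`,
#'   `mean_right`, and list columns `forced_sides`, `forced_rewards`.
#' @examples
#' set.seed(1)
#' games <- generate_session(task_config(n_games = 24, repeat_fraction = 2/3,
#'                                       min_pair_separation = 3))
#' table(games$horizon, games$info_condition)
#' @export
generate_session <- function(cfg) {
  validate_task_config(cfg)
  n_pairs <- cfg$n_pairs
  n_unpaired <- cfg$n_games - 2L * n_pairs
  cells <- expand.grid(horizon = cfg$horizons,
                       info_condition = cfg$info_conditions,
                       mean_diff = cfg$mean_diffs,
                       stringsAsFactors = FALSE)
  proto <- list()
  pair_cells <- spread_counts(n_pairs, nrow(cells))
  unpaired_cells <- spread_counts(n_unpaired, nrow(cells))
  pid <- 0L
  for (ci in seq_len(nrow(cells))) {
    n_rep <- pair_cells[ci] + unpaired_cells[ci]
    for (r in seq_len(n_rep)) {
      g <- generate_game(cfg, cells$horizon[ci], cells$info_condition[ci],
                         mean_diff = cells$mean_diff[ci])
      if (r <= pair_cells[ci]) {
        pid <- pid + 1L
        g$pair_id <- pid
        proto[[length(proto) + 1L]] <- g
        proto[[length(proto) + 1L]] <- g
      } else {
        proto[[length(proto) + 1L]] <- g
      }
    }
  }
  games <- do.call(rbind, proto)
  ord <- schedule_order(games$pair_id, cfg$min_pair_separation)
  games <- games[ord, , drop = FALSE]
  games$game_id <- seq_len(nrow(games))
  games$repeat_index <- NA_integer_
  for (p in unique(stats::na.omit(games$pair_id))) {
    idx <- which(games$pair_id == p)
    games$repeat_index[idx] <- c(1L, 2L)
  }
  rownames(games) <- NULL
  class(games) <- c("horizon_games", "data.frame")
  games
}

# Even allocation of n items over k cells; the remainder goes to random cells.
spread_counts <- function(n, k) {
  base <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) {
    idx <- sample.int(k, extra)
    base[idx] <- base[idx] + 1L
  }
  base
}

# Random presentation order with a minimum number of intervening games
# between pair members; stochastic repair of a random permutation.
schedule_order <- function(pair_id, min_sep) {
  n <- length(pair_id)
  if (min_sep + 2L > n && any(!is.na(pair_id)))
    stop("pair separation constraint infeasible for session length",
         call. = FALSE)
  violations <- function(pos) {
    v <- 0L
    for (p in unique(stats::na.omit(pair_id))) {
      d <- abs(diff(pos[which(pair_id == p)]))
      if (d - 1L < min_sep) v <- v + 1L
    }
    v
  }
  pos <- sample.int(n)
  v <- violations(pos)
  max_iter <- 400L * n
  iter <- 0L
  while (v > 0L && iter < max_iter) {
    iter <- iter + 1L
    bad <- which(vapply(seq_len(n), function(i) {
      if (is.na(pair_id[i])) return(FALSE)
      mate <- which(pair_id == pair_id[i])
      abs(diff(pos[mate])) - 1L < min_sep
    }, logical(1)))
    i <- bad[sample.int(length(bad), 1L)]
    j <- sample.int(n, 1L)
    pos2 <- pos
    pos2[c(i, j)] <- pos2[c(j, i)]
    v2 <- violations(pos2)
    if (v2 <= v) {
      pos <- pos2
      v <- v2
    }
  }
  if (v > 0L)
    stop("could not schedule session: pair separation constraint too tight",
         call. = FALSE)
  order(pos)
}

#' @export
print.horizon_games <- function(x, ...) {
  cat(sprintf("Horizon task session: %d games, %d repeated pairs\n",
              nrow(x), length(unique(stats::na.omit(x$pair_id)))))
  tab <- table(horizon = x$horizon, info = x$info_condition)
  print(tab)
  invisible(x)
}
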