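#' Task configuration for the repeated-games Horizon Task
#'
#' Bundles the stimulus statistics and session layout of the task: Gaussian
#' bandit payoffs with a fixed spread, generative mean differences, anchor
#' means, payout bounds, session length, the fraction of games that are
#' presented twice, and the minimum number of intervening games between the
#' two presentations of a repeated pair.
#'
#' Defaults reproduce the published task: payoff SD 8 points, mean
#' differences 4/8/12/20 points around anchors 40/60, rewards bounded to
#' 1..100, horizons 1 and 6, information conditions "13" (one option forced
#' once, the other three times) and "22" (both forced twice), 156 games of
#' which 65 are repeated pairs, and at least 10 games between the two
#' members of a pair so that repeats go unnoticed.
#'
#' @param reward_sd Gaussian payoff standard deviation, in points.
#' @param mean_anchors Candidate anchor means; one bandit mean always equals
#'   an anchor, the other differs by a generative mean difference.
#' @param mean_diffs Candidate absolute differences between the two bandit
#'   means, in points.
#' @param reward_min,reward_max Payout bounds; sampled rewards are rounded to
#'   integers and clamped into this range.
#' @param n_games Number of games in a session.
#' @param repeat_fraction Fraction of games that belong to a repeated pair
#'   (both members counted). The number of pairs is
#'   `round(n_games * repeat_fraction / 2)`.
#' @param min_pair_separation Minimum number of intervening games between the
#'   two presentations of a pair.
#' @param horizons Horizon conditions (free choices per game).
#' @param info_conditions Information conditions, encoded `"13"` and `"22"`.
#' @param seed Optional integer seed recorded with the configuration (used
#'   by [run_pipeline()]); generation functions use R's global RNG.
#'
#' @return An object of class `horizon_task_config` (a named list).
#' @examples
#' cfg <- task_config()
#' cfg$n_pairs
#' @export
task_config <- function(reward_sd = 8,
                        mean_anchors = c(40, 60),
                        mean_diffs = c(4, 8, 12, 20),
                        reward_min = 1,
                        reward_max = 100,
                        n_games = 156,
                        repeat_fraction = 130 / 156,
                        min_pair_separation = 10,
                        horizons = c(1L, 6L),
                        info_conditions = c("13", "22"),
                        seed = NULL) {
  cfg <- list(
    reward_sd = reward_sd,
    mean_anchors = mean_anchors,
    mean_diffs = mean_diffs,
    reward_min = reward_min,
    reward_max = reward_max,
    n_games = as.integer(n_games),
    repeat_fraction = repeat_fraction,
    min_pair_separation = as.integer(min_pair_separation),
    horizons = as.integer(horizons),
    info_conditions = info_conditions,
    seed = seed
  )
  cfg$n_pairs <- as.integer(round(cfg$n_games * cfg$repeat_fraction / 2))
  class(cfg) <- "horizon_task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "horizon_task_config"))
  if (!is.numeric(cfg$reward_sd) || cfg$reward_sd <= 0)
    stop("reward_sd must be > 0", call. = FALSE)
  if (any(cfg$mean_diffs < 0))
    stop("mean_diffs must be non-negative", call. = FALSE)
  if (cfg$n_games < 2L)
    stop("n_games must be >= 2", call. = FALSE)
  if (cfg$min_pair_separation < 1L)
    stop("min_pair_separation must be >= 1", call. = FALSE)
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction > 1)
    stop("repeat_fraction must lie in [0, 1]", call. = FALSE)
  if (!all(cfg$horizons %in% c(1L, 6L)))
    stop("horizons must be a subset of {1, 6}", call. = FALSE)
  if (!all(cfg$info_conditions %in% c("13", "22")))
    stop("info_conditions must be a subset of {\"13\", \"22\"}", call. = FALSE)
  if (2L * cfg$n_pairs > cfg$n_games)
    stop("repeat_fraction implies more paired games than n_games", call. = FALSE)
  if (cfg$reward_min >= cfg$reward_max)
    stop("reward_min must be < reward_max", call. = FALSE)
  invisible(cfg)
}

#' @export
print.horizon_task_config <- function(x, ...) {
  cat("Horizon task configuration\n")
  cat(sprintf("  games: %d (%d repeated pairs, %d unpaired)\n",
              x$n_games, x$n_pairs, x$n_games - 2L * x$n_pairs))
  cat(sprintf("  payoff: Gaussian sd %g, anchors {%s}, mean diffs {%s}, bounds [%g, %g]\n",
              x$reward_sd, paste(x$mean_anchors, collapse = ", "),
              paste(x$mean_diffs, collapse = ", "), x$reward_min, x$reward_max))
  cat(sprintf("  horizons: {%s}; info conditions: {%s}; min pair separation: %d\n",
              paste(x$horizons, collapse = ", "),
              paste(x$info_conditions, collapse = ", "), x$min_pair_separation))
  invisible(x)
}

#' Write / read a task configuration as a flat key-value file
#'
#' The file format is a minimal TOML-like dialect: one `key = value` pair per
#' line, `#` comments, vectors as comma-separated values.
#'
#' @param cfg A `horizon_task_config`.
#' @param path File path.
#' @return `read_task_config` returns a `horizon_task_config`;
#'   `write_task_config` returns `path` invisibly.
#' @export
write_task_config <- function(cfg, path) {
  validate_task_config(cfg)
  fields <- c("reward_sd", "mean_anchors", "mean_diffs", "reward_min",
              "reward_max", "n_games", "repeat_fraction",
              "min_pair_separation", "horizons", "info_conditions", "seed")
  lines <- vapply(fields, function(f) {
    v <- cfg[[f]]
    if (is.null(v)) return(sprintf("# %s =", f))
    sprintf("%s = %s", f, paste(format(v, scientific = FALSE, trim = TRUE),
                                collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[[`, character(1), 2L))
  parse_val <- function(key, val) {
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (key == "info_conditions") return(parts)
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) stop("non-numeric value for ", key, call. = FALSE)
    num
  }
  args <- stats::setNames(lapply(seq_along(keys),
                                 function(i) parse_val(keys[i], vals[i])),
                          keys)
  known <- names(formals(task_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(task_config, args)
}
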