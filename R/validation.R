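#' Design of a parameter-recovery experiment
#'
#' Declares the ground-truth generating scheme of a recovery run: noise
#' spreads drawn uniformly from a grid spanning 0-10 points (independently
#' per subject, horizon and noise type), information bonus and spatial bias
#' drawn from Gaussian group distributions with moderate means, and fresh
#' default sessions per subject. All fields are recorded in the returned
#' reports.
#'
#' @param n_subjects Number of simulated subjects.
#' @param sigma_grid Grid of candidate true noise spreads (points).
#' @param a_mean Group mean of the information bonus per horizon (named
#'   `h1`, `h6`).
#' @param a_sd,b_sd Group SDs of the information bonus / spatial bias.
#' @param b_mean Group mean of the spatial bias.
#' @param cfg Session [task_config()].
#' @param n_repetitions Independent simulate-and-refit repetitions whose
#'   recovered values are averaged.
#' @param chains,n_samples,n_burnin,n_adapt MCMC settings for the refits.
#' @return A list of class `recovery_design`.
#' @export
recovery_design <- function(n_subjects = 65L,
                            sigma_grid = 0:10,
                            a_mean = c(h1 = 1, h6 = 3), a_sd = 1,
                            b_mean = 0, b_sd = 1,
                            cfg = task_config(),
                            n_repetitions = 1L,
                            chains = 4L, n_samples = 1000L,
                            n_burnin = 1000L, n_adapt = 500L) {
  stopifnot(n_subjects >= 2L)
  structure(list(n_subjects = as.integer(n_subjects), sigma_grid = sigma_grid,
                 a_mean = a_mean, a_sd = a_sd, b_mean = b_mean, b_sd = b_sd,
                 cfg = cfg, n_repetitions = as.integer(n_repetitions),
                 chains = chains, n_samples = n_samples,
                 n_burnin = n_burnin, n_adapt = n_adapt),
            class = "recovery_design")
}

# Truth table for a recovery design: one row per subject x horizon.
draw_recovery_truth <- function(design) {
  hs <- design$cfg$horizons
  grid <- expand.grid(subject_id = sprintf("s%03d", seq_len(design$n_subjects)),
                      horizon = hs, stringsAsFactors = FALSE)
  grid$A <- stats::rnorm(nrow(grid),
                         design$a_mean[paste0("h", grid$horizon)], design$a_sd)
  grid$b <- stats::rnorm(nrow(grid), design$b_mean, design$b_sd)
  pick <- function(n) design$sigma_grid[sample.int(length(design$sigma_grid),
                                                   n, replace = TRUE)]
  grid$sigma_det <- pick(nrow(grid))
  grid$sigma_ran <- pick(nrow(grid))
  grid[order(grid$subject_id, grid$horizon), ]
}

# Truth table -> per-subject parameter lists for simulate_cohort().
params_from_truth <- function(truth) {
  subjects <- unique(truth$subject_id)
  out <- lapply(subjects, function(s) {
    rows <- truth[truth$subject_id == s, , drop = FALSE]
    ps <- lapply(seq_len(nrow(rows)), function(i) {
      subject_params(A = rows$A[i], b = rows$b[i],
                     sigma_det = rows$sigma_det[i],
                     sigma_ran = rows$sigma_ran[i])
    })
    stats::setNames(ps, paste0("h", rows$horizon))
  })
  stats::setNames(out, subjects)
}

# Wide recovered table (posterior means and 95% bounds) from a fit.
recovered_wide <- function(fit) {
  sp <- subject_posterior(fit)
  sp <- sp[sp$info_condition %in% c("all"), , drop = FALSE]
  wide <- stats::reshape(
    sp[, c("subject_id", "horizon", "parameter", "mean", "q2.5", "q97.5")],
    direction = "wide", idvar = c("subject_id", "horizon"),
    timevar = "parameter")
  names(wide) <- sub("^mean\\.", "rec_", names(wide))
  names(wide) <- sub("^q2\\.5\\.", "lo_", names(wide))
  names(wide) <- sub("^q97\\.5\\.", "hi_", names(wide))
  wide
}

#' Parameter recovery: simulate with known parameters, refit, compare
#'
#' Simulates a cohort from the two-noise agent with known subject-level
#' parameters, refits the hierarchical model, and reports, per parameter
#' and horizon, the Pearson correlation between true and recovered
#' (posterior-mean) values, the through-origin regression slope
#' recovered-on-true, the mean bias, and the coverage rate of the central
#' 95% posterior intervals.
#'
#' @param design A [recovery_design()].
#' @param truth Optional truth table (as produced internally, columns
#'   `subject_id`, `horizon`, `A`, `b`, `sigma_det`, `sigma_ran`);
#'   generated from the design when `NULL`.
#' @param seed Seed for truth draw, simulation and MCMC.
#' @return A list of class `recovery_report`: `truth`, `recovered` (merged
#'   table, averaged over repetitions), `report` (the per-parameter summary),
#'   `design`, `seed`, and `fit` (the last fit object).
#' @export
parameter_recovery <- function(design = recovery_design(), truth = NULL,
                               seed = 1L) {
  set.seed(seed)
  if (is.null(truth)) truth <- draw_recovery_truth(design)
  rec_reps <- vector("list", design$n_repetitions)
  cover_reps <- vector("list", design$n_repetitions)
  fit <- NULL
  for (rep in seq_len(design$n_repetitions)) {
    set.seed(seed + 1000L * rep)
    trials <- simulate_cohort(params_from_truth(truth), design$cfg)
    fc <- first_free_choices(trials)
    fit <- fit_noise_model(fc, chains = design$chains,
                           n_samples = design$n_samples,
                           n_burnin = design$n_burnin,
                           n_adapt = design$n_adapt,
                           seed = seed + 1000L * rep)
    w <- recovered_wide(fit)
    rec_reps[[rep]] <- w[order(w$subject_id, w$horizon), ]
  }
  rec <- rec_reps[[1]]
  if (design$n_repetitions > 1L) {
    num <- grep("^(rec|lo|hi)_", names(rec))
    for (rep in 2:design$n_repetitions)
      rec[num] <- rec[num] + rec_reps[[rep]][num]
    rec[num] <- rec[num] / design$n_repetitions
  }
  merged <- merge(truth, rec, by = c("subject_id", "horizon"))
  report <- recovery_report_table(merged)
  structure(list(truth = truth, recovered = merged, report = report,
                 design = design, seed = seed, fit = fit),
            class = "recovery_report")
}

slope_through_origin <- function(true, rec) {
  if (all(true == 0)) return(NA_real_)
  sum(true * rec) / sum(true^2)
}

recovery_report_table <- function(merged) {
  params <- c("A", "b", "sigma_det", "sigma_ran")
  rows <- list()
  for (p in params) {
    for (h in sort(unique(merged$horizon))) {
      m <- merged[merged$horizon == h, , drop = FALSE]
      true <- m[[p]]; rec <- m[[paste0("rec_", p)]]
      covered <- mean(true >= m[[paste0("lo_", p)]] &
                        true <= m[[paste0("hi_", p)]])
      r <- if (stats::sd(true) == 0 || stats::sd(rec) == 0) NA_real_
           else stats::cor(true, rec)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, horizon = h, n = nrow(m), pearson_r = r,
        slope = slope_through_origin(true, rec),
        bias = mean(rec - true), coverage95 = covered,
        stringsAsFactors = FALSE)
    }
    true <- merged[[p]]; rec <- merged[[paste0("rec_", p)]]
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, horizon = NA_integer_, n = nrow(merged),
      pearson_r = if (stats::sd(true) == 0) NA_real_ else stats::cor(true, rec),
      slope = slope_through_origin(true, rec),
      bias = mean(rec - true),
      coverage95 = mean(true >= merged[[paste0("lo_", p)]] &
                          true <= merged[[paste0("hi_", p)]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d subjects, %d repetition(s)\n",
              x$design$n_subjects, x$design$n_repetitions))
  print(x$report, digits = 3)
  invisible(x)
}

#' Group-level (hyperprior) recovery
#'
#' Simulates subject-level parameters from specified group-level
#' distributions (Gaussian for `A`, `b`; Gamma for the noise spreads),
#' simulates sessions and choices, refits, and compares the recovered
#' posterior of the group-mean noise spreads (`k / lambda`) and their
#' between-horizon differences to the generating truth.
#'
#' @param hypers A data.frame with one row per horizon and columns
#'   `horizon`, `mu_A`, `sd_A`, `mu_b`, `sd_b`, `k_det`, `lam_det`,
#'   `k_ran`, `lam_ran`.
#' @param design A [recovery_design()] (its truth-drawing fields are
#'   ignored; cohort size, sessions and MCMC settings are used).
#' @param seed Seed.
#' @return A list: `truth` (the hypers with implied group means),
#'   `posterior` (recovered summaries per horizon: posterior mean, 95%
#'   interval and truth-coverage flag for the group-mean spreads, plus the
#'   horizon differences), and `fit`.
#' @export
hyperprior_recovery <- function(hypers, design = recovery_design(),
                                seed = 1L) {
  set.seed(seed)
  subjects <- sprintf("s%03d", seq_len(design$n_subjects))
  truth <- do.call(rbind, lapply(seq_len(nrow(hypers)), function(i) {
    h <- hypers[i, ]
    data.frame(subject_id = subjects, horizon = h$horizon,
               A = stats::rnorm(length(subjects), h$mu_A, h$sd_A),
               b = stats::rnorm(length(subjects), h$mu_b, h$sd_b),
               sigma_det = stats::rgamma(length(subjects), h$k_det, h$lam_det),
               sigma_ran = stats::rgamma(length(subjects), h$k_ran, h$lam_ran),
               stringsAsFactors = FALSE)
  }))
  trials <- simulate_cohort(params_from_truth(truth), design$cfg)
  fit <- fit_noise_model(first_free_choices(trials), chains = design$chains,
                         n_samples = design$n_samples,
                         n_burnin = design$n_burnin,
                         n_adapt = design$n_adapt, seed = seed)
  g <- group_posterior_draws(fit)
  rows <- list()
  for (i in seq_len(nrow(hypers))) {
    h <- hypers[i, ]
    gh <- g[g$horizon == h$horizon, ]
    for (nm in c("det", "ran")) {
      tr <- h[[paste0("k_", nm)]] / h[[paste0("lam_", nm)]]
      v <- gh[[paste0("mean_sigma_", nm)]]
      q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = paste0("mean_sigma_", nm), horizon = h$horizon,
        truth = tr, post_mean = mean(v), q2.5 = q[1], q97.5 = q[2],
        covered = tr >= q[1] & tr <= q[2], stringsAsFactors = FALSE)
    }
  }
  if (nrow(hypers) == 2L) {
    for (nm in c("det", "ran")) {
      tr <- hypers[[paste0("k_", nm)]][2] / hypers[[paste0("lam_", nm)]][2] -
        hypers[[paste0("k_", nm)]][1] / hypers[[paste0("lam_", nm)]][1]
      v <- g[[paste0("mean_sigma_", nm)]][g$horizon == hypers$horizon[2]] -
        g[[paste0("mean_sigma_", nm)]][g$horizon == hypers$horizon[1]]
      q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = paste0("diff_sigma_", nm), horizon = NA,
        truth = tr, post_mean = mean(v), q2.5 = q[1], q97.5 = q[2],
        covered = tr >= q[1] & tr <= q[2], stringsAsFactors = FALSE)
    }
  }
  list(truth = hypers, posterior = do.call(rbind, rows), fit = fit)
}

#' Shuffled-truth control for recovery cross-talk
#'
#' Permutes best-fit (or true) noise parameters independently across
#' subjects to form new ground truths, reruns recovery, and reports the
#' cross-correlations between the shuffled truth of one noise type and the
#' recovered values of the other, which should be indistinguishable from
#' zero. With `permutations = NULL` random permutations are drawn; identity
#' permutations reproduce plain recovery.
#'
#' @param base_truth Truth table (columns as in [parameter_recovery()]),
#'   e.g. fitted subject-level means from a previous analysis.
#' @param design A [recovery_design()].
#' @param permutations Optional list with integer vectors `det` and `ran`
#'   (applied within each horizon across subjects).
#' @param seed Seed.
#' @return A list: `report` with per-horizon same- and cross-correlations
#'   and the two-sided 5% critical value for the design's n, `recovery`
#'   (the underlying `recovery_report`).
#' @export
shuffled_control <- function(base_truth, design = recovery_design(),
                             permutations = NULL, seed = 1L) {
  set.seed(seed)
  subjects <- unique(base_truth$subject_id)
  n <- length(subjects)
  if (is.null(permutations))
    permutations <- list(det = sample.int(n), ran = sample.int(n))
  truth <- base_truth
  for (h in unique(truth$horizon)) {
    idx <- which(truth$horizon == h)
    idx <- idx[match(subjects, truth$subject_id[idx])]
    truth$sigma_det[idx] <- base_truth$sigma_det[idx][permutations$det]
    truth$sigma_ran[idx] <- base_truth$sigma_ran[idx][permutations$ran]
  }
  rec <- parameter_recovery(design, truth = truth, seed = seed)
  m <- rec$recovered
  rows <- lapply(sort(unique(m$horizon)), function(h) {
    mm <- m[m$horizon == h, ]
    data.frame(
      horizon = h,
      r_det_det = stats::cor(mm$sigma_det, mm$rec_sigma_det),
      r_ran_ran = stats::cor(mm$sigma_ran, mm$rec_sigma_ran),
      r_ran_true_det_rec = stats::cor(mm$sigma_ran, mm$rec_sigma_det),
      r_det_true_ran_rec = stats::cor(mm$sigma_det, mm$rec_sigma_ran),
      stringsAsFactors = FALSE)
  })
  tcrit <- stats::qt(0.975, n - 2L)
  r_crit <- tcrit / sqrt(n - 2L + tcrit^2)
  list(report = do.call(rbind, rows), r_crit = r_crit,
       permutations = permutations, recovery = rec)
}

#' Reduced-model detection matrix
#'
#' Simulates cohorts from generating models in which each noise type either
#' does or does not change with horizon, fits the full model to each, and
#' reports the posterior probability of a horizon increase and of presence
#' (`P(group-mean spread > presence_eps)`) per noise type. Detection uses
#' declared tail thresholds: a horizon change is flagged when
#' `P(increase) > detect_p`, presence when `P(spread > presence_eps) >
#' detect_p`. A correct method flags a change exactly in the scenarios that
#' generated one.
#'
#' @param scenarios Subset of `"both_dep"`, `"ran_dep"`, `"det_dep"`,
#'   `"none_dep"` (which noise types are horizon-dependent).
#' @param levels Named list of generating spreads: `dep` (length-2, H1/H6
#'   levels when horizon-dependent) and `flat` (constant level otherwise).
#' @param design A [recovery_design()] for cohort size, sessions, MCMC.
#' @param detect_p Posterior tail threshold for detection.
#' @param presence_eps Spread (points) below which a noise is "absent".
#' @param seed Seed.
#' @return A data.frame, one row per scenario x noise type:
#'   `truth_dependent`, `p_increase`, `p_present`, `detected_change`,
#'   `detected_present`.
#' @export
reduced_model_detection <- function(scenarios = c("both_dep", "ran_dep",
                                                  "det_dep", "none_dep"),
                                    levels = list(dep = c(2, 6), flat = 4),
                                    design = recovery_design(),
                                    detect_p = 0.95, presence_eps = 0.5,
                                    seed = 1L) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  out <- list()
  for (sc in scenarios) {
    det_dep <- sc %in% c("both_dep", "det_dep")
    ran_dep <- sc %in% c("both_dep", "ran_dep")
    set.seed(seed + match(sc, c("both_dep", "ran_dep", "det_dep", "none_dep")))
    truth <- draw_recovery_truth(design)
    lev <- function(dep, h) if (dep) levels$dep[match(h, design$cfg$horizons)]
                            else levels$flat
    truth$sigma_det <- vapply(truth$horizon, function(h) lev(det_dep, h),
                              numeric(1))
    truth$sigma_ran <- vapply(truth$horizon, function(h) lev(ran_dep, h),
                              numeric(1))
    rec <- parameter_recovery(design, truth = truth, seed = seed)
    g <- group_posterior_draws(rec$fit)
    g1 <- g[g$horizon == design$cfg$horizons[1], ]
    g2 <- g[g$horizon == design$cfg$horizons[2], ]
    for (nm in c("det", "ran")) {
      v1 <- g1[[paste0("mean_sigma_", nm)]]
      v2 <- g2[[paste0("mean_sigma_", nm)]]
      p_inc <- mean(v2 > v1)
      p_pres <- mean(c(v1, v2) > presence_eps)
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, noise = nm,
        truth_dependent = if (nm == "det") det_dep else ran_dep,
        p_increase = p_inc, p_present = p_pres,
        detected_change = p_inc > detect_p,
        detected_present = p_pres > detect_p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Posterior predictive check of the model-free statistics
#'
#' Takes the subject-level posterior-mean parameters from a fit, has the
#' agent replay each subject's original game sequence `n_rep` times (fresh
#' noise each replicate), recomputes the model-free statistics, and
#' compares the observed group means to the simulated distribution:
#' `p_high_info`, `p_low_mean` per horizon and `p_inconsistent` per
#' horizon and information condition, each with the simulated mean, a 95%
#' band across replicates, and the analytic pure-random and
#' pure-deterministic bounds from the observed data.
#'
#' @param fit A `noise_fit`.
#' @param games_by_subject Named list (by subject id) of `horizon_games`
#'   sessions -- the stimuli each subject actually saw.
#' @param cfg The [task_config()] of those sessions.
#' @param observed_fc The observed `first_choices` table.
#' @param n_rep Number of simulated replicates.
#' @param seed Seed.
#' @return A data.frame, one row per statistic x cell: observed value,
#'   simulated mean and 95% band, inside-band flag, and the pure-noise
#'   bounds for the inconsistency rows.
#' @export
posterior_predictive_check <- function(fit, games_by_subject, cfg,
                                       observed_fc, n_rep = 20L, seed = 1L) {
  sp <- subject_posterior(fit)
  subjects <- unique(sp$subject_id)
  missing <- setdiff(subjects, names(games_by_subject))
  if (length(missing))
    stop("missing game sequences for subject(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  par_list <- lapply(subjects, function(s) {
    rows <- sp[sp$subject_id == s & sp$info_condition == "all", ]
    hs <- sort(unique(rows$horizon))
    ps <- lapply(hs, function(h) {
      val <- function(p) {
        r <- rows[rows$horizon == h & rows$parameter == p, "mean"]
        if (length(r)) r else 0
      }
      subject_params(A = val("A"), b = val("b"),
                     sigma_det = max(val("sigma_det"), 0),
                     sigma_ran = max(val("sigma_ran"), 0))
    })
    stats::setNames(ps, paste0("h", hs))
  })
  names(par_list) <- subjects
  set.seed(seed)
  sim_stats <- lapply(seq_len(n_rep), function(rep) {
    trials <- do.call(rbind, lapply(subjects, function(s) {
      play_session(games_by_subject[[s]], par_list[[s]], cfg, subject_id = s)
    }))
    class(trials) <- c("horizon_trials", "data.frame")
    group_mean_stats(model_free_stats(first_free_choices(trials)))
  })
  obs <- group_mean_stats(model_free_stats(observed_fc))
  sim_mat <- do.call(rbind, lapply(sim_stats, function(s) s$value))
  bands <- apply(sim_mat, 2, stats::quantile, probs = c(0.025, 0.975),
                 na.rm = TRUE)
  out <- data.frame(
    statistic = obs$statistic, horizon = obs$horizon,
    info_condition = obs$info_condition, observed = obs$value,
    sim_mean = colMeans(sim_mat, na.rm = TRUE),
    sim_lo = bands[1, ], sim_hi = bands[2, ],
    stringsAsFactors = FALSE)
  out$inside_band <- out$observed >= out$sim_lo & out$observed <= out$sim_hi
  out$pure_deterministic <- ifelse(grepl("inconsistent", out$statistic), 0, NA)
  out$pure_random <- NA_real_
  mf_obs <- model_free_stats(observed_fc)
  for (i in which(grepl("inconsistent", out$statistic))) {
    ic <- out$info_condition[i]
    col <- paste0("pred_random_", ic)
    out$pure_random[i] <- mean(mf_obs[mf_obs$horizon == out$horizon[i], col],
                               na.rm = TRUE)
  }
  rownames(out) <- NULL
  out
}

# Group means of the per-subject model-free statistics, long format.
group_mean_stats <- function(mf) {
  rows <- list()
  for (h in sort(unique(mf$horizon))) {
    m <- mf[mf$horizon == h, ]
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = c("p_high_info", "p_low_mean", "p_inconsistent",
                    "p_inconsistent"),
      horizon = h, info_condition = c("13", "22", "13", "22"),
      value = c(mean(m$p_high_info, na.rm = TRUE),
                mean(m$p_low_mean, na.rm = TRUE),
                mean(m$p_inconsistent_13, na.rm = TRUE),
                mean(m$p_inconsistent_22, na.rm = TRUE)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
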