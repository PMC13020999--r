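#' Sample the posterior with MCMC (JAGS)
#'
#' Runs independent Markov chains on a [build_posterior()] model, discards a
#' burn-in period and returns the retained draws. Defaults mirror the
#' reference fitting procedure (10 chains of 5000 retained samples after a
#' 5000-sample burn-in, thin 1); reduced settings are used for the scaled
#' validation experiments. Per-chain RNG seeds are derived deterministically
#' from the master seed, so identical calls produce identical draws.
#'
#' If JAGS fails to initialise (non-finite density at the starting point),
#' initial values are jittered and initialisation retried up to
#' `max_retries` times.
#'
#' @param model A `noise_model` from [build_posterior()].
#' @param chains Number of chains (>= 2 recommended for diagnostics).
#' @param n_samples Retained samples per chain.
#' @param n_burnin Burn-in samples per chain (discarded).
#' @param thin Thinning interval.
#' @param n_adapt Sampler adaptation iterations (also discarded).
#' @param seed Master seed.
#' @param monitor_latent Also record the latent per-pair noise values.
#' @param max_retries Re-initialisation attempts on failure.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `noise_fit`: `draws` (a [coda::mcmc.list]),
#'   the `model`, and the MCMC settings.
#' @export
run_mcmc <- function(model, chains = 10L, n_samples = 5000L,
                     n_burnin = 5000L, thin = 1L, n_adapt = 500L,
                     seed = 1L, monitor_latent = FALSE, max_retries = 3L,
                     quiet = TRUE) {
  stopifnot(inherits(model, "noise_model"), chains >= 1L, thin >= 1L)
  monitors <- model$monitors
  if (monitor_latent && !"no_det" %in% model$variant)
    monitors <- c(monitors, "ndet")
  jm <- NULL
  for (attempt in seq_len(max_retries + 1L)) {
    inits <- lapply(seq_len(chains), function(ch) {
      noise_model_inits(model, chain_seed = seed + 7919L * ch + attempt - 1L,
                        jitter = 0.2 * (attempt - 1L))
    })
    jm <- tryCatch(
      rjags::jags.model(textConnection(model$code), data = model$data,
                        inits = inits, n.chains = chains, n.adapt = n_adapt,
                        quiet = quiet),
      error = function(e) if (attempt > max_retries) stop(e) else NULL)
    if (!is.null(jm)) break
  }
  if (n_burnin > 0L)
    stats::update(jm, n.iter = n_burnin, progress.bar = if (quiet) "none" else "text")
  draws <- rjags::coda.samples(jm, variable.names = monitors,
                               n.iter = n_samples * thin, thin = thin,
                               progress.bar = if (quiet) "none" else "text")
  structure(list(draws = draws, model = model,
                 mcmc = list(chains = chains, n_samples = n_samples,
                             n_burnin = n_burnin, thin = thin,
                             n_adapt = n_adapt, seed = seed)),
            class = "noise_fit")
}

#' Fit the hierarchical two-noise model to first free choices
#'
#' Convenience wrapper: [build_posterior()] followed by [run_mcmc()].
#'
#' @inheritParams build_posterior
#' @inheritParams run_mcmc
#' @param ... Passed to [run_mcmc()].
#' @return A `noise_fit`.
#' @examples
#' \donttest{
#' set.seed(2)
#' cfg <- task_config(n_games = 24, repeat_fraction = 2/3, min_pair_separation = 2)
#' pars <- lapply(1:4, function(s)
#'   list(h1 = subject_params(sigma_det = 2, sigma_ran = 4),
#'        h6 = subject_params(A = 3, sigma_det = 3, sigma_ran = 7)))
#' fc <- first_free_choices(simulate_cohort(pars, cfg))
#' fit <- fit_noise_model(fc, chains = 2, n_samples = 200, n_burnin = 200)
#' subject_posterior(fit)[1:4, ]
#' }
#' @export
fit_noise_model <- function(fc, priors = hyperprior_config(),
                            variant = character(), chains = 10L,
                            n_samples = 5000L, n_burnin = 5000L,
                            seed = 1L, ...) {
  model <- build_posterior(fc, priors = priors, variant = variant)
  run_mcmc(model, chains = chains, n_samples = n_samples,
           n_burnin = n_burnin, seed = seed, ...)
}

#' @export
print.noise_fit <- function(x, ...) {
  cat("Hierarchical two-noise model fit\n")
  print(x$model)
  cat(sprintf("  MCMC: %d chains x %d retained (burn-in %d, thin %d, seed %s)\n",
              x$mcmc$chains, x$mcmc$n_samples, x$mcmc$n_burnin, x$mcmc$thin,
              format(x$mcmc$seed)))
  invisible(x)
}

# Draws of one scalar JAGS node as an iterations x chains matrix.
node_matrix <- function(fit, node) {
  sapply(fit$draws, function(ch) as.numeric(ch[, node]))
}

#' Subject-level posterior summaries
#'
#' Posterior mean, SD and central 95% interval of each subject-level
#' parameter (`A`, `b`, `sigma_det`, `sigma_ran`) per subject and horizon.
#' With the `"sigma_by_info"` variant the noise parameters are additionally
#' indexed by information condition.
#'
#' @param fit A `noise_fit`.
#' @return A long data.frame: `subject_id`, `horizon`, `info_condition`
#'   (`"all"` unless the variant splits it), `parameter`, `mean`, `sd`,
#'   `q2.5`, `q97.5`.
#' @export
subject_posterior <- function(fit) {
  m <- fit$model
  post <- as.matrix(fit$draws)
  out <- list()
  grab <- function(node, param, s, i, c = NULL) {
    col <- if (is.null(c)) sprintf("%s[%d,%d]", node, s, i)
           else sprintf("%s[%d,%d,%d]", node, s, i, c)
    v <- post[, col]
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    data.frame(subject_id = m$subjects[s], horizon = m$horizons[i],
               info_condition = if (is.null(c)) "all" else m$conds[c],
               parameter = param, mean = mean(v), sd = stats::sd(v),
               q2.5 = q[1], q97.5 = q[2], stringsAsFactors = FALSE)
  }
  for (s in seq_along(m$subjects)) {
    for (i in seq_along(m$horizons)) {
      out[[length(out) + 1L]] <- grab("A", "A", s, i)
      out[[length(out) + 1L]] <- grab("b", "b", s, i)
      for (c in seq_along(m$conds)) {
        if (!"no_det" %in% m$variant)
          out[[length(out) + 1L]] <- grab("sdet", "sigma_det", s, i, c)
        if (!"no_ran" %in% m$variant)
          out[[length(out) + 1L]] <- grab("sran", "sigma_ran", s, i, c)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-level posterior draws
#'
#' One row per retained MCMC draw with the group-level hyperparameters per
#' horizon and the implied group-mean noise spreads `k / lambda` (the Gamma
#' prior mean).
#'
#' @param fit A `noise_fit`.
#' @param cond Information-condition index (only relevant under
#'   `"sigma_by_info"`).
#' @return A data.frame with columns `chain`, `iteration`, `horizon`,
#'   `mu_A`, `sd_A`, `mu_b`, `sd_b`, and (when present) `k_det`, `lam_det`,
#'   `k_ran`, `lam_ran`, `mean_sigma_det`, `mean_sigma_ran`.
#' @export
group_posterior_draws <- function(fit, cond = 1L) {
  m <- fit$model
  n_iter <- nrow(fit$draws[[1]])
  chains <- length(fit$draws)
  out <- list()
  for (i in seq_along(m$horizons)) {
    df <- data.frame(
      chain = rep(seq_len(chains), each = n_iter),
      iteration = rep(seq_len(n_iter), chains),
      horizon = m$horizons[i],
      mu_A = as.numeric(node_matrix(fit, sprintf("mu_A[%d]", i))),
      sd_A = as.numeric(node_matrix(fit, sprintf("sd_A[%d]", i))),
      mu_b = as.numeric(node_matrix(fit, sprintf("mu_b[%d]", i))),
      sd_b = as.numeric(node_matrix(fit, sprintf("sd_b[%d]", i)))
    )
    if (!"no_det" %in% m$variant) {
      lev <- m$data$hmap_det[i]
      df$k_det <- as.numeric(node_matrix(fit, sprintf("k_det[%d,%d]", lev, cond)))
      df$lam_det <- as.numeric(node_matrix(fit, sprintf("lam_det[%d,%d]", lev, cond)))
      df$mean_sigma_det <- df$k_det / df$lam_det
    }
    if (!"no_ran" %in% m$variant) {
      lev <- m$data$hmap_ran[i]
      df$k_ran <- as.numeric(node_matrix(fit, sprintf("k_ran[%d,%d]", lev, cond)))
      df$lam_ran <- as.numeric(node_matrix(fit, sprintf("lam_ran[%d,%d]", lev, cond)))
      df$mean_sigma_ran <- df$k_ran / df$lam_ran
    }
    out[[i]] <- df
  }
  do.call(rbind, out)
}

#' Split-R-hat and effective sample size diagnostics
#'
#' Computes the split-chain potential scale reduction factor (each chain is
#' halved, so `m` chains yield `2m` sequences) and the effective sample
#' size (via [coda::effectiveSize()]) for every monitored parameter. The
#' `pass` flag requires split-R-hat < 1.1 on all parameters and effective
#' sample size > 400 on the group-level parameters.
#'
#' @param fit A `noise_fit`, or a [coda::mcmc.list].
#' @param rhat_max,ess_min Pass thresholds.
#' @return A list with `table` (per-parameter `rhat`, `ess`, `group_level`),
#'   `pass`, and `limited` (`TRUE` when only one chain is available, in
#'   which case R-hat is split within the single chain and flagged).
#' @export
convergence_check <- function(fit, rhat_max = 1.1, ess_min = 400) {
  draws <- if (inherits(fit, "noise_fit")) fit$draws else fit
  stopifnot(inherits(draws, "mcmc.list"))
  pars <- colnames(draws[[1]])
  limited <- length(draws) < 2L
  rhat <- vapply(pars, function(p) {
    split_rhat(sapply(draws, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  ess <- vapply(pars, function(p) {
    sum(vapply(draws, function(ch) unname(coda::effectiveSize(ch[, p])),
               numeric(1)))
  }, numeric(1))
  group_level <- grepl("^(mu_|sd_|k_|lam_)", pars)
  tab <- data.frame(parameter = pars, rhat = rhat, ess = ess,
                    group_level = group_level, stringsAsFactors = FALSE,
                    row.names = NULL)
  pass <- all(tab$rhat < rhat_max, na.rm = TRUE) &&
    all(tab$ess[tab$group_level] > ess_min) && !limited
  list(table = tab, pass = pass, limited = limited)
}

#' Split-chain potential scale reduction factor
#'
#' Textbook split-R-hat: chains are split in half, and
#' `R-hat = sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean
#' within-sequence variance and `B/n` the between-sequence variance of the
#' sequence means. Values near 1 indicate the sequences are mixing over the
#' same distribution.
#'
#' @param x Matrix of draws, iterations x chains (a single chain as a
#'   one-column matrix is split into two sequences).
#' @return The split-R-hat value (`NA` if fewer than 4 iterations).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  seqs <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1L):n, j])
  }))
  m <- ncol(seqs)
  n <- nrow(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(ifelse(B == 0, 1, Inf))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Derived posterior quantities
#'
#' Per retained draw, forms the group-level mean noise spreads (`k /
#' lambda`) per horizon and computes: the deterministic fraction of noise
#' variance `sigma_det^2 / (sigma_det^2 + sigma_ran^2)` (per horizon and
#' pooled over horizons by averaging the group means; the pooled version is
#' the headline number), the between-horizon ratios
#' `sigma(H6) / sigma(H1)` per noise type, and the posterior probability
#' that each noise type increases with horizon. Summaries are posterior
#' means with central 95% intervals.
#'
#' @param fit A `noise_fit` of the full model over two horizons.
#' @return A list with `draws` (per-draw derived quantities) and `summary`
#'   (a data.frame of posterior means and 95% intervals).
#' @export
derived_summaries <- function(fit) {
  m <- fit$model
  if ("no_det" %in% m$variant || "no_ran" %in% m$variant)
    stop("derived_summaries needs both noise components in the model",
         call. = FALSE)
  if (length(m$horizons) != 2L)
    stop("derived_summaries expects two horizon conditions", call. = FALSE)
  g <- group_posterior_draws(fit)
  g1 <- g[g$horizon == m$horizons[1], ]
  g2 <- g[g$horizon == m$horizons[2], ]
  sdet_pool <- (g1$mean_sigma_det + g2$mean_sigma_det) / 2
  sran_pool <- (g1$mean_sigma_ran + g2$mean_sigma_ran) / 2
  draws <- data.frame(
    chain = g1$chain, iteration = g1$iteration,
    det_fraction = sdet_pool^2 / (sdet_pool^2 + sran_pool^2),
    det_fraction_h1 = g1$mean_sigma_det^2 /
      (g1$mean_sigma_det^2 + g1$mean_sigma_ran^2),
    det_fraction_h6 = g2$mean_sigma_det^2 /
      (g2$mean_sigma_det^2 + g2$mean_sigma_ran^2),
    ratio_det = g2$mean_sigma_det / g1$mean_sigma_det,
    ratio_ran = g2$mean_sigma_ran / g1$mean_sigma_ran,
    diff_det = g2$mean_sigma_det - g1$mean_sigma_det,
    diff_ran = g2$mean_sigma_ran - g1$mean_sigma_ran
  )
  summarise <- function(v) c(mean = mean(v),
                             stats::quantile(v, c(0.025, 0.975), names = FALSE))
  qs <- t(vapply(draws[, -(1:2)], summarise, numeric(3)))
  summary <- data.frame(quantity = rownames(qs), mean = qs[, 1],
                        q2.5 = qs[, 2], q97.5 = qs[, 3],
                        row.names = NULL, stringsAsFactors = FALSE)
  summary <- rbind(summary, data.frame(
    quantity = c("p_increase_det", "p_increase_ran"),
    mean = c(mean(draws$diff_det > 0), mean(draws$diff_ran > 0)),
    q2.5 = NA_real_, q97.5 = NA_real_, stringsAsFactors = FALSE))
  list(draws = draws, summary = summary)
}
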