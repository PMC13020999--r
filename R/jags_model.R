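#' Hyperprior configuration for the hierarchical model
#'
#' Group-level priors per horizon: Gaussian priors on the information bonus
#' and spatial bias (means with Gaussian hyperpriors, spreads with
#' Exponential hyperpriors) and Gamma(shape `k`, rate `lambda`) priors on
#' the two noise spreads, with Exponential hyperpriors on `k` and `lambda`.
#' The Gamma prior mean is `k / lambda` (shape-rate parameterisation, the
#' JAGS convention).
#'
#' Defaults are the broad hyperpriors of the model: `mu ~ Gaussian(0, 100)`,
#' `sd ~ Exponential(0.01)`, `k ~ Exponential(0.01)`,
#' `lambda ~ Exponential(10)`. A narrower variant
#' (`mu ~ Gaussian(0, 10)`, `sd ~ Exponential(0.1)`) can be selected with
#' `hyperprior_config(mu_sd = 10, sd_rate = 0.1)`.
#'
#' @param mu_mean,mu_sd Gaussian hyperprior on the group means of `A`, `b`.
#' @param sd_rate Exponential hyperprior rate on the group spreads of `A`, `b`.
#' @param k_rate,lambda_rate Exponential hyperprior rates on the Gamma shape
#'   and rate of the noise-spread priors.
#' @param gaussian_param `"sd"` (default) treats the Gaussian second
#'   parameter as a standard deviation; `"precision"` reinterprets `mu_sd`
#'   as a precision for cross-checking against precision-convention
#'   samplers.
#' @return An object of class `hyperprior_config`.
#' @export
hyperprior_config <- function(mu_mean = 0, mu_sd = 100, sd_rate = 0.01,
                              k_rate = 0.01, lambda_rate = 10,
                              gaussian_param = c("sd", "precision")) {
  gaussian_param <- match.arg(gaussian_param)
  stopifnot(mu_sd > 0, sd_rate > 0, k_rate > 0, lambda_rate > 0)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd, sd_rate = sd_rate,
                 k_rate = k_rate, lambda_rate = lambda_rate,
                 gaussian_param = gaussian_param),
            class = "hyperprior_config")
}

noise_variants <- c("sigma_by_info", "variance_dI", "no_det", "no_ran",
                    "det_fixed_across_horizon", "ran_fixed_across_horizon")

check_variant <- function(variant) {
  unknown <- setdiff(variant, noise_variants)
  if (length(unknown))
    stop("unknown variant flag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (all(c("no_det", "det_fixed_across_horizon") %in% variant))
    stop("contradictory flags: no_det + det_fixed_across_horizon",
         call. = FALSE)
  if (all(c("no_ran", "ran_fixed_across_horizon") %in% variant))
    stop("contradictory flags: no_ran + ran_fixed_across_horizon",
         call. = FALSE)
  variant
}

#' Build the hierarchical two-noise posterior
#'
#' Assembles the joint model fitted by [run_mcmc()]: per horizon `i` and
#' subject `s`, `A[s,i] ~ Gaussian(mu_A[i], sd_A[i])`,
#' `b[s,i] ~ Gaussian(mu_b[i], sd_b[i])`,
#' `sigma_det[s,i] ~ Gamma(k_det[i], lambda_det[i])` and
#' `sigma_ran[s,i] ~ Gamma(k_ran[i], lambda_ran[i])`, with the hyperpriors
#' of [hyperprior_config()]. Each repeated game pair (and each unpaired
#' game) carries one latent deterministic-noise value
#' `n_det ~ Logistic(0, sigma_det[s,i])` shared by both presentations, and
#' each first free choice is Bernoulli with
#' `P(right) = logistic((delta_R + A*delta_I + b + n_det) / sigma_ran)`.
#'
#' Variant flags modify the posterior: `"sigma_by_info"` estimates the
#' noise spreads separately per information condition; `"variance_dI"`
#' replaces the categorical `delta_I` with the difference of forced-reward
#' sample variances (requires a `delta_V` column, see
#' [add_variance_information()]); `"no_det"` / `"no_ran"` drop a noise
#' component; `"det_fixed_across_horizon"` /
#' `"ran_fixed_across_horizon"` share the corresponding group-level prior
#' across horizons.
#'
#' Subjects lacking rows in one of the horizons are dropped with a warning.
#'
#' @param fc A `first_choices` data.frame ([first_free_choices()]).
#' @param priors A [hyperprior_config()].
#' @param variant Character vector of variant flags (empty for the full
#'   model).
#' @param fixed_hypers Optional list pinning the group-level parameters to
#'   known constants instead of sampling them: elements `mu_A`, `sd_A`,
#'   `mu_b`, `sd_b` (vectors over horizons) and `k_det`, `lam_det`,
#'   `k_ran`, `lam_ran` (matrices horizon-level x condition, or vectors
#'   recycled). Used for prior-identity checks and toy-posterior oracles.
#' @param prior_only If `TRUE`, drop the likelihood so that sampling
#'   returns draws from the prior (the data still define the index
#'   structure).
#' @return An object of class `noise_model`: the JAGS model string, the data
#'   list, index maps for subjects/horizons/pair units, and an init
#'   generator.
#' @export
build_posterior <- function(fc, priors = hyperprior_config(),
                            variant = character(), fixed_hypers = NULL,
                            prior_only = FALSE) {
  stopifnot(inherits(priors, "hyperprior_config"))
  variant <- check_variant(variant)
  horizons <- sort(unique(fc$horizon))
  by_sub <- table(fc$subject_id, fc$horizon)
  complete <- rownames(by_sub)[apply(by_sub > 0, 1, all)]
  dropped <- setdiff(unique(fc$subject_id), complete)
  if (length(dropped)) {
    warning("dropping subject(s) missing a horizon: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    fc <- fc[fc$subject_id %in% complete, , drop = FALSE]
  }
  if (!nrow(fc)) stop("no data left to fit", call. = FALSE)
  subjects <- sort(unique(fc$subject_id))
  tsub <- match(fc$subject_id, subjects)
  thor <- match(fc$horizon, horizons)
  use_cond <- "sigma_by_info" %in% variant
  conds <- if (use_cond) c("13", "22") else "all"
  tcond <- if (use_cond) match(fc$info_condition, conds) else rep(1L, nrow(fc))
  dI <- if ("variance_dI" %in% variant) {
    if (is.null(fc$delta_V))
      stop("variance_dI requires a delta_V column; see add_variance_information()",
           call. = FALSE)
    fc$delta_V
  } else fc$delta_I
  unit_key <- ifelse(is.na(fc$pair_id),
                     paste0(tsub, ".g", fc$game_id),
                     paste0(tsub, ".p", fc$pair_id))
  units <- unique(unit_key)
  tunit <- match(unit_key, units)
  first_of_unit <- match(units, unit_key)
  no_det <- "no_det" %in% variant
  no_ran <- "no_ran" %in% variant
  hmap_det <- if ("det_fixed_across_horizon" %in% variant)
    rep(1L, length(horizons)) else seq_along(horizons)
  hmap_ran <- if ("ran_fixed_across_horizon" %in% variant)
    rep(1L, length(horizons)) else seq_along(horizons)
  mu_prec <- if (priors$gaussian_param == "sd") priors$mu_sd^-2 else priors$mu_sd
  data <- list(
    NS = length(subjects), NH = length(horizons), NC = length(conds),
    NT = nrow(fc), y = as.integer(fc$chose_right), dR = fc$delta_R,
    dI = as.numeric(dI), tsub = tsub, thor = thor, tcond = tcond,
    hp_mu_mean = priors$mu_mean, hp_mu_prec = mu_prec,
    hp_sd_rate = priors$sd_rate, hp_k_rate = priors$k_rate,
    hp_lam_rate = priors$lambda_rate,
    NDL = max(hmap_det), NRL = max(hmap_ran),
    hmap_det = hmap_det, hmap_ran = hmap_ran
  )
  if (!no_det) {
    data$NU <- length(units)
    data$tunit <- tunit
    data$usub <- tsub[first_of_unit]
    data$uhor <- thor[first_of_unit]
    data$ucond <- tcond[first_of_unit]
  }
  fixed <- !is.null(fixed_hypers)
  if (fixed) {
    as_mat <- function(x, nr) matrix(x, nrow = nr, ncol = data$NC)
    data$mu_A <- rep(fixed_hypers$mu_A, length.out = data$NH)
    data$sd_A <- rep(fixed_hypers$sd_A, length.out = data$NH)
    data$mu_b <- rep(fixed_hypers$mu_b, length.out = data$NH)
    data$sd_b <- rep(fixed_hypers$sd_b, length.out = data$NH)
    if (!no_det) {
      data$k_det <- as_mat(fixed_hypers$k_det, data$NDL)
      data$lam_det <- as_mat(fixed_hypers$lam_det, data$NDL)
    }
    if (!no_ran) {
      data$k_ran <- as_mat(fixed_hypers$k_ran, data$NRL)
      data$lam_ran <- as_mat(fixed_hypers$lam_ran, data$NRL)
    }
    data$hp_mu_mean <- data$hp_mu_prec <- data$hp_sd_rate <- NULL
    data$hp_k_rate <- data$hp_lam_rate <- NULL
  }
  if (prior_only)
    data[c("y", "NT", "dR", "dI", "tsub", "thor", "tcond", "tunit")] <- NULL
  if (fixed || no_det) data$NDL <- NULL
  if (fixed || no_ran) data$NRL <- NULL
  if (fixed)
    data[c("hp_mu_mean", "hp_mu_prec", "hp_sd_rate", "hp_k_rate",
           "hp_lam_rate")] <- NULL
  model <- structure(list(
    code = jags_model_code(no_det = no_det, no_ran = no_ran,
                           fixed = fixed, prior_only = prior_only),
    data = data, subjects = subjects, horizons = horizons, conds = conds,
    variant = variant, priors = priors, fixed_hypers = fixed_hypers,
    prior_only = prior_only,
    monitors = jags_monitors(no_det = no_det, no_ran = no_ran, fixed = fixed)
  ), class = "noise_model")
  model
}

jags_monitors <- function(no_det, no_ran, fixed = FALSE) {
  mon <- c("A", "b")
  if (!fixed) mon <- c(mon, "mu_A", "sd_A", "mu_b", "sd_b")
  if (!no_det) {
    mon <- c(mon, "sdet")
    if (!fixed) mon <- c(mon, "k_det", "lam_det")
  }
  if (!no_ran) {
    mon <- c(mon, "sran")
    if (!fixed) mon <- c(mon, "k_ran", "lam_ran")
  }
  mon
}

jags_model_code <- function(no_det, no_ran, fixed = FALSE,
                            prior_only = FALSE) {
  hyper <- if (fixed) "
  for (i in 1:NH) {
    tau_A[i] <- pow(sd_A[i], -2)
    tau_b[i] <- pow(sd_b[i], -2)
  }" else "
  for (i in 1:NH) {
    mu_A[i] ~ dnorm(hp_mu_mean, hp_mu_prec)
    sd_A[i] ~ dexp(hp_sd_rate)
    tau_A[i] <- pow(sd_A[i], -2)
    mu_b[i] ~ dnorm(hp_mu_mean, hp_mu_prec)
    sd_b[i] ~ dexp(hp_sd_rate)
    tau_b[i] <- pow(sd_b[i], -2)
  }"
  det_hyper <- if (no_det || fixed) "" else "
  for (i in 1:NDL) {
    for (c in 1:NC) {
      k_det[i,c] ~ dexp(hp_k_rate)
      lam_det[i,c] ~ dexp(hp_lam_rate)
    }
  }"
  ran_hyper <- if (no_ran || fixed) "" else "
  for (i in 1:NRL) {
    for (c in 1:NC) {
      k_ran[i,c] ~ dexp(hp_k_rate)
      lam_ran[i,c] ~ dexp(hp_lam_rate)
    }
  }"
  subj <- paste0("
  for (s in 1:NS) {
    for (i in 1:NH) {
      A[s,i] ~ dnorm(mu_A[i], tau_A[i])
      b[s,i] ~ dnorm(mu_b[i], tau_b[i])",
    if (no_det) "" else "
      for (c in 1:NC) {
        sdet[s,i,c] ~ dgamma(k_det[hmap_det[i],c], lam_det[hmap_det[i],c])
      }",
    if (no_ran) "" else "
      for (c in 1:NC) {
        sran[s,i,c] ~ dgamma(k_ran[hmap_ran[i],c], lam_ran[hmap_ran[i],c])
      }", "
    }
  }")
  latent <- if (no_det) "" else "
  for (u in 1:NU) {
    ndet[u] ~ dlogis(0, 1 / sdet[usub[u], uhor[u], ucond[u]])
  }"
  drive <- paste0("dR[t] + A[tsub[t],thor[t]] * dI[t] + b[tsub[t],thor[t]]",
                  if (no_det) "" else " + ndet[tunit[t]]")
  lik <- if (prior_only) "" else if (no_ran) sprintf("
  for (t in 1:NT) {
    drive[t] <- %s
    p[t] <- 1.0E-6 + (1 - 2.0E-6) * step(drive[t])
    y[t] ~ dbern(p[t])
  }", drive) else sprintf("
  for (t in 1:NT) {
    drive[t] <- %s
    p[t] <- ilogit(drive[t] / sran[tsub[t],thor[t],tcond[t]])
    y[t] ~ dbern(p[t])
  }", drive)
  paste0("model {", hyper, det_hyper, ran_hyper, subj, latent, lik, "\n}\n")
}

# Initial values for one chain; jitter > 0 perturbs the starting point on
# re-initialisation retries.
noise_model_inits <- function(model, chain_seed, jitter = 0) {
  d <- model$data
  no_det <- "no_det" %in% model$variant
  no_ran <- "no_ran" %in% model$variant
  fixed <- !is.null(model$fixed_hypers)
  set.seed(chain_seed)
  jit <- function(x) x * exp(stats::rnorm(length(x), 0, jitter))
  a_centre <- if (fixed) d$mu_A else rep(0, d$NH)
  b_centre <- if (fixed) d$mu_b else rep(0, d$NH)
  sdet0 <- if (fixed) pmax(d$k_det[1] / d$lam_det[1], 0.1) else 2
  sran0 <- if (fixed) pmax(d$k_ran[1] / d$lam_ran[1], 0.1) else 5
  inits <- list(
    A = matrix(a_centre, d$NS, d$NH, byrow = TRUE),
    b = matrix(b_centre, d$NS, d$NH, byrow = TRUE),
    .RNG.name = "base::Mersenne-Twister", .RNG.seed = chain_seed
  )
  if (!fixed) {
    inits$mu_A <- rep(0, d$NH); inits$sd_A <- jit(rep(5, d$NH))
    inits$mu_b <- rep(0, d$NH); inits$sd_b <- jit(rep(5, d$NH))
  }
  if (!no_det) {
    if (!fixed) {
      inits$k_det <- matrix(jit(rep(2, d$NDL * d$NC)), d$NDL, d$NC)
      inits$lam_det <- matrix(jit(rep(1, d$NDL * d$NC)), d$NDL, d$NC)
    }
    inits$sdet <- array(jit(rep(sdet0, d$NS * d$NH * d$NC)),
                        c(d$NS, d$NH, d$NC))
    inits$ndet <- rep(0, d$NU)
  }
  if (!no_ran) {
    if (!fixed) {
      inits$k_ran <- matrix(jit(rep(2, d$NRL * d$NC)), d$NRL, d$NC)
      inits$lam_ran <- matrix(jit(rep(1, d$NRL * d$NC)), d$NRL, d$NC)
    }
    inits$sran <- array(jit(rep(sran0, d$NS * d$NH * d$NC)),
                        c(d$NS, d$NH, d$NC))
  }
  inits
}

#' @export
print.noise_model <- function(x, ...) {
  cat("Hierarchical two-noise choice model\n")
  cat(sprintf("  %d subjects, %d horizons, %d observations, %s latent pair-noise values\n",
              x$data$NS, x$data$NH, x$data$NT,
              if (is.null(x$data$NU)) "no" else x$data$NU))
  if (length(x$variant)) cat("  variant:", paste(x$variant, collapse = ", "), "\n")
  invisible(x)
}

#' Attach the variance-based information difference
#'
#' Computes, per game, the difference of the forced-reward sample variances
#' (right minus left, population formula so that a single forced play has
#' variance 0) and attaches it to a `first_choices` table as `delta_V`, the
#' non-categorical information regressor used by the `"variance_dI"` model
#' variant.
#'
#' @param fc A `first_choices` data.frame.
#' @param trials The `horizon_trials` table the first choices came from.
#' @return `fc` with a `delta_V` column.
#' @export
add_variance_information <- function(fc, trials) {
  validate_trials(trials)
  forced <- trials[trials$trial_index <= 4L, , drop = FALSE]
  key <- paste(forced$subject_id, forced$game_id)
  popvar <- function(x) mean((x - mean(x))^2)
  vr <- tapply(seq_len(nrow(forced)), key, function(idx) {
    f <- forced[idx, ]
    r <- f$reward[f$side == "right"]; l <- f$reward[f$side == "left"]
    popvar(r) - popvar(l)
  })
  fc$delta_V <- as.numeric(vr[paste(fc$subject_id, fc$game_id)])
  fc
}

#' Log-likelihood of a repeated pair given the frozen noise
#'
#' Sum over the pair's presentations of the Bernoulli log-probability of the
#' observed side, with the shared deterministic-noise value entering both.
#' With `sigma_ran = 0` an impossible observed choice yields `-Inf` (not an
#' error).
#'
#' @param params A [subject_params()].
#' @param n_det Shared deterministic-noise value, points.
#' @param rows One or two rows of a `first_choices` table (the pair).
#' @return Log-probability.
#' @export
pair_log_likelihood <- function(params, n_det, rows) {
  p <- vapply(seq_len(nrow(rows)), function(i) {
    choice_prob_right(params, rows$delta_R[i], rows$delta_I[i], n_det)
  }, numeric(1))
  obs <- ifelse(rows$chose_right, p, 1 - p)
  sum(log(obs))
}

#' Marginal quantities by quadrature over the frozen noise
#'
#' Cross-check utilities that integrate over the logistic prior of the
#' deterministic noise numerically (the MCMC model instead samples it as a
#' latent variable). `marginal_choice_prob` is the marginal probability of
#' choosing right; `marginal_pair_agreement` is the probability that the two
#' first free choices of a repeated pair agree, using the fact that the
#' frozen value is shared while random noise is independent.
#'
#' @inheritParams pair_log_likelihood
#' @param delta_R,delta_I Stimulus summary of the (shared) pair stimulus.
#' @return A probability.
#' @export
marginal_choice_prob <- function(params, delta_R, delta_I) {
  if (params$sigma_det == 0)
    return(choice_prob_right(params, delta_R, delta_I, 0))
  f <- function(x) stats::dlogis(x, 0, params$sigma_det) *
    choice_prob_right(params, delta_R, delta_I, x)
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
}

#' @rdname marginal_choice_prob
#' @export
marginal_pair_agreement <- function(params, delta_R, delta_I) {
  if (params$sigma_det == 0) {
    p <- choice_prob_right(params, delta_R, delta_I, 0)
    return(p^2 + (1 - p)^2)
  }
  f <- function(x) {
    p <- choice_prob_right(params, delta_R, delta_I, x)
    stats::dlogis(x, 0, params$sigma_det) * (p^2 + (1 - p)^2)
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
}
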