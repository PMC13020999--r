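test_that("pair_log_likelihood scores observed choices under shared frozen noise", {
  rows <- make_fc(2, delta_R = 0, delta_I = 0L, chose_right = c(TRUE, FALSE),
                  pair_id = 1L)
  pars <- subject_params(sigma_ran = 3)
  expect_equal(pair_log_likelihood(pars, 0, rows), 2 * log(0.5))
  # one game, net drive equal to the logistic scale, chose right
  one <- make_fc(1, delta_R = 3, delta_I = 0L, chose_right = TRUE)
  expect_equal(pair_log_likelihood(subject_params(sigma_ran = 3), 0, one),
               log(1 / (1 + exp(-1))))
  # impossible observation under a hard threshold returns -Inf
  det <- subject_params(sigma_ran = 0)
  expect_equal(pair_log_likelihood(det, 0, make_fc(1, delta_R = -5,
                                                   chose_right = TRUE)),
               -Inf)
})

test_that("likelihood is symmetric under mirroring left and right", {
  pars <- subject_params(A = 2, b = 1.5, sigma_det = 2, sigma_ran = 4)
  mirrored <- subject_params(A = 2, b = -1.5, sigma_det = 2, sigma_ran = 4)
  rows <- make_fc(2, delta_R = c(4, 4), delta_I = c(1L, 1L),
                  chose_right = c(TRUE, FALSE), pair_id = 1L)
  flip <- rows
  flip$delta_R <- -rows$delta_R
  flip$delta_I <- -rows$delta_I
  flip$chose_right <- !rows$chose_right
  for (nd in c(-1.2, 0, 2.5)) {
    expect_equal(pair_log_likelihood(pars, nd, rows),
                 pair_log_likelihood(mirrored, -nd, flip))
  }
})

test_that("quadrature pair agreement matches direct simulation of the generative model", {
  set.seed(41)
  pars <- subject_params(A = 1, b = 0.5, sigma_det = 3, sigma_ran = 4)
  dR <- -4; dI <- 1
  n <- 2e5
  nd <- rlogis(n, 0, pars$sigma_det)
  drive <- dR + pars$A * dI + pars$b + nd
  c1 <- (drive + rlogis(n, 0, pars$sigma_ran)) > 0
  c2 <- (drive + rlogis(n, 0, pars$sigma_ran)) > 0
  sim <- mean(c1 == c2)
  q <- marginal_pair_agreement(pars, dR, dI)
  expect_lt(abs(sim - q), 3.5 * sqrt(q * (1 - q) / n))
})

test_that("variant flags are validated and change the posterior accordingly", {
  set.seed(42)
  cfg <- mini_cfg()
  fc <- first_free_choices(simulate_cohort(
    lapply(1:2, function(i) flat_params(sigma_det = 2, sigma_ran = 4)), cfg))
  expect_error(build_posterior(fc, variant = "bogus"), "unknown variant")
  expect_error(build_posterior(fc, variant = c("no_det", "det_fixed_across_horizon")),
               "contradictory")
  expect_error(build_posterior(fc, variant = c("no_ran", "ran_fixed_across_horizon")),
               "contradictory")
  full <- build_posterior(fc)
  expect_identical(build_posterior(fc, variant = character())$code, full$code)
  expect_false(grepl("ndet", build_posterior(fc, variant = "no_det")$code))
  expect_false(grepl("sran", build_posterior(fc, variant = "no_ran")$code))
  byinfo <- build_posterior(fc, variant = "sigma_by_info")
  expect_equal(byinfo$data$NC, 2L)
  expect_equal(full$data$NC, 1L)
  shared <- build_posterior(fc, variant = "det_fixed_across_horizon")
  expect_equal(shared$data$hmap_det, c(1L, 1L))
  expect_error(build_posterior(fc, variant = "variance_dI"), "delta_V")
})

test_that("variance-based information difference is zero for equal spread", {
  tr <- make_game_trials(forced_rewards = c(48, 52, 38, 42))
  fc <- add_variance_information(first_free_choices(tr), tr)
  expect_equal(fc$delta_V, 0)
  tr2 <- make_game_trials(forced_rewards = c(50, 50, 30, 50))
  fc2 <- add_variance_information(first_free_choices(tr2), tr2)
  expect_equal(fc2$delta_V, 100) # var right {30,50} minus var left {50,50}
})

test_that("subjects missing a horizon are dropped with a warning", {
  set.seed(43)
  cfg <- mini_cfg()
  fc <- first_free_choices(simulate_cohort(
    lapply(1:2, function(i) flat_params(sigma_ran = 4)), cfg))
  fc_broken <- fc[!(fc$subject_id == "s002" & fc$horizon == 6), ]
  expect_warning(m <- build_posterior(fc_broken), "missing a horizon")
  expect_equal(m$data$NS, 1L)
})

test_that("with no data the sampler reproduces the prior", {
  set.seed(44)
  cfg <- mini_cfg()
  fc <- first_free_choices(simulate_cohort(list(flat_params(sigma_ran = 4)),
                                           cfg))
  fh <- list(mu_A = 1.5, sd_A = 2, mu_b = 0, sd_b = 1,
             k_det = 3, lam_det = 1.5, k_ran = 2, lam_ran = 0.5)
  m <- build_posterior(fc, fixed_hypers = fh, prior_only = TRUE)
  fit <- run_mcmc(m, chains = 2, n_samples = 3000, n_burnin = 200,
                  n_adapt = 200, seed = 7)
  draws <- as.matrix(fit$draws)
  probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  qs <- quantile(draws[, "sdet[1,1,1]"], probs)
  expect_equal(unname(qs), qgamma(probs, 3, 1.5), tolerance = 0.06)
  qs_a <- quantile(draws[, "A[1,1]"], probs)
  expect_equal(unname(qs_a), qnorm(probs, 1.5, 2), tolerance = 0.12)
  qs_r <- quantile(draws[, "sran[1,2,1]"], probs)
  expect_equal(unname(qs_r), qgamma(probs, 2, 0.5), tolerance = 0.12)
})

test_that("chains with identical seeds reproduce identical draws", {
  set.seed(45)
  cfg <- mini_cfg()
  fc <- first_free_choices(simulate_cohort(
    lapply(1:2, function(i) flat_params(sigma_det = 1, sigma_ran = 4)), cfg))
  f1 <- fit_noise_model(fc, chains = 2, n_samples = 100, n_burnin = 100,
                        n_adapt = 150, seed = 11)
  f2 <- fit_noise_model(fc, chains = 2, n_samples = 100, n_burnin = 100,
                        n_adapt = 150, seed = 11)
  expect_identical(as.matrix(f1$draws), as.matrix(f2$draws))
})

test_that("split-Rhat separates mixed from non-mixed chains", {
  set.seed(46)
  iid <- coda::mcmc.list(lapply(1:4, function(i) coda::mcmc(
    matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "mu_x")))))
  cc <- convergence_check(iid)
  expect_lt(cc$table$rhat[1], 1.05)
  apart <- coda::mcmc.list(
    coda::mcmc(matrix(rnorm(1000, -10), ncol = 1, dimnames = list(NULL, "mu_x"))),
    coda::mcmc(matrix(rnorm(1000, 10), ncol = 1, dimnames = list(NULL, "mu_x"))))
  cc2 <- convergence_check(apart)
  expect_gt(cc2$table$rhat[1], 5)
  expect_false(cc2$pass)
  single <- coda::mcmc.list(coda::mcmc(matrix(rnorm(500), ncol = 1,
                                              dimnames = list(NULL, "x"))))
  expect_true(convergence_check(single)$limited)
})

test_that("split_rhat matches an independent textbook implementation", {
  set.seed(47)
  x <- matrix(rnorm(4000), ncol = 4)
  # independent re-implementation: split chains, W and B from first principles
  halves <- cbind(x[1:500, ], x[501:1000, ])
  m <- ncol(halves); n <- nrow(halves)
  W <- mean(apply(halves, 2, var))
  B <- n / (m - 1) * sum((colMeans(halves) - mean(halves))^2)
  ref <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(split_rhat(x), ref, tolerance = 1e-8)
})

test_that("derived summaries recompute exactly from the group draws", {
  set.seed(48)
  cfg <- mini_cfg()
  fc <- first_free_choices(simulate_cohort(
    lapply(1:3, function(i) flat_params(sigma_det = 2, sigma_ran = 4)), cfg))
  fit <- fit_noise_model(fc, chains = 2, n_samples = 200, n_burnin = 200,
                         n_adapt = 150, seed = 13)
  d <- derived_summaries(fit)
  expect_true(all(d$draws$det_fraction >= 0 & d$draws$det_fraction <= 1))
  g <- group_posterior_draws(fit)
  g1 <- g[g$horizon == 1, ]; g6 <- g[g$horizon == 6, ]
  sd_pool <- (g1$k_det / g1$lam_det + g6$k_det / g6$lam_det) / 2
  sr_pool <- (g1$k_ran / g1$lam_ran + g6$k_ran / g6$lam_ran) / 2
  expect_equal(d$draws$det_fraction, sd_pool^2 / (sd_pool^2 + sr_pool^2))
  expect_equal(d$draws$ratio_ran,
               (g6$k_ran / g6$lam_ran) / (g1$k_ran / g1$lam_ran))
  # inflating the deterministic spread strictly raises every fraction draw
  inflated <- (1.5 * sd_pool)^2 / ((1.5 * sd_pool)^2 + sr_pool^2)
  expect_true(all(inflated > d$draws$det_fraction))
})
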