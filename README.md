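# horizonnoise

Is "random exploration" actually random? When people solve explore-exploit
problems, their choices are variable, and that variability grows when
exploration is worth more. Fitted choice models call the unexplained part
"decision noise" — but a model that is missing a deterministic reaction to
the stimulus will misread that reaction as noise. **horizonnoise**
implements the analysis built around a task that can tell the two apart:
a repeated-games version of the Horizon Task, in which participants
unknowingly face the exact same set of forced-choice trials twice. A
deterministic function of the stimulus must answer the same way both
times; only noise that is re-drawn on each play can produce inconsistent
choices across the repeats.

The package provides, on synthetic data (the study's raw behavioral data
are not deposited):

* a **task generator** for sessions of two-armed bandit games — Gaussian
  payoffs (SD 8, anchor means 40/60, mean differences 4/8/12/20, rewards
  1–100), four forced trials setting [1 3] or [2 2] information
  conditions, horizons 1 and 6, and exact duplication of forced trials in
  repeated game pairs separated in presentation order;
* a **generative two-noise choice agent**: the first free choice follows
  `delta_Q = delta_R + A*delta_I + b + n_det + n_ran`, choosing right when
  `delta_Q > 0`, where `n_det` is logistic noise frozen within a repeated
  pair and `n_ran` is logistic noise drawn fresh every game;
* **model-free statistics**: p(low mean), p(high info), within-pair
  p(inconsistent), with the analytic pure-deterministic bound (0) and the
  pure-random bound `sum_s rho_s * 2 p_s (1 - p_s)` over stimulus strata,
  horizon contrasts (paired t-tests), and the performance-based exclusion
  rule (last-trial accuracy, binomial p < 0.001);
* a **hierarchical Bayesian model** (fit with JAGS via rjags) estimating
  `A`, `b`, `sigma_det`, `sigma_ran` per subject and horizon, with one
  latent frozen-noise value per game pair, Gamma priors on the spreads,
  and derived posteriors: the deterministic variance fraction
  `sigma_det^2/(sigma_det^2+sigma_ran^2)` and between-horizon noise
  ratios;
* the **validation machinery**: parameter recovery, hyperprior recovery,
  shuffled-truth controls, reduced-model detection, and posterior
  predictive checks.

See `vignettes/noise-decomposition.Rmd` for the model, its assumptions,
and every numerical design decision.

## Worked example

Simulate four subjects with more noise (of both kinds) in the long
horizon, compute the model-free statistics, and fit the hierarchical
model at small MCMC settings:

```r
library(horizonnoise)
set.seed(7)
cfg <- task_config()            # 156 games, 65 repeated pairs
pars <- lapply(1:4, function(s) list(
  h1 = subject_params(A = 1, b = 0, sigma_det = 1.5, sigma_ran = 4),
  h6 = subject_params(A = 3, b = 0, sigma_det = 3.0, sigma_ran = 8)))
trials <- simulate_cohort(pars, cfg)
fc <- first_free_choices(trials)

mf <- model_free_stats(fc)
aggregate(cbind(p_low_mean, p_high_info, p_inconsistent_22, pred_random_22)
          ~ horizon, mf, mean)
#>   horizon p_low_mean p_high_info p_inconsistent_22 pred_random_22
#> 1       1  0.1645284   0.5433718          0.203125      0.2436420
#> 2       6  0.2225307   0.5489329          0.328125      0.3329843

fit <- fit_noise_model(fc, chains = 4, n_samples = 1000, n_burnin = 1000,
                       seed = 7)
derived_summaries(fit)$summary
#>          quantity  mean     q2.5  q97.5
#> 1    det_fraction 0.176  0.01730  0.603
#> 2 det_fraction_h1 0.265  0.00664  0.859
#> 3 det_fraction_h6 0.147  0.00483  0.626
#> 4       ratio_det 2.555  0.20594 11.434
#> 5       ratio_ran 2.575  0.74950  6.330
#> 6        diff_det 1.501 -8.44774 13.554
#> 7        diff_ran 8.301 -3.08910 21.970
#> 8  p_increase_det 0.639       NA     NA
#> 9  p_increase_ran 0.934       NA     NA
```

Reading the output: behavioral variability (`p_low_mean`) increases from
horizon 1 to horizon 6, and within-pair inconsistency
(`p_inconsistent_22`) sits between the pure-deterministic bound (0) and
the pure-random bound (`pred_random_22`) — the signature of a mixture of
frozen and per-play noise. The fitted `det_fraction` is the posterior
share of noise variance attributed to the stimulus-frozen component
(generating truth here: `1.5^2/(1.5^2+4^2) = 0.12` in horizon 1), and the
noise ratios between horizons are recovered around their generating
values (2 for both components), with wide intervals at this tiny cohort
size of four subjects.

An end-to-end run (simulate, exclusions, model-free, fit, posterior
predictive check, manifest) is one call:

```r
res <- run_pipeline(run_config(n_subjects = 8, out_dir = "out", seed = 1))
```

or from a shell via the thin wrapper `inst/cli/horizonnoise.R`
(subcommands `simulate`, `analyze`, `fit`, `pipeline`).

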