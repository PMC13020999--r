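---
title: "Separating random from deterministic decision noise in the repeated-games Horizon Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating random from deterministic decision noise in the repeated-games Horizon Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In explore-exploit tasks, people choose the lower-valued option some
fraction of the time, and that fraction grows when exploration is more
valuable. This behavioral variability is usually modelled as "decision
noise". But decision noise, as fitted, is simply the part of behavior the
model cannot explain — it confounds genuinely stochastic processes with
deterministic reactions to features of the stimulus that the model omits.

The repeated-games Horizon Task breaks this confound. Participants play
two-armed bandit games: four forced-choice trials fix what they know about
each option, then they make 1 (horizon 1) or 6 (horizon 6) free choices.
Critically, most games are presented **twice**, far apart in the session,
with identical forced-trial sides and identical forced outcomes. Any
deterministic function of the stimulus must produce the same first free
choice both times; only noise that is re-drawn on every play can make the
two choices differ. Choice consistency across repeats therefore separates
**deterministic noise** (`n_det`, frozen within a repeated pair) from
**random noise** (`n_ran`, independent every game).

## The choice model

The first free choice is modelled through the utility difference between
the right and left options,

    delta_Q = delta_R + A * delta_I + b + n_det + n_ran,

with `delta_R` the difference in forced-trial mean rewards (right minus
left), `delta_I` the information difference (+1 if the right option was
forced once and the left three times, -1 for the reverse, 0 in the equal
[2 2] condition), `A` the information bonus, `b` a rightward spatial bias.
The agent chooses right when `delta_Q > 0`. Both noise terms are logistic
with mean zero and spreads `sigma_det` and `sigma_ran`; marginalising
`n_ran` gives the logistic choice rule

    P(right | n_det) = 1 / (1 + exp(-(delta_R + A*delta_I + b + n_det) / sigma_ran)).

Two analytic bounds anchor the consistency analysis. If noise is purely
deterministic, p(inconsistent) = 0 exactly. If noise is purely random, the
two first choices of a pair are independent given the stimulus, so
p(inconsistent | stimulus) = 2p(1-p) with p = p(low mean | stimulus), and
the observable rate is the mixture of `2p(1-p)` over the stimulus
distribution. Both bounds, and the position of real (or simulated)
behavior between them, are computed by `model_free_stats()`.

### Scale versus standard deviation

The noise spreads are treated throughout as logistic **scale** parameters,
the convention of the Horizon Task model family, in which the choice rule
is `1/(1 + exp(-x/sigma))`. For a logistic distribution the standard
deviation is `scale * pi / sqrt(3)`, about 1.81 times the scale.
`subject_params(..., sigma_is_sd = TRUE)` accepts true standard deviations
and converts. The distinction is a pure reparameterisation: it rescales
fitted values but changes no probability.

### Reward-scaling equivalence

Because only the sign of `delta_Q` matters, multiplying `delta_R` by a
factor `beta` while dividing `A`, `b`, `sigma_det` and `sigma_ran` by
`beta` leaves behavior exactly unchanged
(`reward_scaling_transform()`; verified to 1e-10 in the test suite). This
is why the empirical finding that both noise spreads change with horizon
by a similar *ratio* is interpretable as a change in the gain of reward
processing rather than in the noise itself.

## The synthetic task generator

No raw behavioral data accompany the study, so the package simulates the
task from its printed design:

* Gaussian payoffs with SD 8 points; one bandit mean equals an anchor (40
  or 60), the other differs by 4, 8, 12 or 20 points; rewards are rounded
  to integers and clamped to [1, 100]. Rounding-and-clamping is the
  simplest rule consistent with "integer rewards between 1 and 100"; at
  these means and SD the clamp is almost never active.
* Sessions default to 156 games of which 65 are repeated pairs, matching
  the reported averages (153.7 games, 65.3 pairs). Unpaired games fill the
  session and are retained in fitting with their own latent noise draw.
* Pairs are scheduled with at least 10 intervening games (configurable),
  operationalising "separated by several minutes"; at roughly 9 s per game
  this is several minutes. Scheduling uses stochastic repair of a random
  permutation and fails loudly when the constraint is infeasible.
* Games are allocated to the horizon x information x mean-difference cells
  as evenly as divisibility allows, mirroring the counterbalanced design.

The generative agent (`play_session()`) draws one `n_det` per pair — at
the first encounter of the pair, so presentation order cannot affect the
draw — and fresh `n_ran` per game. Trials 6–10 of horizon-6 games are not
part of the analysed model; the agent plays them with a declared
placeholder policy (greedy on running sample means, with the same logistic
random noise) and flags them `analysis = 0`. They exist only so that the
performance-based exclusion rule (last-trial accuracy, one-sided binomial
p < 0.001 against chance) has data to work with. A utility tie, possible
only when `sigma_ran = 0`, is resolved by a fair coin.

What the generator does **not** emulate: learning or value updating across
free choices, response times, payoff-dependent session length, and any
sequential dependence between games. Passing tests therefore show that the
inference machinery is correct for data generated by the model itself —
they cannot show that real behavior follows the model.

## Model-free statistics

`p(low mean)` (equal condition) and `p(high info)` (unequal condition)
quantify random and directed exploration on first free choices;
`p(inconsistent)` is the fraction of complete repeated pairs whose two
first choices differ. The pure-random prediction conditions on the
stimulus by stratifying `|delta_R|` into quantile bins (quartiles by
default) within each information condition, pooling signs because "low
mean" is sign-agnostic. The stratum weights are the observed stratum
frequencies among pairs.

Stratum probabilities are estimated from all subjects **pooled** by
default. The reason is statistical: the plug-in estimator `2p_hat(1 -
p_hat)` is biased downward by `2 Var(p_hat)`, which with the roughly ten
first choices a single subject contributes per stratum amounts to a few
percentage points — enough that, in the package's own negative control
(a cohort simulated with purely random noise), per-subject predictions
sit detectably below the observed inconsistency, while pooled predictions
are statistically indistinguishable from it in every horizon x information
cell, as the prediction should be. `model_free_stats(pooled = FALSE)`
restores per-subject estimation (useful for per-subject error bars, with
the documented bias). Games
with tied forced-trial means carry no "low mean" event and are excluded
from both the statistic and the prediction; with no eligible data the
statistics return `NA` rather than zero. Horizon contrasts are two-sided
paired t-tests.

## The hierarchical Bayesian model

Per subject `s` and horizon `i` (fit separately per horizon):

* `A[s,i] ~ Gaussian(mu_A[i], sd_A[i])`, `b[s,i] ~ Gaussian(mu_b[i], sd_b[i])`
* `sigma_det[s,i] ~ Gamma(k_det[i], lambda_det[i])`,
  `sigma_ran[s,i] ~ Gamma(k_ran[i], lambda_ran[i])` — shape/**rate**
  parameterisation, so the prior mean is `k / lambda`
* hyperpriors: `mu ~ Gaussian(0, 100)`, `sd ~ Exponential(0.01)`,
  `k ~ Exponential(0.01)`, `lambda ~ Exponential(10)`
* one latent `n_det ~ Logistic(0, sigma_det[s,i])` per repeated pair (and
  per unpaired game), shared by both pair members
* each observed first choice is Bernoulli with the logistic rule above.

Two documented ambiguities are resolved by configuration rather than
silently: (a) the narrower hyperprior set `mu ~ Gaussian(0, 10)`,
`sd ~ Exponential(0.1)` that circulates for this model family is available
via `hyperprior_config(mu_sd = 10, sd_rate = 0.1)`; the broad set is the
default. (b) The Gaussian second parameter is read as a standard
deviation; `gaussian_param = "precision"` reinterprets it for
cross-checking against precision-convention samplers.

The latent `n_det` values are sampled explicitly as graphical-model nodes
(mirroring the JAGS formulation the model family uses) rather than being
marginalised; `marginal_choice_prob()` and `marginal_pair_agreement()`
provide quadrature marginalisation as an independent cross-check, and the
test suite verifies the two routes agree.

Sampling is delegated to JAGS through rjags. Defaults mirror the reference
procedure — 10 chains, 5000 retained draws each after a 5000-draw burn-in,
thin 1 — and every validation experiment states its reduced settings
explicitly. Per-chain seeds derive deterministically from one master seed,
so identical calls give identical draws. Convergence "by eye" is
operationalised as split-R-hat < 1.1 on every monitored parameter plus
effective sample size > 400 on the group-level parameters
(`convergence_check()`).

### Derived quantities

Per posterior draw, the group-level mean spreads `k/lambda` give the
deterministic fraction `sigma_det^2 / (sigma_det^2 + sigma_ran^2)` and the
between-horizon ratios and tail probabilities. Which level (group mean vs
subject means) and which horizon pooling the published headline fraction
used is not stated; this package computes the fraction per horizon and on
the across-horizon average of group means, and reports the pooled version
as the headline, with per-horizon values alongside.

### Model variants

`build_posterior()` accepts flags: `sigma_by_info` (noise spreads per
information condition), `variance_dI` (information difference as the
difference of forced-reward sample variances, population formula so a
single forced play has variance 0), `no_det` / `no_ran` (reduced models;
`no_ran` replaces the logistic likelihood with a step function guarded by
a 1e-6 floor so that the sampler never sees an exactly-zero likelihood),
and `det_fixed_across_horizon` / `ran_fixed_across_horizon` (spread shared
across horizons). Contradictory combinations raise configuration errors.

## Validation machinery and problem sizes

The package ships the full validation suite as functions —
`parameter_recovery()`, `hyperprior_recovery()`, `shuffled_control()`,
`reduced_model_detection()`, `posterior_predictive_check()` — and runs
them in two tiers:

* `scripts/acceptance.R` runs the full-size recovery: 65 subjects, noise
  truths drawn uniformly from the integer grid 0–10 points (the published
  recovery grid spans 0–10), information bonus and bias drawn from
  Gaussian group distributions with moderate means (1 and 3 points for
  `A` in horizons 1 and 6, 0 for `b`, SD 1 — the magnitude of typical
  fits), one default 156-game session per subject, refit with 4 chains x
  1000 retained after 1000 burn-in. This takes a few minutes.
* The test suite runs the recovery-asymmetry check at the same full
  65-subject size (the asymmetry between the two noise types is a
  between-recovery contrast of about 0.1 in slope and correlation, which
  smaller cohorts cannot resolve reliably), and the remaining experiments
  at reduced sizes chosen so the whole suite runs comfortably on one CPU:
  14–16 subjects for zero-noise, shuffled-control and detection
  experiments, 3–4 chains of 500–600 retained draws. The qualitative
  conclusions (near-zero recovery of absent components, vanishing
  cross-correlations, diagonal detection) are stable at these sizes; the
  exact correlation and slope values move with cohort size and truth
  distribution.

Two validation behaviors deserve comment. First, recovery is genuinely
asymmetric: random noise is re-drawn on every game while deterministic
noise contributes one latent value per pair, so the data carry half as
much information about `sigma_det`, and its posterior means are shrunk
harder — lower recovery correlations and a through-origin slope below 1.
Second, the *size* of that slope depends on the distribution of the truth
values. Under this package's declared grid design the underestimation of
`sigma_det` is milder (slope around 0.9) than the published 32% (slope
0.68), whose generating design is not stated; the directional asymmetry
replicates, the magnitude is design-dependent. The acceptance script
reports the measured values without adjustment.

Detection thresholds are conventional posterior tail criteria declared in
advance: `P(increase with horizon) > 0.95` flags a horizon change,
`P(spread > 0.5 points) > 0.95` flags presence.

Posterior predictive checks replay each subject's own game sequence with
that subject's posterior-mean parameters (point summaries, not full
draws — a deliberate simplification that reproduces the qualitative
horizon patterns; using full posterior draws would widen the bands), and
overlay observed statistics on the simulated distribution together with
the two analytic bounds.

## Numerical choices and degenerate inputs

* `sigma_ran = 0` makes the choice rule a hard threshold; probabilities
  are 0, 1/2 or 1, likelihood contributions of impossible observations are
  `-Inf`, and agent ties are fair coins.
* Statistics over empty cells return `NA` ("undefined"), never 0.
* The pair-separation scheduler errors after a bounded number of repair
  iterations rather than looping forever.
* MCMC initialisation retries with jittered starting points a bounded
  number of times before failing.
* Quantile binning of `|delta_R|` collapses duplicate break points; a
  single distinct value forms one stratum.

## Known limitations

* Deterministic noise is defined within a game; deterministic strategies
  spanning games (memory of earlier games) are absorbed into "random"
  noise, which is therefore an upper bound by construction.
* The placeholder policy for late free choices is not a model of behavior;
  only the first free choice is analysed.
* Session length is fixed by configuration; the original task's
  performance-dependent length is not emulated.
* With `no_ran`, the 1e-6 likelihood floor slightly smooths the step
  likelihood; this matters only for data that are impossible under a pure
  threshold.
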