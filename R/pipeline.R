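#' Run configuration for the end-to-end pipeline
#'
#' Bundles everything [run_pipeline()] needs: the task configuration, the
#' generative group-level parameters of the simulated cohort, MCMC
#' settings, analysis options and the output directory. A single master
#' seed drives every stage; each stage derives its own child seed as
#' `seed + 100 * stage_index`, so stages are reproducible in isolation.
#'
#' @param task A [task_config()].
#' @param n_subjects Simulated cohort size.
#' @param gen_hypers Group-level generative parameters: data.frame with one
#'   row per horizon, columns `horizon`, `mu_A`, `sd_A`, `mu_b`, `sd_b`,
#'   `k_det`, `lam_det`, `k_ran`, `lam_ran`.
#' @param mcmc List with `chains`, `n_samples`, `n_burnin`, `thin`,
#'   `n_adapt`.
#' @param variant Model variant flags (see [build_posterior()]).
#' @param exclusions Apply the performance-based exclusion rule.
#' @param pooled_strata Pool subjects when estimating pure-random strata.
#' @param n_bins `|delta_R|` bins for the pure-random prediction.
#' @param ppc_reps Posterior-predictive replicates.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(task = task_config(),
                       n_subjects = 8L,
                       gen_hypers = default_gen_hypers(),
                       mcmc = list(chains = 4L, n_samples = 1000L,
                                   n_burnin = 1000L, thin = 1L,
                                   n_adapt = 500L),
                       variant = character(),
                       exclusions = TRUE,
                       pooled_strata = TRUE,
                       n_bins = 4L,
                       ppc_reps = 20L,
                       out_dir = "horizonnoise-out",
                       seed = 1L) {
  stopifnot(mcmc$thin >= 1L, mcmc$chains >= 1L)
  structure(list(task = task, n_subjects = as.integer(n_subjects),
                 gen_hypers = gen_hypers, mcmc = mcmc,
                 variant = check_variant(variant),
                 exclusions = exclusions, pooled_strata = pooled_strata,
                 n_bins = n_bins, ppc_reps = ppc_reps,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Default generative group-level parameters for simulated cohorts
#'
#' Moderate group-level values in the empirical range of Horizon Task
#' fits: a small information bonus and noise in the short horizon, larger
#' in the long horizon, with random noise roughly twice the deterministic
#' noise.
#'
#' @return A data.frame usable as `gen_hypers` in [run_config()].
#' @export
default_gen_hypers <- function() {
  data.frame(horizon = c(1L, 6L),
             mu_A = c(1, 3), sd_A = c(1, 1),
             mu_b = c(0, 0), sd_b = c(1, 1),
             k_det = c(4, 4), lam_det = c(2.5, 1),
             k_ran = c(4, 4), lam_ran = c(1, 0.4),
             stringsAsFactors = FALSE)
}

#' Run the full simulate-analyse-fit-check pipeline
#'
#' Executes the stages in order -- simulate a cohort, apply the exclusion
#' rule, compute model-free statistics, fit the hierarchical model, derive
#' posterior summaries, run the posterior predictive check -- writing each
#' stage's outputs as CSV into `cfg$out_dir` together with a JSON manifest
#' recording seeds, settings and the MD5 hash of every artifact. Given the
#' same configuration and seed the outputs are byte-identical.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- character()
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    artifacts[[length(artifacts) + 1L]] <<- path
    path
  }

  # stage 1: simulate
  set.seed(cfg$seed + 100L)
  say("simulate: %d subjects x %d games", cfg$n_subjects, cfg$task$n_games)
  truth <- do.call(rbind, lapply(seq_len(nrow(cfg$gen_hypers)), function(i) {
    h <- cfg$gen_hypers[i, ]
    data.frame(subject_id = sprintf("s%03d", seq_len(cfg$n_subjects)),
               horizon = h$horizon,
               A = stats::rnorm(cfg$n_subjects, h$mu_A, h$sd_A),
               b = stats::rnorm(cfg$n_subjects, h$mu_b, h$sd_b),
               sigma_det = stats::rgamma(cfg$n_subjects, h$k_det, h$lam_det),
               sigma_ran = stats::rgamma(cfg$n_subjects, h$k_ran, h$lam_ran),
               stringsAsFactors = FALSE)
  }))
  subjects <- sprintf("s%03d", seq_len(cfg$n_subjects))
  games_by_subject <- stats::setNames(
    lapply(subjects, function(s) generate_session(cfg$task)), subjects)
  par_list <- params_from_truth(truth)
  trials <- do.call(rbind, lapply(subjects, function(s) {
    play_session(games_by_subject[[s]], par_list[[s]], cfg$task,
                 subject_id = s)
  }))
  class(trials) <- c("horizon_trials", "data.frame")
  emit(within(trials, is_forced <- as.integer(is_forced)), "trials.csv")
  emit(truth, "generating_parameters.csv")

  # stage 2: exclusions
  set.seed(cfg$seed + 200L)
  excl <- exclude_subjects(trials, games = games_by_subject)
  emit(excl$summary, "exclusions.csv")
  kept <- if (cfg$exclusions) excl$kept else subjects
  say("exclusions: kept %d of %d subjects", length(kept), length(subjects))
  if (length(kept) < 2L) stop("pipeline: fewer than 2 subjects kept",
                              call. = FALSE)
  trials_kept <- trials[trials$subject_id %in% kept, , drop = FALSE]
  class(trials_kept) <- c("horizon_trials", "data.frame")

  # stage 3: model-free statistics
  set.seed(cfg$seed + 300L)
  fc <- first_free_choices(trials_kept)
  mf <- model_free_stats(fc, n_bins = cfg$n_bins, pooled = cfg$pooled_strata)
  emit(mf, "model_free_subject.csv")
  contrasts <- do.call(rbind, lapply(
    c("p_low_mean", "p_high_info", "p_inconsistent_13", "p_inconsistent_22"),
    function(st) {
      hc <- horizon_contrast(mf, st)
      data.frame(statistic = st, t = hc$t, df = hc$df, p_value = hc$p_value,
                 mean_diff = hc$mean_diff, stringsAsFactors = FALSE)
    }))
  emit(contrasts, "model_free_contrasts.csv")

  # stage 4: hierarchical fit
  say("fit: %d chains x %d samples (+%d burn-in)", cfg$mcmc$chains,
      cfg$mcmc$n_samples, cfg$mcmc$n_burnin)
  fit <- fit_noise_model(fc, variant = cfg$variant,
                         chains = cfg$mcmc$chains,
                         n_samples = cfg$mcmc$n_samples,
                         n_burnin = cfg$mcmc$n_burnin,
                         thin = cfg$mcmc$thin, n_adapt = cfg$mcmc$n_adapt,
                         seed = cfg$seed + 400L)
  emit(subject_posterior(fit), "subject_posterior.csv")
  emit(group_posterior_draws(fit), "group_posterior_draws.csv")
  conv <- convergence_check(fit)
  emit(conv$table, "convergence.csv")
  writeLines(sprintf("converged: %s (max split-Rhat %.3f, min group ESS %.0f)",
                     conv$pass, max(conv$table$rhat, na.rm = TRUE),
                     min(conv$table$ess[conv$table$group_level])),
             file.path(cfg$out_dir, "convergence.txt"))
  artifacts[[length(artifacts) + 1L]] <- file.path(cfg$out_dir, "convergence.txt")

  # stage 5: derived summaries
  derived <- if (length(intersect(c("no_det", "no_ran"), cfg$variant))) NULL
             else derived_summaries(fit)
  if (!is.null(derived)) emit(derived$summary, "derived_posterior.csv")

  # stage 6: posterior predictive check
  set.seed(cfg$seed + 600L)
  ppc <- posterior_predictive_check(fit, games_by_subject[kept], cfg$task,
                                    fc, n_rep = cfg$ppc_reps,
                                    seed = cfg$seed + 600L)
  emit(ppc, "ppc.csv")

  manifest <- list(
    package = "horizonnoise",
    version = as.character(utils::packageVersion("horizonnoise")),
    seed = cfg$seed,
    seed_scheme = "stage k uses master seed + 100 * k",
    n_subjects = cfg$n_subjects, n_kept = length(kept),
    task = cfg$task[setdiff(names(cfg$task), "seed")],
    mcmc = cfg$mcmc, variant = cfg$variant,
    artifacts = lapply(unlist(artifacts), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: %d artifacts in %s", length(artifacts) + 1L, cfg$out_dir)
  invisible(list(trials = trials, exclusions = excl, first_choices = fc,
                 model_free = mf, contrasts = contrasts, fit = fit,
                 convergence = conv, derived = derived, ppc = ppc,
                 manifest = manifest))
}
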