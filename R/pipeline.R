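#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis into one
#' validated object. All randomness flows from the single `seed`: each stage
#' draws from a fixed offset of it, so a configuration determines every
#' output exactly. Unknown arguments are rejected.
#'
#' @param seed Root seed.
#' @param stages Character vector of stages to run, in dependency order
#'   (subsets must respect dependencies: everything downstream of `simulate`
#'   needs `hmm`; `rsa`/`subspace` need `pseudopop`).
#' @param n_blocks,criterion Behavioral session size and block criterion.
#' @param agent,tuning Generator specifications.
#' @param n_restarts,max_iter,tol HMM fitting controls.
#' @param n_per_condition Pseudotrials per condition.
#' @param cv_folds Classifier cross-validation folds.
#' @param n_perm Permutation count for rate contrasts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "hmm", "belief", "metrics",
                                       "pseudopop", "rsa", "subspace"),
                            n_blocks = 12L, criterion = 15L,
                            agent = agent_spec(), tuning = tuning_spec(),
                            n_restarts = 20L, max_iter = 500L, tol = 1e-6,
                            n_per_condition = 20L, cv_folds = 10L,
                            n_perm = 1000L) {
  all_stages <- c("simulate", "hmm", "belief", "metrics", "pseudopop", "rsa",
                  "subspace")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  deps <- list(hmm = "simulate", belief = "hmm", metrics = "hmm",
               pseudopop = "hmm", rsa = "pseudopop", subspace = "pseudopop")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !need %in% stages) {
      stop("stage '", s, "' requires stage '", need, "'")
    }
  }
  structure(
    list(seed = as.integer(seed), stages = stages, n_blocks = n_blocks,
         criterion = criterion, agent = agent, tuning = tuning,
         n_restarts = n_restarts, max_iter = max_iter, tol = tol,
         n_per_condition = n_per_condition, cv_folds = cv_folds,
         n_perm = n_perm),
    class = "pipeline_config"
  )
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in dependency order — simulate behavior and
#' spikes, fit the rule HMM, profile residual choices against the
#' ideal-observer model, compute single-neuron metrics, build
#' pseudopopulations, run the representational similarity analysis, and fit
#' the choice-predictive subspace — writing every stage's tables (TSV) and a
#' summary JSON to `out_dir`. The resolved configuration is echoed to
#' `config.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- config
  cfg_json$agent <- unclass(cfg_json$agent)
  cfg_json$tuning <- unclass(cfg_json$tuning)
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res <- list()
  on <- function(s) s %in% config$stages
  seed <- config$seed

  if (on("simulate")) {
    res$trials <- simulate_behavior(
      agent = config$agent,
      schedule = block_schedule(config$criterion),
      n_blocks = config$n_blocks, seed = seed
    )
    res$spikes <- simulate_neurons(res$trials, config$tuning, seed = seed + 1L)
    write_trials(res$trials, file.path(out_dir, "trials.tsv"))
    write_spikes(res$spikes, file.path(out_dir, "spikes.tsv"))
  }

  if (on("hmm")) {
    res$fit <- fit_baum_welch(res$trials, n_restarts = config$n_restarts,
                              max_iter = config$max_iter, tol = config$tol,
                              seed = seed + 2L)
    res$states <- label_trials(res$trials, res$fit)
    readr::write_tsv(
      dplyr::select(res$states, "session_id", "trial_index", "hmm_state",
                    "rule_based", "state_posterior"),
      file.path(out_dir, "states.tsv"), progress = FALSE)
    jsonlite::write_json(
      list(a_rr = res$fit$hmm$a_rr, a_oo = res$fit$hmm$a_oo,
           log_likelihood = res$fit$log_likelihood,
           converged = res$fit$converged),
      file.path(out_dir, "hmm.json"), auto_unbox = TRUE, digits = NA)
  }

  if (on("belief")) {
    res$infogain <- choice_class_profile(res$trials, res$states$hmm_state,
                                         by_reward = TRUE)
    readr::write_tsv(res$infogain, file.path(out_dir, "infogain.tsv"),
                     progress = FALSE)
  }

  if (on("metrics")) {
    dir.create(file.path(out_dir, "metrics"), showWarnings = FALSE)
    st <- res$states$hmm_state
    res$anova <- tuning_anova_suite(res$spikes, res$trials, st)
    res$mi <- neuron_information(res$spikes, res$trials, st,
                                 seed = seed + 3L)
    res$ic <- identity_category_suite(res$spikes, res$trials, st)
    readr::write_tsv(res$anova$neurons,
                     file.path(out_dir, "metrics", "anova.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$mi, file.path(out_dir, "metrics", "mi.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$ic$neurons,
                     file.path(out_dir, "metrics", "icindex.tsv"),
                     progress = FALSE)
    if (all(paste0("epoch", 1:3, "_count") %in% names(res$spikes))) {
      res$tuning_glm <- relevance_tuning_glm(res$spikes, res$trials, st,
                                             target = "choice")
      readr::write_tsv(res$tuning_glm$model,
                       file.path(out_dir, "metrics", "tuningglm.tsv"),
                       progress = FALSE)
    }
    jsonlite::write_json(res$anova$summary,
                         file.path(out_dir, "metrics", "summary.json"),
                         digits = NA)
  }

  if (on("pseudopop")) {
    res$pseudo <- purrr::map(
      setNames(c("rule_vs_residual", "color_vs_shape_rule", "per_rule"),
               c("rule_vs_residual", "color_vs_shape_rule", "per_rule")),
      function(sch) build_pseudotrials(
        res$spikes, res$trials, res$states$hmm_state, scheme = sch,
        n_per_condition = config$n_per_condition, seed = seed + 4L)
    )
    readr::write_tsv(res$pseudo$rule_vs_residual$roster,
                     file.path(out_dir, "roster.tsv"), progress = FALSE)
  }

  if (on("rsa")) {
    dir.create(file.path(out_dir, "rsa"), showWarnings = FALSE)
    res$rsa <- purrr::map(
      res$pseudo[c("rule_vs_residual", "color_vs_shape_rule")],
      function(pm) distance_matrix(condition_centroids(pm)))
    for (nm in names(res$rsa)) {
      readr::write_tsv(tidy(res$rsa[[nm]]),
                       file.path(out_dir, "rsa",
                                 paste0("distances_", nm, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(rsa_contrasts(res$rsa[[nm]]),
                       file.path(out_dir, "rsa",
                                 paste0("contrasts_", nm, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(rsa_anova(res$rsa[[nm]]),
                       file.path(out_dir, "rsa",
                                 paste0("anova_", nm, ".tsv")),
                       progress = FALSE)
    }
  }

  if (on("subspace")) {
    dir.create(file.path(out_dir, "subspace"), showWarnings = FALSE)
    pm <- res$pseudo$per_rule
    res$choice_dims <- fit_choice_classifiers(pm, cv_folds = config$cv_folds,
                                              seed = seed + 5L)
    res$rule_dims <- fit_rule_classifiers(pm, cv_folds = config$cv_folds,
                                          seed = seed + 6L)
    res$projections <- project_pseudotrials(pm, res$choice_dims)
    res$projection_tests <- projection_anova(res$projections)
    res$angles <- rule_choice_angles(res$choice_dims, res$rule_dims)
    readr::write_tsv(tidy(res$choice_dims),
                     file.path(out_dir, "subspace", "coefficients.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$projections,
                     file.path(out_dir, "subspace", "projections.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$projection_tests$anova,
                     file.path(out_dir, "subspace", "anova.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$angles,
                     file.path(out_dir, "subspace", "angles.tsv"),
                     progress = FALSE)
  }

  invisible(res)
}
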