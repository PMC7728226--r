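#' Construct the constrained 7-state rule HMM
#'
#' The latent-state model of rule-based choice: six rule states (one per
#' feature) plus a maximum-entropy residual state. Emissions are fixed:
#' a rule state emits only choices matching its feature (probability 1, since
#' exactly one presented option matches any feature), and the residual state
#' emits any of the N = 3 options with probability 1/3. Transitions are tied
#' and structurally constrained: direct transitions between different rule
#' states are fixed at 0, rule states exit only to the residual state, and
#' the residual state's exit mass is split uniformly across the six rules.
#' The chain starts in the residual state. The model therefore has exactly
#' two free parameters, `a_rr` and `a_oo`.
#'
#' @param a_rr Rule-state self-transition probability.
#' @param a_oo Residual-state self-transition probability.
#' @return An object of class `rule_hmm` with components `a_rr`, `a_oo`,
#'   `transition` (7 x 7 row-stochastic matrix, state order: residual then
#'   the six features in canonical order), `initial`, and `states`.
#' @examples
#' hmm <- build_hmm(0.95, 0.6)
#' rowSums(hmm$transition)
#' @export
build_hmm <- function(a_rr, a_oo) {
  if (!is.numeric(a_rr) || !is.numeric(a_oo) ||
      length(a_rr) != 1L || length(a_oo) != 1L ||
      is.na(a_rr) || is.na(a_oo) ||
      a_rr < 0 || a_rr > 1 || a_oo < 0 || a_oo > 1) {
    stop("a_rr and a_oo must be single probabilities in [0, 1]")
  }
  S <- length(.state_levels)
  P <- matrix(0, S, S, dimnames = list(.state_levels, .state_levels))
  P[1, 1] <- a_oo
  P[1, -1] <- (1 - a_oo) / 6
  for (i in 2:S) {
    P[i, i] <- a_rr
    P[i, 1] <- 1 - a_rr
  }
  structure(
    list(a_rr = a_rr, a_oo = a_oo, transition = P,
         initial = c(1, rep(0, 6)), states = .state_levels,
         n_free_parameters = 2L),
    class = "rule_hmm"
  )
}

#' Emission log-probability of a choice under a latent state
#'
#' @param chosen_color,chosen_shape Features of the chosen option.
#' @param state `"residual"` or a feature label.
#' @return Log probability; zero-probability emissions are returned as the
#'   log-space sentinel `-1e30` (never exponentiated by the recursions).
#' @export
emission_logprob <- function(chosen_color, chosen_shape, state) {
  if (!all(state %in% .state_levels)) {
    stop("state must be 'residual' or one of: ",
         paste(.features, collapse = ", "))
  }
  p <- ifelse(state == "residual", 1 / 3,
              as.numeric(chosen_color == state | chosen_shape == state))
  ifelse(p > 0, log(p), -1e30)
}

# T x 7 emission probability matrix for a trials table
.emission_matrix <- function(trials) {
  T_ <- nrow(trials)
  E <- matrix(0, T_, 7L, dimnames = list(NULL, .state_levels))
  E[, 1] <- 1 / 3
  for (s in 2:7) {
    f <- .state_levels[s]
    E[, s] <- as.numeric(trials$chosen_color == f | trials$chosen_shape == f)
  }
  E
}

#' Posterior state inference by forward-backward
#'
#' Runs the scaled forward-backward recursions, returning the observed-data
#' log likelihood and per-trial posterior state probabilities. Because the
#' residual state assigns probability 1/3 to every choice, every sequence has
#' positive probability and the log likelihood is always finite.
#'
#' @param trials A trials tibble (needs `chosen_color`, `chosen_shape`).
#' @param hmm A [build_hmm()] model.
#' @return An object of class `state_inference`: `log_likelihood`,
#'   `posteriors` (T x 7 matrix, rows sum to 1), `expected_transitions`
#'   (7 x 7 expected transition counts), `states`, `n_trials`.
#' @export
forward_backward <- function(trials, hmm) {
  stopifnot(inherits(hmm, "rule_hmm"))
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("trials must be a non-empty trials table")
  }
  E <- .emission_matrix(trials)
  fb <- forward_backward_cpp(E, hmm$transition, hmm$initial)
  colnames(fb$gamma) <- .state_levels
  dimnames(fb$xi_sum) <- list(.state_levels, .state_levels)
  structure(
    list(log_likelihood = fb$log_likelihood, posteriors = fb$gamma,
         expected_transitions = fb$xi_sum, states = .state_levels,
         n_trials = nrow(trials)),
    class = "state_inference"
  )
}

#' Viterbi decoding of the latent state path
#'
#' Returns the jointly most probable state sequence. Ties are broken
#' deterministically toward the lowest state index (residual first, then the
#' features in canonical order).
#'
#' @inheritParams forward_backward
#' @return Character vector of state labels, one per trial.
#' @export
viterbi <- function(trials, hmm) {
  stopifnot(inherits(hmm, "rule_hmm"))
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("trials must be a non-empty trials table")
  }
  E <- .emission_matrix(trials)
  logE <- ifelse(E > 0, log(E), -1e30)
  logP <- ifelse(hmm$transition > 0, log(hmm$transition), -1e30)
  logI <- ifelse(hmm$initial > 0, log(hmm$initial), -1e30)
  .state_levels[viterbi_cpp(logE, logP, logI)]
}

#' Fit the rule HMM by Baum-Welch with random restarts
#'
#' Expectation-maximization over the two free parameters. The M-step pools
#' expected transition counts across the six tied rule states; the structural
#' zeros and the fixed emission model are never updated, so they are
#' preserved exactly at every iteration. Each restart is initialized with
#' both parameters drawn uniformly on (0.5, 0.999); the restart with the
#' highest observed-data log likelihood wins.
#'
#' @param trials A non-empty trials tibble.
#' @param n_restarts Number of random restarts (the reference protocol uses
#'   100; the two-parameter likelihood surface is benign, so small counts
#'   behave identically in practice).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence threshold on the log-likelihood increment.
#' @param seed Optional seed for the restart initializations.
#' @return An object of class `rule_hmm_fit`: `hmm` (the best model),
#'   `inference` (the [forward_backward()] result under it), `viterbi_path`,
#'   `log_likelihood`, `restarts` (per-restart tibble), `ll_trace`
#'   (per-iteration log likelihoods of the best restart), `converged`.
#' @export
fit_baum_welch <- function(trials, n_restarts = 100L, max_iter = 500L,
                           tol = 1e-6, seed = NULL) {
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("trials must be a non-empty trials table")
  }
  if (!is.null(seed)) set.seed(seed)
  E <- .emission_matrix(trials)

  run_em <- function(a_rr, a_oo) {
    trace <- numeric(0)
    converged <- FALSE
    fb <- NULL
    for (iter in seq_len(max_iter)) {
      hmm <- build_hmm(a_rr, a_oo)
      fb <- forward_backward_cpp(E, hmm$transition, hmm$initial)
      trace <- c(trace, fb$log_likelihood)
      if (iter > 1 &&
          abs(trace[iter] - trace[iter - 1]) < tol) {
        converged <- TRUE
        break
      }
      xi <- fb$xi_sum
      gamma <- fb$gamma
      T_ <- nrow(E)
      # expected occupancy of each state over t = 1..T-1
      occ <- colSums(gamma[-T_, , drop = FALSE])
      rule_self <- sum(diag(xi)[-1])
      rule_occ <- sum(occ[-1])
      res_self <- xi[1, 1]
      res_occ <- occ[1]
      a_rr <- if (rule_occ > 0) rule_self / rule_occ else a_rr
      a_oo <- if (res_occ > 0) res_self / res_occ else a_oo
      a_rr <- min(max(a_rr, 0), 1)
      a_oo <- min(max(a_oo, 0), 1)
    }
    list(a_rr = a_rr, a_oo = a_oo, log_likelihood = trace[length(trace)],
         iterations = length(trace), converged = converged, trace = trace)
  }

  inits <- matrix(runif(2L * n_restarts, 0.5, 0.999), ncol = 2L)
  fits <- lapply(seq_len(n_restarts), function(r) {
    run_em(inits[r, 1], inits[r, 2])
  })
  restarts <- tibble::tibble(
    restart = seq_len(n_restarts),
    a_rr = vapply(fits, `[[`, numeric(1), "a_rr"),
    a_oo = vapply(fits, `[[`, numeric(1), "a_oo"),
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    iterations = vapply(fits, `[[`, integer(1), "iterations"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  if (!any(restarts$converged)) {
    warning("no Baum-Welch restart converged; returning the best iterate")
  }
  best <- which.max(restarts$log_likelihood)
  hmm <- build_hmm(fits[[best]]$a_rr, fits[[best]]$a_oo)
  structure(
    list(hmm = hmm,
         inference = forward_backward(trials, hmm),
         viterbi_path = viterbi(trials, hmm),
         log_likelihood = fits[[best]]$log_likelihood,
         restarts = restarts,
         best_restart = best,
         ll_trace = fits[[best]]$trace,
         converged = fits[[best]]$converged),
    class = "rule_hmm_fit"
  )
}

#' Attach inferred state labels to a trials table
#'
#' @param trials A trials tibble.
#' @param fit A [fit_baum_welch()] result (or a `rule_hmm` to decode with).
#' @return `trials` with columns `hmm_state` (Viterbi label), `rule_based`
#'   (logical), and `state_posterior` (posterior probability of the labeled
#'   state).
#' @export
label_trials <- function(trials, fit) {
  if (inherits(fit, "rule_hmm")) {
    path <- viterbi(trials, fit)
    gamma <- forward_backward(trials, fit)$posteriors
  } else {
    stopifnot(inherits(fit, "rule_hmm_fit"))
    path <- fit$viterbi_path
    gamma <- fit$inference$posteriors
  }
  trials$hmm_state <- path
  trials$rule_based <- path != "residual"
  trials$state_posterior <- gamma[cbind(seq_len(nrow(trials)),
                                        match(path, .state_levels))]
  trials
}

#' Block-based alternative trial labelings
#'
#' The two traditional rule-labeling schemes the latent-state model is
#' compared against: (A) rule-based iff the choice was correct; (B)
#' rule-based iff correct and past an initial burn-in period within the block.
#'
#' @param trials A trials tibble with `reward` and block structure
#'   (`block_index`; `block_trial` is derived if absent).
#' @param burn_in Within-block trial count treated as the learning period.
#' @return `trials` with logical columns `label_correct` and
#'   `label_burn_in`.
#' @export
alternative_labelings <- function(trials, burn_in = 5L) {
  if (!"block_trial" %in% names(trials)) {
    trials <- trials |>
      dplyr::group_by(.data$session_id, .data$block_index) |>
      dplyr::mutate(block_trial = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  trials$label_correct <- trials$reward == 1
  trials$label_burn_in <- trials$label_correct & trials$block_trial > burn_in
  trials
}

#' Compare trial labelings by Poisson GLM fits to spike counts
#'
#' For each labeling, each neuron's spike count is modeled as Poisson with a
#' log-linear dependence on the binary rule label (`exp(b0 + b1 * rule)`);
#' log likelihoods are summed within region and converted to AIC/BIC and the
#' corresponding model weights (`w_m` proportional to `exp(-delta_m / 2)`).
#'
#' @param spikes A spikes tibble.
#' @param labelings Named list of logical vectors, each of length equal to
#'   the session trial count, in `trial_index` order (e.g. HMM, correct,
#'   burn-in labels).
#' @return A tibble with one row per region and labeling: `n_neurons`, `k`
#'   (parameter count), `log_likelihood`, `aic`, `bic`, `aic_weight`,
#'   `bic_weight`.
#' @export
compare_labelings <- function(spikes, labelings) {
  stopifnot(is.list(labelings), !is.null(names(labelings)))
  trial_ids <- sort(unique(spikes$trial_index))
  n_trials <- length(trial_ids)
  bad <- vapply(labelings, function(l) length(l) != n_trials, logical(1))
  if (any(bad)) stop("labelings must have one entry per trial")

  per_neuron <- spikes |>
    dplyr::group_by(.data$region, .data$neuron_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$trial_index)
      y <- df$spike_count
      if (all(y == 0)) {
        message("excluding neuron with no spikes: ", key$neuron_id)
        return(tibble::tibble())
      }
      purrr::map_dfr(names(labelings), function(nm) {
        lab <- labelings[[nm]][match(df$trial_index, trial_ids)]
        fit <- glm(y ~ lab, family = poisson())
        tibble::tibble(labeling = nm, log_likelihood = as.numeric(logLik(fit)),
                       k = 2L, n = length(y))
      })
    }) |>
    dplyr::ungroup()

  per_neuron |>
    dplyr::group_by(.data$region, .data$labeling) |>
    dplyr::summarise(
      n_neurons = dplyr::n(),
      k = sum(.data$k),
      n_obs = sum(.data$n),
      log_likelihood = sum(.data$log_likelihood),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(
      aic = 2 * .data$k - 2 * .data$log_likelihood,
      bic = .data$k * log(.data$n_obs) - 2 * .data$log_likelihood,
      aic_weight = {
        d <- .data$aic - min(.data$aic)
        exp(-d / 2) / sum(exp(-d / 2))
      },
      bic_weight = {
        d <- .data$bic - min(.data$bic)
        exp(-d / 2) / sum(exp(-d / 2))
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_obs")
}

#' @importFrom stats logLik
NULL
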