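#' Uniform prior belief over the six features
#'
#' The ideal-observer model tracks a probability vector over the six features
#' ("which feature is currently correct?"), initialized uniform at 1/6.
#'
#' @return Named numeric vector of length 6 summing to 1.
#' @export
init_prior <- function() {
  setNames(rep(1 / 6, 6), .features)
}

#' One-step likelihood of a choice outcome over features
#'
#' After a choice, the likelihood that each feature is the correct one is
#' outcome-dependent: a rewarded choice puts mass 1/2 on each of its two
#' features and 0 elsewhere; an unrewarded choice puts 0 on its two features
#' and 1/(Nf - 2) = 1/4 on each of the other four.
#'
#' @param color,shape Features of the choice.
#' @param reward 0/1 outcome.
#' @return Named numeric vector over the six features.
#' @export
belief_likelihood <- function(color, shape, reward) {
  stopifnot(color %in% .colors, shape %in% .shapes, reward %in% c(0, 1))
  chosen <- .features %in% c(color, shape)
  if (reward == 1) {
    setNames(ifelse(chosen, 1 / 2, 0), .features)
  } else {
    setNames(ifelse(chosen, 0, 1 / 4), .features)
  }
}

# renormalize an unnormalized belief, replacing exact zeros with the
# magnitude of Gaussian noise (sd `noise_sd`) so entropies stay computable
.normalize_belief <- function(p, noise_sd) {
  if (noise_sd > 0) {
    z <- p == 0
    p[z] <- abs(rnorm(sum(z), 0, noise_sd))
  }
  s <- sum(p)
  if (s <= 0) stop("degenerate belief: all-zero unnormalized posterior")
  p / s
}

#' Bayesian belief update after a choice outcome
#'
#' Posterior proportional to prior times the outcome likelihood. Exact zeros
#' in the unnormalized posterior are replaced by `|N(0, noise_sd)|` draws
#' before renormalization, matching the reference procedure; set
#' `noise_sd = 0` for the noise-free update (entropies then use the
#' `0 log 0 = 0` convention).
#'
#' @param belief Named probability vector over the six features.
#' @param color,shape Features of the choice.
#' @param reward 0/1 outcome.
#' @param noise_sd SD of the zero-replacement noise (default `1e-4`).
#' @return Updated belief vector.
#' @export
update_belief <- function(belief, color, shape, reward, noise_sd = 1e-4) {
  stopifnot(length(belief) == 6, all(belief >= 0),
            abs(sum(belief) - 1) < 1e-8)
  .normalize_belief(belief * belief_likelihood(color, shape, reward), noise_sd)
}

#' Shannon entropy of a belief, in bits
#'
#' @param belief Probability vector; `0 log 0` is treated as 0.
#' @return Entropy in bits.
#' @export
belief_entropy <- function(belief) {
  p <- belief[belief > 0]
  -sum(p * log2(p))
}

#' Expected information gain and reward probability of a candidate choice
#'
#' For a candidate option, the reward probability is the total belief mass on
#' its two features. The expected posterior entropy averages the rewarded and
#' unrewarded posterior branches, weighted by the reward probability; the
#' expected information gain is the prior entropy minus that average.
#'
#' @param belief Prior belief vector.
#' @param color,shape Features of the candidate option.
#' @param noise_sd Zero-replacement noise for the branch posteriors
#'   (default 0: the `0 log 0 = 0` convention keeps everything finite).
#' @return A one-row tibble: `p_reward`, `prior_entropy`,
#'   `expected_posterior_entropy`, `infogain`.
#' @export
expected_info_gain <- function(belief, color, shape, noise_sd = 0) {
  stopifnot(length(belief) == 6, abs(sum(belief) - 1) < 1e-8)
  p_reward <- sum(belief[c(color, shape)])
  H_t <- belief_entropy(belief)
  H_rew <- if (p_reward > 0) {
    belief_entropy(update_belief(belief, color, shape, 1, noise_sd))
  } else 0
  H_unr <- if (p_reward < 1) {
    belief_entropy(update_belief(belief, color, shape, 0, noise_sd))
  } else 0
  H_hat <- p_reward * H_rew + (1 - p_reward) * H_unr
  tibble::tibble(
    p_reward = p_reward,
    prior_entropy = H_t,
    expected_posterior_entropy = H_hat,
    infogain = H_t - H_hat
  )
}

#' Reward-marginalized one-trial-history belief
#'
#' The typical belief going into a residual choice, when only the previous
#' choice is known but its outcome is uncertain: the two one-step likelihood
#' branches are averaged with weight `p_prev_reward` (the observed
#' probability that the preceding trial was rewarded, 0.52 in the reference
#' data), combined with the uniform prior, and renormalized.
#'
#' @param prev_color,prev_shape Features of the previous choice.
#' @param p_prev_reward Probability the previous trial was rewarded.
#' @param prior Prior belief before the previous outcome (default uniform).
#' @param noise_sd Zero-replacement noise (default 0).
#' @return Belief vector over the six features.
#' @export
residual_prior_mixture <- function(prev_color, prev_shape,
                                   p_prev_reward = 0.52,
                                   prior = init_prior(), noise_sd = 0) {
  stopifnot(p_prev_reward >= 0, p_prev_reward <= 1)
  lik <- p_prev_reward * belief_likelihood(prev_color, prev_shape, 1) +
    (1 - p_prev_reward) * belief_likelihood(prev_color, prev_shape, 0)
  .normalize_belief(prior * lik, noise_sd)
}

#' Observed versus model-optimal choice-relation profile of residual choices
#'
#' For every residual trial (after the first), classifies the choice by how
#' many feature dimensions it changed from the previous choice, and compares
#' the observed class frequencies with (a) the availability-weighted chance
#' rate of picking each class at random, and (b) the ideal-observer expected
#' information gain and reward probability of the options in each class,
#' computed from a one-trial-history belief conditioned on the actual
#' previous choice and outcome.
#'
#' @param trials A trials tibble.
#' @param state_labels Character vector of per-trial state labels (e.g. the
#'   Viterbi path); `"residual"` marks residual trials.
#' @param by_reward Split the profile by the previous trial's outcome.
#' @return A tibble with one row per relation class (and outcome group when
#'   `by_reward`): `n`, `freq` (observed choice frequency), `chance`
#'   (availability rate under random choice), `infogain`, `p_reward`
#'   (model expectations averaged over trials and qualifying options).
#' @export
choice_class_profile <- function(trials, state_labels, by_reward = FALSE) {
  stopifnot(length(state_labels) == nrow(trials))
  T_ <- nrow(trials)
  idx <- which(state_labels == "residual" & seq_len(T_) > 1L)
  if (!length(idx)) {
    message("no residual trials after the first; empty profile")
    return(tibble::tibble())
  }

  oc <- cbind(trials$opt1_color, trials$opt2_color, trials$opt3_color)
  os <- cbind(trials$opt1_shape, trials$opt2_shape, trials$opt3_shape)
  rows <- purrr::map_dfr(idx, function(t) {
    pc <- trials$chosen_color[t - 1L]
    ps <- trials$chosen_shape[t - 1L]
    pr <- trials$reward[t - 1L]
    classes <- choice_relation(pc, ps, oc[t, ], os[t, ])
    belief <- update_belief(init_prior(), pc, ps, pr, noise_sd = 0)
    opt <- purrr::map_dfr(1:3, function(j) {
      expected_info_gain(belief, oc[t, j], os[t, j])
    })
    tibble::tibble(
      trial_index = t,
      prev_reward = pr,
      option = 1:3,
      relation = classes,
      chosen = 1:3 == trials$choice_index[t],
      infogain = opt$infogain,
      p_reward = opt$p_reward
    )
  })

  groups <- if (by_reward) c("prev_reward", "relation") else "relation"
  profile <- rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n = sum(.data$chosen),
      n_available = dplyr::n(),
      infogain = mean(.data$infogain),
      p_reward = mean(.data$p_reward),
      .groups = "drop"
    )
  denom <- if (by_reward) {
    rows |>
      dplyr::group_by(.data$prev_reward) |>
      dplyr::summarise(n_trials = dplyr::n_distinct(.data$trial_index),
                       .groups = "drop")
  } else {
    tibble::tibble(n_trials = length(idx))
  }
  profile <- if (by_reward) {
    dplyr::left_join(profile, denom, by = "prev_reward")
  } else {
    dplyr::mutate(profile, n_trials = denom$n_trials)
  }
  profile |>
    dplyr::mutate(
      freq = .data$n / .data$n_trials,
      chance = .data$n_available / (3 * .data$n_trials)
    ) |>
    dplyr::select(dplyr::all_of(groups), "n", "freq", "chance",
                  "infogain", "p_reward")
}
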