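#' Behavioral agent specification
#'
#' Parameterizes the generative counterpart of the rule-state model: a hidden
#' chain over 6 rule states and one residual state, with tied self-transition
#' probabilities and rule-to-rule transitions forbidden. Rule states emit the
#' option matching the rule's feature (up to a lapse probability); residual
#' states emit choices according to a policy over choice-relation classes
#' (0, 1, or 2 feature dimensions changed from the previous choice),
#' conditioned on whether the previous trial was rewarded.
#'
#' The default residual policy concentrates on the novel option (class 2)
#' after reward omission, mirroring the observed 95% rate of that
#' information/reward-maximizing choice, and on single-dimension shifts
#' (class 1, the hypothesis-testing "keep one feature" move) after reward.
#'
#' @param a_rr Probability of remaining in a rule state on each trial.
#' @param a_oo Probability of remaining in the residual state.
#' @param residual_policy 2 x 3 matrix of class probabilities; rows
#'   `after_reward` and `after_omission`, columns classes 0:2; rows sum to 1.
#'   `NULL` selects uniformly among the three options instead (the
#'   max-entropy agent matched to the model's residual emission assumption,
#'   used for parameter-recovery checks).
#' @param lapse Probability that a rule-state trial violates the rule.
#' @return A list of class `agent_spec`.
#' @export
agent_spec <- function(a_rr = 0.95, a_oo = 0.6,
                       residual_policy = default_residual_policy(),
                       lapse = 0) {
  stopifnot(a_rr >= 0, a_rr <= 1, a_oo >= 0, a_oo <= 1,
            lapse >= 0, lapse <= 1)
  if (!is.null(residual_policy)) {
    stopifnot(
      is.matrix(residual_policy), nrow(residual_policy) == 2,
      ncol(residual_policy) == 3, all(residual_policy >= 0),
      all(abs(rowSums(residual_policy) - 1) < 1e-8)
    )
    rownames(residual_policy) <- c("after_reward", "after_omission")
    colnames(residual_policy) <- c("class0", "class1", "class2")
  }
  structure(
    list(a_rr = a_rr, a_oo = a_oo, residual_policy = residual_policy,
         lapse = lapse),
    class = "agent_spec"
  )
}

#' @rdname agent_spec
#' @param p_novel_after_omission Probability of the novel (class 2) option
#'   after an unrewarded trial.
#' @param p_change1_after_reward Probability of a single-dimension change
#'   (class 1) after a rewarded trial.
#' @export
default_residual_policy <- function(p_novel_after_omission = 0.95,
                                    p_change1_after_reward = 0.65) {
  rbind(
    after_reward = c(0.25, p_change1_after_reward,
                     1 - 0.25 - p_change1_after_reward),
    after_omission = c(0.2 * (1 - p_novel_after_omission),
                       0.8 * (1 - p_novel_after_omission),
                       p_novel_after_omission)
  )
}

# sample the next latent state given the current one
.next_state <- function(state, agent) {
  if (state == "residual") {
    if (runif(1) < agent$a_oo) "residual" else sample(.features, 1L)
  } else {
    if (runif(1) < agent$a_rr) state else "residual"
  }
}

#' Simulate a CSST session from a latent-state agent
#'
#' Generates a full session: randomized option sets, latent rule/residual
#' state dynamics, state-conditional choices, rewards, and block structure.
#' The session starts in the residual state. The returned tibble carries the
#' ground-truth state per trial in `true_state`, and the generating
#' `agent_spec`/`block_schedule` as attributes `agent` and `schedule`.
#'
#' @param agent An [agent_spec()].
#' @param schedule A [block_schedule()].
#' @param n_blocks Number of completed blocks to simulate.
#' @param seed Optional integer seed; fixing it fixes the table bit-for-bit.
#' @param session_id Session label.
#' @param max_trials Safety cap on session length.
#' @return A trials tibble, one row per trial, with the columns of the trials
#'   TSV interface plus `true_state` and `block_trial` (1-based position
#'   within block).
#' @export
simulate_behavior <- function(agent = agent_spec(),
                              schedule = block_schedule(),
                              n_blocks = 6L,
                              seed = NULL,
                              session_id = "synthetic-01",
                              max_trials = n_blocks * schedule$criterion * 40L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(agent, "agent_spec"), inherits(schedule, "block_schedule"))

  opts <- generate_option_set(max_trials)
  opt_colors <- as.matrix(opts[paste0("opt", 1:3, "_color")])
  opt_shapes <- as.matrix(opts[paste0("opt", 1:3, "_shape")])

  state <- "residual"
  correct_feature <- draw_correct_feature(NULL, schedule)
  block <- 1L
  block_trial <- 0L
  count <- 0L
  prev_color <- NA_character_
  prev_shape <- NA_character_
  prev_reward <- NA_integer_

  res <- vector("list", max_trials)
  t <- 0L
  while (block <= n_blocks) {
    t <- t + 1L
    if (t > max_trials) {
      stop("session did not complete ", n_blocks, " blocks within ",
           max_trials, " trials; raise max_trials or revise the agent")
    }
    oc <- opt_colors[t, ]
    os <- opt_shapes[t, ]
    block_trial <- block_trial + 1L

    if (state != "residual") {
      match_idx <- which(oc == state | os == state)  # exactly one option
      if (agent$lapse > 0 && runif(1) < agent$lapse) {
        choice <- sample(setdiff(1:3, match_idx), 1L)
      } else {
        choice <- match_idx
      }
    } else if (is.na(prev_color) || is.null(agent$residual_policy)) {
      choice <- sample.int(3L, 1L)
    } else {
      classes <- choice_relation(prev_color, prev_shape, oc, os)
      row <- if (isTRUE(prev_reward == 1L)) 1L else 2L
      probs <- agent$residual_policy[row, ]
      avail <- sort(unique(classes))
      mass <- probs[avail + 1L]
      if (sum(mass) <= 0) {
        stop("residual policy has no mass on any available relation class ",
             "at trial ", t)
      }
      cls <- if (length(avail) == 1L) avail else {
        sample(avail, 1L, prob = mass / sum(mass))
      }
      cand <- which(classes == cls)
      choice <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }

    reward <- is_correct(oc[choice], os[choice], correct_feature)
    res[[t]] <- list(
      trial_index = t, block_index = block, block_trial = block_trial,
      correct_feature = correct_feature, choice_index = choice,
      chosen_color = oc[choice], chosen_shape = os[choice],
      reward = reward, true_state = state
    )

    adv <- advance_block(count, reward, schedule, correct_feature)
    count <- adv$correct_count
    if (adv$block_changed) {
      block <- block + 1L
      block_trial <- 0L
      correct_feature <- adv$correct_feature
    }
    prev_color <- oc[choice]
    prev_shape <- os[choice]
    prev_reward <- reward
    state <- .next_state(state, agent)
  }

  core <- dplyr::bind_rows(res[seq_len(t)])
  trials <- dplyr::bind_cols(
    tibble::tibble(session_id = session_id),
    core[c("trial_index", "block_index", "block_trial", "correct_feature")],
    opts[seq_len(t), ],
    core[c("choice_index", "chosen_color", "chosen_shape", "reward",
           "true_state")]
  )
  attr(trials, "agent") <- agent
  attr(trials, "schedule") <- schedule
  trials
}

#' Reward rate of a uniformly random chooser
#'
#' Simulates the task with an agent that picks uniformly among the three
#' presented options, under the standard option-generation and block-reward
#' rules. Because exactly one option matches any feature, the analytic reward
#' probability is 1/3.
#'
#' @param n_trials Number of trials to simulate.
#' @param schedule A [block_schedule()].
#' @param seed Optional seed.
#' @return A list with `n_trials`, `n_rewarded`, and `percent_rewarded`.
#' @export
simulate_random_policy <- function(n_trials = 100000L,
                                   schedule = block_schedule(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  opts <- generate_option_set(n_trials)
  oc <- as.matrix(opts[paste0("opt", 1:3, "_color")])
  os <- as.matrix(opts[paste0("opt", 1:3, "_shape")])
  choice <- sample.int(3L, n_trials, replace = TRUE)
  idx <- cbind(seq_len(n_trials), choice)
  chosen_color <- oc[idx]
  chosen_shape <- os[idx]

  # walk the block schedule; only the correct feature depends on history
  correct_feature <- character(n_trials)
  feat <- draw_correct_feature(NULL, schedule)
  count <- 0L
  reward <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    correct_feature[t] <- feat
    r <- (chosen_color[t] == feat) || (chosen_shape[t] == feat)
    reward[t] <- as.integer(r)
    count <- count + as.integer(r)
    if (count >= schedule$criterion) {
      count <- 0L
      feat <- draw_correct_feature(feat, schedule)
    }
  }
  list(
    n_trials = n_trials,
    n_rewarded = sum(reward),
    percent_rewarded = 100 * mean(reward)
  )
}

#' Neural tuning specification for the spike-count generator
#'
#' Log-linear Poisson tuning for synthetic neurons: per-neuron baseline rates
#' plus coefficients for rule identity (6 levels), chosen color (3), chosen
#' shape (3), and the 9-level color-by-shape identity interaction. Rule-based
#' trials apply a multiplicative `state_gain` to the rate (the default < 1
#' emulates the observed firing-rate reduction) and scale the chosen-feature
#' coefficients by `relevant_gain`/`irrelevant_gain` according to whether that
#' feature's domain is relevant to the active rule (expansion of rule-relevant
#' coding, compression of rule-irrelevant coding).
#'
#' The default generator also shifts the form of choice coding with the
#' latent state, mirroring the identity-to-category shift the analyses are
#' built to detect: residual-state trials carry conjunction (identity)
#' coding (`identity_coef` at full strength, additive feature coding scaled
#' by `residual_feature_gain`, 0 by default), while rule-based trials carry
#' additive category coding warped by the relevance gains (identity coding
#' scaled by `rule_identity_gain`, 0 by default). With these defaults,
#' choices that share a feature are represented more similarly only during
#' rule-based trials, and the rule-irrelevant domain collapses within each
#' rule. Setting every gain to 1 and `rule_sd = 0` yields a state-blind
#' ("no-warping") code for null calibration.
#'
#' @param n_neurons Named integer vector of neurons per region tag.
#' @param baseline_range Range (spikes/s) for uniform baseline rates.
#' @param rule_sd,feature_sd,identity_sd SDs of the Gaussian draws for rule
#'   identity, chosen color/shape, and identity-interaction coefficients
#'   (log-rate units).
#' @param state_gain Multiplicative rate factor on rule-based trials.
#' @param relevant_gain,irrelevant_gain Multipliers on chosen-feature
#'   coefficients when the feature's domain is rule-relevant / irrelevant.
#' @param residual_feature_gain Multiplier on additive feature coefficients
#'   during residual trials.
#' @param rule_identity_gain Multiplier on identity-interaction coefficients
#'   during rule-based trials.
#' @param rule_choice_alignment Correlation in `[0, 1]` between a rule's
#'   identity coefficients and the matching feature's choice coefficients.
#'   Positive values make rule and matching-choice coding share substrate, so
#'   their coding dimensions are neither identical nor orthogonal; 0 draws
#'   them independently.
#' @param epoch_duration Analysis epoch length in seconds.
#' @param presentation_epochs Also emit three 400-ms presentation-epoch counts
#'   per trial (for the stimulus/choice tuning analyses).
#' @return A list of class `tuning_spec`.
#' @export
tuning_spec <- function(n_neurons = c(OFC = 20L, VS = 20L, DS = 20L),
                        baseline_range = c(2, 10),
                        rule_sd = 0.3, feature_sd = 0.35, identity_sd = 0.3,
                        state_gain = 0.9,
                        relevant_gain = 1.8, irrelevant_gain = 0.3,
                        residual_feature_gain = 0, rule_identity_gain = 0,
                        rule_choice_alignment = 0.5,
                        epoch_duration = 3.35,
                        presentation_epochs = TRUE) {
  stopifnot(
    all(n_neurons > 0), !is.null(names(n_neurons)),
    epoch_duration > 0, state_gain > 0,
    relevant_gain >= 0, irrelevant_gain >= 0,
    residual_feature_gain >= 0, rule_identity_gain >= 0,
    rule_choice_alignment >= 0, rule_choice_alignment <= 1
  )
  structure(
    list(n_neurons = n_neurons, baseline_range = baseline_range,
         rule_sd = rule_sd, feature_sd = feature_sd, identity_sd = identity_sd,
         state_gain = state_gain, relevant_gain = relevant_gain,
         irrelevant_gain = irrelevant_gain,
         residual_feature_gain = residual_feature_gain,
         rule_identity_gain = rule_identity_gain,
         rule_choice_alignment = rule_choice_alignment,
         epoch_duration = epoch_duration,
         presentation_epochs = presentation_epochs),
    class = "tuning_spec"
  )
}

#' @rdname tuning_spec
#' @param ... Overrides passed to [tuning_spec()].
#' @export
no_warping_tuning <- function(...) {
  tuning_spec(rule_sd = 0, state_gain = 1, relevant_gain = 1,
              irrelevant_gain = 1, residual_feature_gain = 1,
              rule_identity_gain = 1, ...)
}

# realize per-neuron coefficients from a tuning_spec
.draw_tuning <- function(tuning) {
  n <- sum(tuning$n_neurons)
  ids <- sprintf("n%03d", seq_len(n))
  color_coef <- matrix(rnorm(n * 3, 0, tuning$feature_sd), n, 3,
                       dimnames = list(ids, .colors))
  shape_coef <- matrix(rnorm(n * 3, 0, tuning$feature_sd), n, 3,
                       dimnames = list(ids, .shapes))
  # rule coding partially aligned with the matching feature's choice coding
  al <- tuning$rule_choice_alignment
  feat_coef <- cbind(color_coef, shape_coef)
  feat_std <- if (tuning$feature_sd > 0) feat_coef / tuning$feature_sd else
    feat_coef * 0
  rule_coef <- tuning$rule_sd *
    (al * feat_std + sqrt(1 - al^2) * matrix(rnorm(n * 6), n, 6))
  dimnames(rule_coef) <- list(ids, .features)
  list(
    neuron_id = ids,
    region = rep(names(tuning$n_neurons), tuning$n_neurons),
    baseline = runif(n, tuning$baseline_range[1], tuning$baseline_range[2]),
    rule_coef = rule_coef,
    color_coef = color_coef,
    shape_coef = shape_coef,
    identity_coef = matrix(rnorm(n * 9, 0, tuning$identity_sd), n, 9,
                           dimnames = list(ids, paste(rep(.colors, each = 3),
                                                      .shapes, sep = "-")))
  )
}

#' Simulate Poisson spike counts for a session
#'
#' Draws `count ~ Poisson(rate * epoch_duration)` per neuron and trial, with
#' the log rate assembled from the [tuning_spec()] terms and the session's
#' ground-truth states. When `presentation_epochs` is set, three additional
#' 400-ms counts per trial are generated with the same rate model evaluated
#' on each presented option's features (in presentation order).
#'
#' @param trials A trials tibble from [simulate_behavior()] (needs
#'   `true_state`).
#' @param tuning A [tuning_spec()].
#' @param seed Optional seed.
#' @return A long tibble (neuron x trial) with columns `neuron_id`, `region`,
#'   `session_id`, `trial_index`, `spike_count`, and (optionally)
#'   `epoch1_count`..`epoch3_count`. The realized coefficients are attached as
#'   attribute `tuning_truth`; `epoch_duration` as attribute of same name.
#' @export
simulate_neurons <- function(trials, tuning = tuning_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot("true_state" %in% names(trials))
  tt <- .draw_tuning(tuning)
  n <- length(tt$neuron_id)
  T_ <- nrow(trials)

  state <- trials$true_state
  rule_based <- state != "residual"
  rule_domain <- ifelse(rule_based, feature_domain(ifelse(rule_based, state,
                                                          .features[1])), NA)
  g_color <- ifelse(!rule_based, tuning$residual_feature_gain,
                    ifelse(rule_domain == "color",
                           tuning$relevant_gain, tuning$irrelevant_gain))
  g_shape <- ifelse(!rule_based, tuning$residual_feature_gain,
                    ifelse(rule_domain == "shape",
                           tuning$relevant_gain, tuning$irrelevant_gain))
  g_identity <- ifelse(rule_based, tuning$rule_identity_gain, 1)
  identity <- paste(trials$chosen_color, trials$chosen_shape, sep = "-")

  # n x T log-rate matrix
  log_rate <- matrix(log(tt$baseline), n, T_)
  rule_term <- matrix(0, n, T_)
  rule_term[, rule_based] <- tt$rule_coef[, state[rule_based], drop = FALSE]
  log_rate <- log_rate + rule_term +
    sweep(tt$color_coef[, trials$chosen_color, drop = FALSE], 2, g_color, `*`) +
    sweep(tt$shape_coef[, trials$chosen_shape, drop = FALSE], 2, g_shape, `*`) +
    sweep(tt$identity_coef[, identity, drop = FALSE], 2, g_identity, `*`)
  rate <- exp(log_rate)
  rate[, rule_based] <- rate[, rule_based] * tuning$state_gain
  if (any(rate <= 0)) stop("nonpositive firing rate in tuning configuration")

  counts <- matrix(rpois(n * T_, rate * tuning$epoch_duration), n, T_)
  out <- tibble::tibble(
    neuron_id = rep(tt$neuron_id, T_),
    region = rep(tt$region, T_),
    session_id = rep(trials$session_id, each = n),
    trial_index = rep(trials$trial_index, each = n),
    spike_count = as.integer(counts)
  )

  if (isTRUE(tuning$presentation_epochs)) {
    # option presented j-th in order, per trial
    ord <- cbind(trials$opt1_order, trials$opt2_order, trials$opt3_order)
    oc <- cbind(trials$opt1_color, trials$opt2_color, trials$opt3_color)
    os <- cbind(trials$opt1_shape, trials$opt2_shape, trials$opt3_shape)
    for (j in 1:3) {
      slot <- apply(ord, 1, function(o) which(o == j))
      stim_color <- oc[cbind(seq_len(T_), slot)]
      stim_shape <- os[cbind(seq_len(T_), slot)]
      lr <- matrix(log(tt$baseline), n, T_) + rule_term +
        sweep(tt$color_coef[, stim_color, drop = FALSE], 2, g_color, `*`) +
        sweep(tt$shape_coef[, stim_shape, drop = FALSE], 2, g_shape, `*`)
      r <- exp(lr)
      r[, rule_based] <- r[, rule_based] * tuning$state_gain
      out[[paste0("epoch", j, "_count")]] <-
        as.integer(matrix(rpois(n * T_, r * 0.4), n, T_))
    }
  }

  attr(out, "tuning_truth") <- tt
  attr(out, "tuning_spec") <- tuning
  attr(out, "epoch_duration") <- tuning$epoch_duration
  out
}

#' Canonical synthetic fixture suite
#'
#' Bundles the small, deterministic datasets the test-suite and examples use:
#' (a) a 6-block behavioral session from the default agent; (b) a 60-neuron,
#' 3-region spike table for that session; (c) a degenerate all-residual
#' session; and (d) a noiseless mini-population with known identity-coded
#' versus additive-coded neurons (deterministic responses, for tuning-index
#' checks).
#'
#' @param seed Integer seed; the same seed reproduces every table exactly.
#' @return A named list `behavior`, `spikes`, `residual_only`, `noiseless`.
#' @export
make_fixture_suite <- function(seed = 1L) {
  behavior <- simulate_behavior(seed = seed)
  spikes <- simulate_neurons(behavior, tuning_spec(), seed = seed + 1L)
  # long enough that maximum likelihood prefers the all-residual explanation
  # over labeling chance feature streaks as short rule states
  residual_only <- simulate_behavior(
    agent = agent_spec(a_oo = 1, residual_policy = NULL),
    n_blocks = 12L, seed = seed + 2L, session_id = "synthetic-residual"
  )

  # noiseless mini-population: responses are exact means, no Poisson draw
  grid <- tidyr::expand_grid(color = .colors, shape = .shapes)
  grid <- dplyr::bind_rows(replicate(4, grid, simplify = FALSE))
  identity_effect <- setNames(seq(-2, 2, length.out = 9),
                              paste(rep(.colors, each = 3), .shapes, sep = "-"))
  # identity-tuned neuron: pure interaction pattern orthogonal to additive fit
  inter <- outer(c(1, -2, 1), c(1, -2, 1)) / 2
  dimnames(inter) <- list(.colors, .shapes)
  noiseless <- dplyr::bind_rows(
    tibble::tibble(neuron_id = "identity_cell", grid,
                   response = inter[cbind(grid$color, grid$shape)]),
    tibble::tibble(neuron_id = "additive_cell", grid,
                   response = (match(grid$color, .colors) - 2) +
                     0.5 * (match(grid$shape, .shapes) - 2))
  )
  noiseless$response <- noiseless$response +
    rep(seq(0, 0.03, length.out = 36), 2)  # tiny ramp so variances are nonzero

  list(behavior = behavior, spikes = spikes,
       residual_only = residual_only, noiseless = noiseless)
}
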