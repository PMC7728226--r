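# Shared, lazily built fixtures. Everything is generated in code under fixed
# seeds; the cache keeps expensive objects (sessions, spike tables, HMM fits)
# from being rebuilt across test files.
.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, builder(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# standard 12-block session from the default agent, with spikes and HMM fit
std_trials <- function() fx("std_trials", function() {
  simulate_behavior(n_blocks = 12L, seed = 5)
})

std_spikes <- function() fx("std_spikes", function() {
  simulate_neurons(std_trials(), tuning_spec(), seed = 6)
})

std_fit <- function() fx("std_fit", function() {
  fit_baum_welch(std_trials(), n_restarts = 5, seed = 7)
})

std_states <- function() std_fit()$viterbi_path

null_spikes <- function() fx("null_spikes", function() {
  simulate_neurons(std_trials(), no_warping_tuning(), seed = 6)
})

per_rule_pm <- function() fx("per_rule_pm", function() {
  build_pseudotrials(std_spikes(), std_trials(), std_states(),
                     scheme = "per_rule", seed = 101)
})

choice_dims <- function() fx("choice_dims", function() {
  fit_choice_classifiers(per_rule_pm(), cv_folds = 10, seed = 102)
})

# exhaustive-enumeration oracles for short sessions: every state path is kept
# separate until the end, so these are independent of the forward/Viterbi
# recursions they check
enumerate_paths <- function(E, P, init) {
  T_ <- nrow(E)
  S <- ncol(E)
  prob <- init * E[1, ]
  last <- seq_len(S)
  if (T_ > 1) {
    for (t in 2:T_) {
      old_len <- length(prob)
      prob <- unlist(lapply(seq_len(S), function(j) {
        prob * P[last, j] * E[t, j]
      }))
      last <- rep(seq_len(S), each = old_len)
    }
  }
  list(prob = prob, n_paths = length(prob))
}

brute_loglik <- function(trials, hmm) {
  E <- rulewarp:::.emission_matrix(trials)
  log(sum(enumerate_paths(E, hmm$transition, hmm$initial)$prob))
}

# joint probability of a specific state path under the model
path_prob <- function(trials, hmm, path) {
  E <- rulewarp:::.emission_matrix(trials)
  s <- match(path, hmm$states)
  p <- hmm$initial[s[1]] * E[1, s[1]]
  for (t in seq_along(s)[-1]) {
    p <- p * hmm$transition[s[t - 1], s[t]] * E[t, s[t]]
  }
  p
}

brute_viterbi <- function(trials, hmm) {
  E <- rulewarp:::.emission_matrix(trials)
  enum <- enumerate_paths(E, hmm$transition, hmm$initial)
  best <- which.max(enum$prob)  # first max = lowest path index
  # decode the path index: trial-1 state varies fastest in the construction
  idx <- best - 1L
  T_ <- nrow(E)
  path <- integer(T_)
  for (t in seq_len(T_)) {
    path[t] <- idx %% 7L + 1L
    idx <- idx %/% 7L
  }
  hmm$states[path]
}

# a random short session: choices drawn at random so all states stay live
random_short_session <- function(T_) {
  opts <- generate_option_set(T_)
  choice <- sample.int(3L, T_, replace = TRUE)
  idx <- cbind(seq_len(T_), choice)
  tibble::tibble(
    session_id = "oracle",
    trial_index = seq_len(T_),
    chosen_color = as.matrix(opts[paste0("opt", 1:3, "_color")])[idx],
    chosen_shape = as.matrix(opts[paste0("opt", 1:3, "_shape")])[idx]
  )
}

# independent two-branch oracle for expected information gain: plain
# arithmetic, no calls into the belief-update code path
oracle_info_gain <- function(belief, color, shape) {
  feats <- names(belief)
  chosen <- feats %in% c(color, shape)
  p_rew <- sum(belief[chosen])
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  lik_r <- ifelse(chosen, 0.5, 0)
  lik_u <- ifelse(chosen, 0, 0.25)
  post_r <- belief * lik_r
  post_u <- belief * lik_u
  h_r <- if (sum(post_r) > 0) ent(post_r / sum(post_r)) else 0
  h_u <- if (sum(post_u) > 0) ent(post_u / sum(post_u)) else 0
  ent(belief) - (p_rew * h_r + (1 - p_rew) * h_u)
}
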