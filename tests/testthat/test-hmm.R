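test_that("the constructed transition matrix has the tied, constrained form", {
  hmm <- build_hmm(0.95, 0.6)
  P <- hmm$transition
  expect_equal(unname(rowSums(P)), rep(1, 7))
  expect_identical(hmm$n_free_parameters, 2L)
  # structural zeros: no rule-to-rule transitions
  rules <- 2:7
  off <- P[rules, rules]
  diag(off) <- 0
  expect_true(all(off == 0))
  expect_equal(unname(diag(P)[rules]), rep(0.95, 6))
  expect_equal(unname(P[rules, 1]), rep(0.05, 6))
  expect_equal(unname(P[1, rules]), rep(0.4 / 6, 6))
  expect_equal(hmm$initial, c(1, rep(0, 6)))

  degenerate <- build_hmm(1, 1)
  expect_equal(unname(diag(degenerate$transition)), rep(1, 7))
  expect_error(build_hmm(1.2, 0.5), "probabilities")
  expect_error(build_hmm(0.5, -0.1), "probabilities")
})

test_that("emission model matches the fixed observation probabilities", {
  expect_equal(emission_logprob("cyan", "star", "cyan"), 0)
  expect_equal(emission_logprob("cyan", "star", "star"), 0)
  expect_equal(emission_logprob("cyan", "star", "magenta"), -1e30)
  expect_equal(emission_logprob("cyan", "star", "residual"), log(1 / 3))
  expect_error(emission_logprob("cyan", "star", "banana"), "state")
})

test_that("forward-backward matches exhaustive enumeration on short sessions", {
  set.seed(51)
  for (i in 1:60) {
    T_ <- sample(2:7, 1)
    tr <- random_short_session(T_)
    hmm <- build_hmm(runif(1, 0.3, 0.99), runif(1, 0.3, 0.99))
    inf <- forward_backward(tr, hmm)
    expect_equal(inf$log_likelihood, brute_loglik(tr, hmm), tolerance = 1e-10)
    expect_equal(unname(rowSums(inf$posteriors)), rep(1, T_),
                 tolerance = 1e-10)
  }
})

test_that("posteriors respect the start state and zero emissions", {
  one <- random_short_session(1)
  inf <- forward_backward(one, build_hmm(0.9, 0.6))
  expect_equal(unname(inf$posteriors[1, "residual"]), 1)

  tr <- tibble::tibble(chosen_color = c("cyan", "cyan"),
                       chosen_shape = c("star", "star"))
  g <- forward_backward(tr, build_hmm(0.9, 0.6))$posteriors
  # a cyan-star choice has zero posterior on every non-matching rule
  expect_equal(unname(g[1, c("magenta", "yellow", "circle", "triangle")]),
               rep(0, 4))
  expect_error(forward_backward(tr[0, ], build_hmm(0.9, 0.6)), "non-empty")
})

test_that("viterbi matches exhaustive argmax on short sessions", {
  set.seed(52)
  for (i in 1:40) {
    T_ <- sample(2:7, 1)
    tr <- random_short_session(T_)
    hmm <- build_hmm(runif(1, 0.3, 0.99), runif(1, 0.3, 0.99))
    # co-optimal paths exist (different tie orders are both correct), so the
    # check is on the achieved joint probability, not path identity
    expect_equal(path_prob(tr, hmm, viterbi(tr, hmm)),
                 path_prob(tr, hmm, brute_viterbi(tr, hmm)),
                 tolerance = 1e-12)
  }
})

test_that("viterbi labels persistent single-feature runs as that rule", {
  set.seed(53)
  shapes <- sample(feature_space()$shapes, 10, replace = TRUE)
  tr <- tibble::tibble(chosen_color = rep("cyan", 10), chosen_shape = shapes)
  path <- viterbi(tr, build_hmm(0.9, 0.6))
  expect_true(all(path[-1] == "cyan"))

  # alternating incompatible choices can only come from the residual state
  tr2 <- tibble::tibble(
    chosen_color = rep(c("cyan", "magenta"), 4),
    chosen_shape = rep(c("star", "circle"), 4)
  )
  expect_true(all(viterbi(tr2, build_hmm(0.9, 0.6)) == "residual"))
})

test_that("Baum-Welch recovers generating parameters and is monotone", {
  # recovery is assessed under the model's own generative assumptions
  # (max-entropy residual choices), so the emission model is well specified
  tr <- simulate_behavior(agent = agent_spec(a_rr = 0.95, a_oo = 0.6,
                                             residual_policy = NULL),
                          n_blocks = 130, seed = 54)
  tr <- tr[seq_len(min(nrow(tr), 5000)), ]
  fit <- fit_baum_welch(tr, n_restarts = 3, seed = 55)
  expect_lt(abs(fit$hmm$a_rr - 0.95), 0.05)
  expect_lt(abs(fit$hmm$a_oo - 0.60), 0.05)
  expect_true(all(diff(fit$ll_trace) > -1e-9))
  # fitted likelihood is at least that of the generating parameters
  gen_ll <- forward_backward(tr, build_hmm(0.95, 0.6))$log_likelihood
  expect_gte(fit$log_likelihood, gen_ll - 1e-6)
  # structural zeros survive EM
  P <- fit$hmm$transition
  off <- P[2:7, 2:7]
  diag(off) <- 0
  expect_true(all(off == 0))
  # decoded rules track the generating correct feature on rule trials
  lab <- label_trials(tr, fit)
  rule_trials <- tr$true_state != "residual" & lab$hmm_state != "residual"
  expect_gte(mean(lab$hmm_state[lab$rule_based] ==
                    tr$true_state[lab$rule_based]), 0.90)
})

test_that("alternative labelings implement the block-based definitions", {
  tr <- alternative_labelings(std_trials(), burn_in = 5)
  expect_identical(tr$label_correct, tr$reward == 1)
  expect_true(all(tr$label_burn_in[tr$block_trial <= 5] == FALSE))
  # burn-in labeling is a subset of the correct labeling
  expect_true(all(!tr$label_burn_in | tr$label_correct))
})

test_that("labeling comparison prefers the generating state labels", {
  tr <- std_trials()
  sp <- std_spikes()
  trl <- alternative_labelings(tr)
  labs <- list(hmm = std_states() != "residual",
               correct = trl$label_correct,
               burn_in = trl$label_burn_in)
  cmp <- compare_labelings(sp, labs)
  sums <- cmp |>
    dplyr::group_by(region) |>
    dplyr::summarise(w = sum(aic_weight), wb = sum(bic_weight))
  expect_equal(sums$w, rep(1, nrow(sums)), tolerance = 1e-12)
  expect_equal(sums$wb, rep(1, nrow(sums)), tolerance = 1e-12)
  best <- cmp |>
    dplyr::group_by(region) |>
    dplyr::slice_min(aic, n = 1)
  expect_true(all(best$labeling == "hmm"))

  # identical labelings tie exactly
  cmp2 <- compare_labelings(sp, list(a = labs$hmm, b = labs$hmm))
  wide <- tidyr::pivot_wider(cmp2[, c("region", "labeling", "aic")],
                             names_from = "labeling", values_from = "aic")
  expect_equal(wide$a, wide$b)
})
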