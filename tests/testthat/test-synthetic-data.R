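test_that("behavior generation is deterministic in the seed", {
  a <- simulate_behavior(n_blocks = 3, seed = 41)
  b <- simulate_behavior(n_blocks = 3, seed = 41)
  expect_identical(a, b)
  sp1 <- simulate_neurons(a, tuning_spec(n_neurons = c(OFC = 4L)), seed = 42)
  sp2 <- simulate_neurons(b, tuning_spec(n_neurons = c(OFC = 4L)), seed = 42)
  expect_identical(sp1$spike_count, sp2$spike_count)
})

test_that("a lapse-free agent in the correct rule is always rewarded", {
  tr <- simulate_behavior(agent = agent_spec(a_rr = 0.9, a_oo = 0.5,
                                             lapse = 0),
                          n_blocks = 4, seed = 43)
  in_rule <- tr$true_state == tr$correct_feature
  expect_gt(sum(in_rule), 0)
  expect_true(all(tr$reward[in_rule] == 1))
  # and with a lapse, rule states sometimes violate the rule
  trl <- simulate_behavior(agent = agent_spec(a_rr = 0.9, a_oo = 0.5,
                                              lapse = 0.3),
                           n_blocks = 4, seed = 43)
  rule_trials <- trl$true_state != "residual"
  matches <- is_correct(trl$chosen_color[rule_trials],
                        trl$chosen_shape[rule_trials],
                        trl$true_state[rule_trials])
  expect_lt(mean(matches), 1)
})

test_that("post-omission residual choices never repeat features when novel-forced", {
  pol <- rbind(after_reward = c(0.25, 0.65, 0.10),
               after_omission = c(0, 0, 1))
  tr <- simulate_behavior(agent = agent_spec(a_oo = 1, residual_policy = pol),
                          n_blocks = 3, seed = 44)
  prev_rewarded <- c(NA, head(tr$reward, -1))
  rel <- c(NA, choice_relation(head(tr$chosen_color, -1),
                               head(tr$chosen_shape, -1),
                               tr$chosen_color[-1], tr$chosen_shape[-1]))
  post_omit <- which(!is.na(prev_rewarded) & prev_rewarded == 0)
  expect_true(all(rel[post_omit] == 2))
})

test_that("state run lengths are geometric with the chain parameters", {
  tr <- simulate_behavior(agent = agent_spec(a_rr = 0.95, a_oo = 0.6),
                          n_blocks = 130, seed = 45)
  tr <- tr[seq_len(min(nrow(tr), 5000)), ]
  runs <- rle(tr$true_state)
  # drop the final (possibly truncated) run
  lens <- head(runs$lengths, -1)
  vals <- head(runs$values, -1)
  rule_lens <- lens[vals != "residual"]
  res_lens <- lens[vals == "residual"]
  # chi-square goodness of fit against the geometric pmf (run lengths are
  # discrete, so a KS test would be miscalibrated by ties); tail pooled so
  # every expected cell count is adequate
  gof_p <- function(x, p_leave, k_max) {
    obs <- table(factor(pmin(x, k_max), levels = 1:k_max))
    probs <- dgeom(0:(k_max - 1), p_leave)
    probs[k_max] <- 1 - pgeom(k_max - 2, p_leave)
    suppressWarnings(chisq.test(as.vector(obs), p = probs)$p.value)
  }
  expect_gt(gof_p(rule_lens, 0.05, 40), 0.01)
  expect_gt(gof_p(res_lens, 0.40, 8), 0.01)
})

test_that("spike counts are Poisson with the configured rates", {
  tr <- std_trials()
  flat <- tuning_spec(n_neurons = c(OFC = 30L), rule_sd = 0, feature_sd = 0,
                      identity_sd = 0, state_gain = 1, relevant_gain = 1,
                      irrelevant_gain = 1, residual_feature_gain = 1,
                      rule_identity_gain = 1, baseline_range = c(5, 5),
                      presentation_epochs = FALSE)
  sp <- simulate_neurons(tr, flat, seed = 46)
  mu <- 5 * 3.35
  n <- nrow(sp)
  expect_lt(abs(mean(sp$spike_count) - mu), 3 * sqrt(mu / n))
  # index of dispersion near 1 at large n
  disp <- var(sp$spike_count) / mean(sp$spike_count)
  expect_lt(abs(disp - 1), 3 * sqrt(2 / n))
})

test_that("state_gain < 1 lowers rule-based firing rates", {
  tr <- std_trials()
  # isolate the state gain: identical coding in both states so the rate
  # contrast reflects the multiplicative factor alone
  sp <- simulate_neurons(tr, tuning_spec(state_gain = 0.9, rule_sd = 0,
                                         relevant_gain = 1,
                                         irrelevant_gain = 1,
                                         residual_feature_gain = 1,
                                         rule_identity_gain = 1,
                                         presentation_epochs = FALSE),
                         seed = 47)
  rb <- tibble::tibble(trial_index = tr$trial_index,
                       rule = tr$true_state != "residual")
  d <- dplyr::inner_join(zscore_within_neuron(sp, "center"), rb,
                         by = "trial_index")
  tt <- t.test(d$z[d$rule], d$z[!d$rule], alternative = "less")
  expect_lt(tt$p.value, 0.001)
})

test_that("irrelevant gain zero removes irrelevant-domain decodability", {
  tr <- std_trials()
  sp <- simulate_neurons(tr, tuning_spec(irrelevant_gain = 0), seed = 48)
  z <- zscore_within_neuron(sp)
  rule <- tr$true_state != "residual"
  dom <- ifelse(rule, ifelse(tr$true_state %in% feature_space()$colors,
                             "color", "shape"), NA)
  wide <- tidyr::pivot_wider(
    dplyr::select(z, "neuron_id", "trial_index", "z"),
    names_from = "neuron_id", values_from = "z")
  wide <- wide[match(tr$trial_index, wide$trial_index), ]
  x <- as.matrix(wide[, -1])
  # under color rules the shape is the irrelevant domain
  rows <- which(rule & dom == "color")
  y <- factor(tr$chosen_shape[rows])
  set.seed(49)
  folds <- sample(rep_len(1:5, length(rows)))
  acc <- vapply(1:5, function(k) {
    tr_rows <- rows[folds != k]
    te_rows <- rows[folds == k]
    centroid <- sapply(levels(y), function(l) {
      colMeans(x[tr_rows[y[folds != k] == l], , drop = FALSE])
    })
    pred <- levels(y)[apply(x[te_rows, , drop = FALSE] %*% centroid -
                              rep(colSums(centroid^2) / 2,
                                  each = length(te_rows)),
                            1, which.max)]
    mean(pred == y[folds == k])
  }, numeric(1))
  expect_lt(abs(mean(acc) - 1 / 3), 0.12)
})

test_that("the fixture suite is reproducible and behaves as designed", {
  fxa <- make_fixture_suite(seed = 2)
  fxb <- make_fixture_suite(seed = 2)
  expect_identical(fxa$behavior, fxb$behavior)
  expect_identical(fxa$spikes$spike_count, fxb$spikes$spike_count)
  expect_identical(dim(fxa$spikes), dim(fxb$spikes))

  # the all-residual session decodes as residual nearly everywhere
  fitc <- fit_baum_welch(fxa$residual_only, n_restarts = 3, seed = 3,
                         max_iter = 2000)
  expect_gte(mean(fitc$viterbi_path == "residual"), 0.99)

  # identity-category index separates conjunction from additive tuning
  nl <- fxa$noiseless
  idx <- lapply(split(nl, nl$neuron_id), function(d) {
    identity_category_index(d$response, d$color, d$shape)$index
  })
  expect_gt(idx$identity_cell, idx$additive_cell)
})
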