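test_that("within-neuron normalization centers and scales as requested", {
  sp <- std_spikes()
  z <- zscore_within_neuron(sp)
  by_n <- z |>
    dplyr::group_by(neuron_id) |>
    dplyr::summarise(m = mean(z), s = sd(z))
  expect_true(all(abs(by_n$m) < 1e-9))
  expect_true(all(abs(by_n$s - 1) < 1e-9))
  cz <- zscore_within_neuron(sp, "center")
  by_c <- cz |>
    dplyr::group_by(neuron_id) |>
    dplyr::summarise(m = mean(z))
  expect_true(all(abs(by_c$m) < 1e-9))
  # normalization preserves within-neuron ordering
  one <- sp$neuron_id[1]
  expect_identical(order(z$z[z$neuron_id == one]),
                   order(cz$z[cz$neuron_id == one]))
  # constant neurons are centered, not scaled, with a message
  flat <- tibble::tibble(neuron_id = "f1", region = "OFC",
                         session_id = "s", trial_index = 1:10,
                         spike_count = rep(4L, 10))
  expect_message(fz <- zscore_within_neuron(flat), "zero-variance")
  expect_true(all(fz$z == 0))
})

test_that("permutation test matches exact enumeration and detects shifts", {
  x <- c(1.2, 0.8, 1.5, 1.1, 3.1, 2.8, 3.3, 2.9)
  lab <- rep(c(FALSE, TRUE), each = 4)
  mc <- rate_contrast_permutation(x, lab, n_perm = 4000, seed = 71)
  ex <- rate_contrast_permutation(x, lab, exact = TRUE)
  expect_equal(ex$difference, mean(x[lab]) - mean(x[!lab]))
  expect_equal(ex$n_perm, choose(8, 4))
  expect_lt(abs(mc$p - ex$p), 0.02)

  set.seed(72)
  y <- c(rnorm(200), rnorm(200, 1))
  shifted <- rate_contrast_permutation(y, rep(c(FALSE, TRUE), each = 200),
                                       n_perm = 1000, seed = 73)
  expect_lt(shifted$p, 0.01)
  expect_error(rate_contrast_permutation(1:5, c(TRUE, rep(FALSE, 4))),
               "at least 2")
})

test_that("tuning ANOVAs recover generator tuning and match hand-computed F", {
  suite <- tuning_anova_suite(std_spikes(), std_trials(), std_states())
  sm <- suite$summary
  rid <- sm[sm$factor == "rule_identity", ]
  expect_true(all(rid$proportion > 0.3))
  expect_true(all(rid$p_binomial < 0.001))

  # hand-computed one-way F on a small synthetic neuron
  counts <- c(10, 12, 11, 30, 31, 29, 50, 52, 51)
  g <- rep(c("a", "b", "c"), each = 3)
  k <- 3; n <- 9
  gm <- mean(counts)
  ssb <- sum(tapply(counts, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(counts, g, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / (k - 1)) / (ssw / (n - k))
  a <- anova(lm(counts ~ factor(g)))
  expect_equal(a$`F value`[1], f_hand, tolerance = 1e-12)
  # the suite reports the same F for an equivalent six-level contrast
  expect_true(all(c("F", "p") %in% names(suite$neurons)))
})

test_that("the Gini index follows the printed formula and its invariances", {
  expect_equal(gini_index(c(0, 0, 0, 1)), 0.75)       # 1 - 1/N
  expect_equal(gini_index(rep(3.7, 11)), 0, tolerance = 1e-12)
  set.seed(74)
  x <- rexp(40)
  expect_equal(gini_index(x), gini_index(5.3 * x), tolerance = 1e-12)
  expect_equal(gini_index(x), gini_index(sample(x)), tolerance = 1e-12)
  expect_gte(gini_index(c(x, 0)), gini_index(x))
  expect_error(gini_index(rep(0, 5)), "all-zero")
  expect_error(gini_index(c(1, -1)), "non-negative")
})

test_that("mutual information matches hand plug-in values", {
  # deterministic binary channel: 1 bit
  x <- rep(c(0L, 10L), each = 50)
  id <- rep(c("a", "b"), each = 50)
  res <- mutual_information(x, id, rep(FALSE, 100), seed = 75)
  resid <- res[res$choice_type == "residual", ]
  expect_equal(resid$mi, 1)
  expect_equal(resid$bits_per_spike, 1 / mean(x))

  # 2x2 joint counts 30/10/10/30, hand plug-in arithmetic
  counts <- c(rep(0L, 30), rep(5L, 10), rep(0L, 10), rep(5L, 30))
  ids <- c(rep("a", 40), rep("b", 40))
  out <- mutual_information(counts, ids, rep(FALSE, 80), seed = 76)
  p <- c(30, 10, 10, 30) / 80
  hand <- sum(p * log2(p / (c(0.5, 0.5, 0.5, 0.5) * 0.5)))
  expect_equal(out$mi[out$choice_type == "residual"], hand, tolerance = 1e-12)
})

test_that("MI sits at the shuffle floor when counts are independent of choice", {
  set.seed(77)
  diffs <- replicate(50, {
    n <- 120
    counts <- rpois(n, 8)
    id <- sample(rep(paste(rep(feature_space()$colors, each = 3),
                           feature_space()$shapes), length.out = n))
    res <- mutual_information(counts, id, rep(FALSE, n), n_shuffle = 30)
    r <- res[res$choice_type == "residual", ]
    r$mi - r$mi_shuffle
  })
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("rule-based downsampling equates the trial counts", {
  set.seed(78)
  counts <- rpois(300, 6)
  id <- sample(letters[1:9], 300, replace = TRUE)
  rb <- c(rep(TRUE, 220), rep(FALSE, 80))
  res <- mutual_information(counts, id, rb, seed = 79)
  expect_equal(res$n[res$choice_type == "rule_based"], 80)
  expect_equal(res$n[res$choice_type == "residual"], 80)
})

test_that("identity-category index separates conjunction from additive codes", {
  set.seed(80)
  grid <- tidyr::expand_grid(color = feature_space()$colors,
                             shape = feature_space()$shapes)
  d <- dplyr::bind_rows(replicate(12, grid, simplify = FALSE))
  inter <- outer(c(1, -2, 1), c(1, -2, 1)) / 2
  dimnames(inter) <- list(feature_space()$colors, feature_space()$shapes)
  seeds <- 1:12
  idx <- vapply(seeds, function(s) {
    set.seed(s)
    noise <- rnorm(nrow(d), 0, 0.3)
    y_add <- (match(d$color, feature_space()$colors) - 2) +
      0.5 * (match(d$shape, feature_space()$shapes) - 2) + noise
    y_int <- inter[cbind(d$color, d$shape)] + noise
    c(add = identity_category_index(y_add, d$color, d$shape)$index,
      int = identity_category_index(y_int, d$color, d$shape)$index)
  }, numeric(2))
  expect_lt(t.test(idx["add", ] - idx["int", ])$p.value, 0.01)
  expect_true(mean(idx["add", ]) < mean(idx["int", ]))

  # F values agree with the reference linear-model ANOVA machinery
  y <- inter[cbind(d$color, d$shape)] + rnorm(nrow(d), 0, 0.2)
  got <- identity_category_index(y, d$color, d$shape)
  ref_id <- summary(aov(y ~ factor(paste(d$color, d$shape))))[[1]]
  expect_equal(got$F_id, ref_id$`F value`[1], tolerance = 1e-9)

  # identical data under both labels gives an identical index
  expect_equal(identity_category_index(y, d$color, d$shape)$index,
               identity_category_index(y, d$color, d$shape)$index)
})

test_that("identity-category suite finds stronger identity coding in residual", {
  ic <- identity_category_suite(std_spikes(), std_trials(), std_states())
  expect_true(all(ic$contrast$difference < 0))
  # pooled across regions (20 neurons per region is thin for per-region tests)
  wide <- tidyr::pivot_wider(
    ic$neurons[, c("region", "neuron_id", "choice_type", "index")],
    names_from = "choice_type", values_from = "index")
  wide <- wide[stats::complete.cases(wide), ]
  pooled <- t.test(wide$rule_based, wide$residual, paired = TRUE)
  expect_lt(pooled$p.value, 0.01)
  expect_lt(unname(pooled$estimate), 0)
})

test_that("BH control matches the hand-applied step-up rule", {
  expect_true(all(bh_fdr(rep(0.001, 10))$reject))
  expect_false(any(bh_fdr(rep(0.9, 10))$reject))
  p <- c(0.01, 0.04, 0.03, 0.005, 0.2)
  # hand: sorted p = .005 .01 .03 .04 .2 vs (k/5)*.05 = .01 .02 .03 .04 .05;
  # largest k with p_(k) <= threshold is k = 4 -> reject the four smallest
  out <- bh_fdr(p)
  expect_identical(out$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$p_adjusted, p.adjust(p, "BH"))
})

test_that("relevance sharpens tuning for the rule-relevant domain", {
  res <- relevance_tuning_glm(std_spikes(), std_trials(), std_states(),
                              target = "choice")
  b <- setNames(res$model$estimate, res$model$term)
  pv <- setNames(res$model$p, res$model$term)
  expect_gt(b[["S:R"]], 0)
  expect_lt(pv[["S:R"]], 0.01)
  expect_gt(b[["S"]] + b[["S:R"]], 0)  # relevant-domain tuning slope
  ci <- res$contrasts
  rvi <- ci[ci$contrast == "relevant_vs_irrelevant", ]
  expect_gt(rvi$difference, 0)
  expect_lt(rvi$p, 0.01)

  # no relevance modulation in a state-blind generator
  res0 <- relevance_tuning_glm(null_spikes(), std_trials(), std_states(),
                               target = "choice")
  t0 <- res0$model$statistic[res0$model$term == "S:R"]
  expect_lt(abs(t0), 3)
})
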