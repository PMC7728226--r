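test_that("condition schemes enumerate the documented condition sets", {
  expect_equal(nrow(scheme_conditions("rule_vs_residual")), 18)
  expect_equal(nrow(scheme_conditions("color_vs_shape_rule")), 18)
  s3 <- scheme_conditions("per_rule")
  expect_equal(nrow(s3), 27)  # 6 rules x 3 matching identities + 9 residual
  # each rule condition's identity matches the rule feature
  rule_rows <- s3[s3$type != "residual", ]
  expect_true(all(rule_rows$chosen_color == rule_rows$type |
                    rule_rows$chosen_shape == rule_rows$type))
})

test_that("pseudotrial matrices have the documented shape and determinism", {
  pm <- build_pseudotrials(std_spikes(), std_trials(), std_states(),
                           scheme = "rule_vs_residual", seed = 81)
  expect_equal(nrow(pm$values), 9 * 2 * 20)
  expect_equal(table(pm$conditions$condition) |> unique() |> as.integer(), 20L)
  pm2 <- build_pseudotrials(std_spikes(), std_trials(), std_states(),
                            scheme = "rule_vs_residual", seed = 81)
  expect_identical(pm$values, pm2$values)
})

test_that("exclusion and imputation rules follow the roster policy", {
  tr <- std_trials()
  sp <- std_spikes()
  # engineer a silent neuron and a low-rate neuron
  silent <- sp[sp$neuron_id == "n001", ]
  silent$neuron_id <- "silent"
  silent$spike_count <- 0L
  slow <- sp[sp$neuron_id == "n001", ]
  slow$neuron_id <- "slow"
  slow$spike_count <- rbinom(nrow(slow), 1, 0.5)  # far below 2 spikes/s
  sp2 <- dplyr::bind_rows(sp, silent, slow)
  pm <- suppressMessages(
    build_pseudotrials(sp2, tr, std_states(),
                       scheme = "rule_vs_residual", seed = 82)
  )
  roster <- pm$roster
  expect_identical(roster$status[roster$neuron_id == "silent"], "excluded")
  expect_match(roster$reason[roster$neuron_id == "silent"], "rate<2")
  expect_identical(roster$status[roster$neuron_id == "slow"], "excluded")
  expect_false("silent" %in% colnames(pm$values))

  # a neuron missing a few conditions is imputed at its mean normalized rate
  drop_cond <- std_states() == "residual" &
    tr$chosen_color == "cyan" & tr$chosen_shape == "star"
  sp3 <- dplyr::bind_rows(
    sp,
    dplyr::mutate(
      dplyr::filter(sp, .data$neuron_id == "n002",
                    !.data$trial_index %in% tr$trial_index[drop_cond]),
      neuron_id = "gappy")
  )
  pm3 <- build_pseudotrials(sp3, tr, std_states(),
                            scheme = "rule_vs_residual", seed = 83)
  r3 <- pm3$roster[pm3$roster$neuron_id == "gappy", ]
  expect_identical(r3$status, "included")
  expect_match(r3$reason, "imputed")
  rows <- pm3$conditions$condition == "cyan|star|residual"
  expect_equal(var(pm3$values[rows, "gappy"]), 0)
})

test_that("pseudotrial condition means converge to the true trial means", {
  tr <- std_trials()
  sp <- std_spikes()
  z <- zscore_within_neuron(sp)
  one <- "n010"
  cond_trials <- tr$trial_index[std_states() != "residual" &
                                  tr$chosen_color == "cyan" &
                                  tr$chosen_shape == "circle"]
  truth <- mean(z$z[z$neuron_id == one & z$trial_index %in% cond_trials])
  means <- vapply(1:60, function(s) {
    pm <- build_pseudotrials(sp, tr, std_states(),
                             scheme = "rule_vs_residual", seed = 100 + s)
    mean(pm$values[pm$conditions$condition == "cyan|circle|rule_based", one])
  }, numeric(1))
  expect_lt(abs(mean(means) - truth), 0.1)
})

test_that("split halves share no trials and reproduce under a seed", {
  sh1 <- split_half_pseudotrials(std_spikes(), std_trials(), std_states(),
                                 seed = 84, n_per_condition = 10)
  sh2 <- split_half_pseudotrials(std_spikes(), std_trials(), std_states(),
                                 seed = 84, n_per_condition = 10)
  expect_identical(sh1$A$values, sh2$A$values)
  expect_identical(sh1$B$values, sh2$B$values)
  expect_identical(sh1$A$roster$status, sh1$B$roster$status)

  # disjointness of the underlying trial pools, made observable by a tracer
  # neuron whose response is unique to each trial
  tr <- std_trials()
  tracer <- tibble::tibble(
    neuron_id = "tracer", region = "OFC", session_id = tr$session_id,
    trial_index = tr$trial_index, spike_count = 100L + tr$trial_index
  )
  sh <- split_half_pseudotrials(tracer, tr, std_states(),
                                seed = 87, n_per_condition = 15)
  conds <- unique(sh$A$conditions$condition)
  shared <- vapply(conds, function(cn) {
    a <- unique(sh$A$values[sh$A$conditions$condition == cn, "tracer"])
    b <- unique(sh$B$values[sh$B$conditions$condition == cn, "tracer"])
    # singleton conditions fall back to the imputed mean in one half
    if (length(a) == 1 || length(b) == 1) 0L else length(intersect(a, b))
  }, integer(1))
  expect_true(all(shared == 0))
})

test_that("bootstrap machinery returns calibrated intervals", {
  tr <- std_trials()
  sp <- std_spikes()
  # degenerate statistic: exact zero every rebuild
  bz <- bootstrap_pseudopopulations(sp, tr, std_states(),
                                    statistic = function(pm) 0,
                                    n_boot = 10, seed = 85,
                                    n_per_condition = 5)
  expect_equal(diff(bz$ci), 0)
  expect_equal(bz$p, 1)

  # a real effect: mean rule-based minus residual value of a tuned neuron
  stat <- function(pm) {
    rb <- pm$conditions$type == "rule_based"
    mean(pm$values[rb, ]) - mean(pm$values[!rb, ])
  }
  bt <- bootstrap_pseudopopulations(sp, tr, std_states(), statistic = stat,
                                    n_boot = 40, seed = 86,
                                    n_per_condition = 10)
  expect_true(bt$ci[1] <= bt$mean && bt$mean <= bt$ci[2])
  expect_length(bt$distribution, 40)
})
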