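#' Condition schemes for pseudotrial matrices
#'
#' Three ways of defining the condition ("state") axis of a pseudotrial
#' matrix, differing only in how much rule information they keep:
#' `"rule_vs_residual"` crosses the 9 choice identities with rule-based
#' versus residual (rules pooled; 18 conditions); `"color_vs_shape_rule"`
#' crosses choice identity with the rule domain (18 conditions, rule trials
#' only); `"per_rule"` crosses choice identity with the specific state (each
#' rule admits only its 3 matching identities, plus 9 residual conditions:
#' 27 in all).
#'
#' @param scheme Scheme name.
#' @return A tibble of conditions: `condition`, `chosen_color`,
#'   `chosen_shape`, `type`.
#' @export
scheme_conditions <- function(scheme = c("rule_vs_residual",
                                         "color_vs_shape_rule",
                                         "per_rule")) {
  scheme <- match.arg(scheme)
  ids <- tidyr::expand_grid(chosen_color = .colors, chosen_shape = .shapes)
  conds <- switch(
    scheme,
    rule_vs_residual = tidyr::expand_grid(
      ids, type = c("rule_based", "residual")),
    color_vs_shape_rule = tidyr::expand_grid(
      ids, type = c("color_rule", "shape_rule")),
    per_rule = dplyr::bind_rows(
      purrr::map_dfr(.features, function(f) {
        dplyr::filter(ids, .data$chosen_color == f | .data$chosen_shape == f) |>
          dplyr::mutate(type = f)
      }),
      dplyr::mutate(ids, type = "residual")
    )
  )
  conds |>
    dplyr::mutate(condition = paste(.data$chosen_color, .data$chosen_shape,
                                    .data$type, sep = "|")) |>
    dplyr::relocate("condition")
}

# per-trial condition label under a scheme, NA when the trial does not enter
.trial_conditions <- function(trials, state_labels, scheme) {
  type <- switch(
    scheme,
    rule_vs_residual = ifelse(state_labels == "residual",
                              "residual", "rule_based"),
    color_vs_shape_rule = ifelse(
      state_labels == "residual", NA_character_,
      paste0(feature_domain(replace(state_labels,
                                    state_labels == "residual",
                                    .features[1])), "_rule")),
    per_rule = state_labels
  )
  ifelse(is.na(type), NA_character_,
         paste(trials$chosen_color, trials$chosen_shape, type, sep = "|"))
}

#' Build a pseudotrial matrix
#'
#' Assembles separately recorded neurons into a pseudopopulation: within each
#' condition of the chosen scheme, each neuron's z-scored firing rates are
#' sampled with replacement (independently across neurons) to form
#' `n_per_condition` pseudotrial vectors per condition. Neurons with a mean
#' firing rate below `min_rate` spikes/s are excluded; neurons missing
#' 1 to `impute_max` conditions have their mean (z-scored) rate imputed for
#' those conditions; neurons missing more conditions are excluded. The
#' roster records every exclusion and imputation.
#'
#' @param spikes A spikes tibble.
#' @param trials The matching trials tibble.
#' @param state_labels Per-trial state labels.
#' @param scheme Condition scheme (see [scheme_conditions()]).
#' @param n_per_condition Pseudotrials per condition.
#' @param seed Optional seed; (seed, inputs) fully determine the matrix.
#' @param min_rate Exclusion threshold in spikes/s (full epoch, all trials).
#' @param impute_max Largest number of missing conditions that is imputed
#'   rather than excluded.
#' @return An object of class `pseudotrial_matrix`: `values` (rows =
#'   condition x pseudotrial, columns = retained neurons), `conditions`
#'   (row-aligned tibble), `roster`, `scheme`.
#' @export
build_pseudotrials <- function(spikes, trials, state_labels,
                               scheme = "rule_vs_residual",
                               n_per_condition = 20L, seed = NULL,
                               min_rate = 2, impute_max = 4L) {
  scheme <- match.arg(scheme, c("rule_vs_residual", "color_vs_shape_rule",
                                "per_rule"))
  if (!is.null(seed)) set.seed(seed)
  conds <- scheme_conditions(scheme)
  z <- zscore_within_neuron(spikes)
  lab <- tibble::tibble(
    trial_index = trials$trial_index,
    condition = .trial_conditions(trials, state_labels, scheme)
  )
  df <- dplyr::inner_join(z, lab, by = "trial_index") |>
    dplyr::filter(!is.na(.data$condition))

  .assemble_pseudotrials(df, conds, n_per_condition, scheme,
                         min_rate, impute_max)
}

# core sampler shared by build_pseudotrials and split_half_pseudotrials;
# df carries neuron_id, region, rate, z, condition
.assemble_pseudotrials <- function(df, conds, n_per_condition, scheme,
                                   min_rate, impute_max,
                                   roster_fixed = NULL) {
  n_cond <- nrow(conds)
  stats <- df |>
    dplyr::group_by(.data$neuron_id, .data$region) |>
    dplyr::summarise(
      mean_rate = mean(.data$rate),
      mean_z = mean(.data$z),
      n_missing = n_cond - dplyr::n_distinct(.data$condition),
      .groups = "drop"
    )
  if (is.null(roster_fixed)) {
    roster <- stats |>
      dplyr::mutate(
        status = dplyr::case_when(
          .data$mean_rate < min_rate ~ "excluded",
          .data$n_missing > impute_max ~ "excluded",
          TRUE ~ "included"),
        reason = dplyr::case_when(
          .data$mean_rate < min_rate ~ paste0("rate<", min_rate),
          .data$n_missing > impute_max ~
            paste0(.data$n_missing, " missing conditions"),
          .data$n_missing > 0 ~ paste0(.data$n_missing, " imputed"),
          TRUE ~ "")
      )
  } else {
    roster <- dplyr::left_join(
      dplyr::select(roster_fixed, "neuron_id", "region", "status", "reason"),
      dplyr::select(stats, "neuron_id", "mean_rate", "mean_z", "n_missing"),
      by = "neuron_id")
  }
  kept <- roster$neuron_id[roster$status == "included"]
  if (!length(kept)) stop("no neurons survive the exclusion rules")

  # hard error when a condition is missing for most retained neurons
  # (skipped for half-splits, where singleton conditions impute by design)
  if (is.null(roster_fixed)) {
  miss_by_cond <- df |>
    dplyr::filter(.data$neuron_id %in% kept) |>
    dplyr::distinct(.data$neuron_id, .data$condition) |>
    dplyr::count(.data$condition, name = "n_present")
  present <- setNames(rep(0L, n_cond), conds$condition)
  present[miss_by_cond$condition] <- miss_by_cond$n_present
  bad <- names(present)[present < length(kept) / 2]
  if (length(bad)) {
    stop("condition(s) missing for more than half the neurons: ",
         paste(bad, collapse = ", "))
  }
  }

  mean_z <- setNames(roster$mean_z, roster$neuron_id)
  values <- matrix(NA_real_, n_cond * n_per_condition, length(kept),
                   dimnames = list(NULL, kept))
  grouped <- split(df[df$neuron_id %in% kept, c("neuron_id", "z")],
                   df$condition[df$neuron_id %in% kept])
  for (ci in seq_len(n_cond)) {
    cname <- conds$condition[ci]
    rows <- (ci - 1L) * n_per_condition + seq_len(n_per_condition)
    g <- grouped[[cname]]
    pools <- if (is.null(g)) list() else split(g$z, g$neuron_id)
    for (nid in kept) {
      pool <- pools[[nid]]
      values[rows, nid] <- if (is.null(pool) || !length(pool)) {
        mean_z[[nid]]  # imputation: the neuron's mean normalized rate
      } else {
        sample(pool, n_per_condition, replace = TRUE)
      }
    }
  }
  conditions <- conds[rep(seq_len(n_cond), each = n_per_condition), ]
  conditions$pseudotrial <- rep(seq_len(n_per_condition), n_cond)
  structure(
    list(values = values, conditions = conditions, roster = roster,
         scheme = scheme, n_per_condition = n_per_condition),
    class = "pseudotrial_matrix"
  )
}

#' Split-half pseudotrial matrices for cross-validated distances
#'
#' Partitions each neuron's trials within each condition at random into two
#' equal subsets (each condition represented at least once per subset where
#' possible) and builds a pseudotrial matrix from each, so that distances
#' computed between matrix A and matrix B share no trials. The neuron roster
#' is determined once from the full data so both halves align.
#'
#' @inheritParams build_pseudotrials
#' @return A list with elements `A` and `B` (two `pseudotrial_matrix`
#'   objects with identical rosters and condition layouts).
#' @export
split_half_pseudotrials <- function(spikes, trials, state_labels,
                                    scheme = "rule_vs_residual",
                                    n_per_condition = 20L, seed = NULL,
                                    min_rate = 2, impute_max = 4L) {
  scheme <- match.arg(scheme, c("rule_vs_residual", "color_vs_shape_rule",
                                "per_rule"))
  if (!is.null(seed)) set.seed(seed)
  conds <- scheme_conditions(scheme)
  z <- zscore_within_neuron(spikes)
  lab <- tibble::tibble(
    trial_index = trials$trial_index,
    condition = .trial_conditions(trials, state_labels, scheme)
  )
  df <- dplyr::inner_join(z, lab, by = "trial_index") |>
    dplyr::filter(!is.na(.data$condition))

  full <- .assemble_pseudotrials(df, conds, n_per_condition, scheme,
                                 min_rate, impute_max)
  # random half-split within neuron x condition; singletons stay in one half
  # and the other half falls back to imputation
  df <- df |>
    dplyr::group_by(.data$neuron_id, .data$condition) |>
    dplyr::mutate(half = {
      n <- dplyr::n()
      sample(rep(c("A", "B"), length.out = n))
    }) |>
    dplyr::ungroup()
  halves <- purrr::map(c("A", "B"), function(h) {
    .assemble_pseudotrials(dplyr::filter(df, .data$half == h), conds,
                           n_per_condition, scheme, min_rate, impute_max,
                           roster_fixed = full$roster)
  })
  names(halves) <- c("A", "B")
  halves
}

#' Bootstrap a statistic over re-seeded pseudopopulations
#'
#' Rebuilds the pseudotrial matrix under `n_boot` derived seeds and applies
#' a statistic to each, returning the bootstrap distribution, percentile
#' confidence interval, and a two-sided sign-crossing p-value (doubled tail
#' fraction, floored at `1/n_boot`).
#'
#' @inheritParams build_pseudotrials
#' @param statistic Function of a `pseudotrial_matrix` returning one number
#'   (for paired contrasts, compute the difference inside).
#' @param n_boot Number of rebuilds.
#' @param conf Confidence level of the percentile interval.
#' @param ... Passed on to [build_pseudotrials()].
#' @return A list: `distribution`, `mean`, `ci` (length 2), `p`, `n_boot`.
#' @export
bootstrap_pseudopopulations <- function(spikes, trials, state_labels,
                                        scheme = "rule_vs_residual",
                                        statistic, n_boot = 200L,
                                        seed = 1L, conf = 0.95, ...) {
  stopifnot(is.function(statistic), n_boot >= 2)
  stat <- vapply(seq_len(n_boot), function(b) {
    pm <- build_pseudotrials(spikes, trials, state_labels, scheme = scheme,
                             seed = seed + b, ...)
    out <- statistic(pm)
    if (!is.numeric(out) || length(out) != 1L || !is.finite(out)) {
      stop("statistic failed on bootstrap rebuild with seed ", seed + b)
    }
    out
  }, numeric(1))
  alpha <- 1 - conf
  p <- 2 * min(mean(stat <= 0), mean(stat >= 0))
  list(
    distribution = stat,
    mean = mean(stat),
    ci = unname(quantile(stat, c(alpha / 2, 1 - alpha / 2))),
    p = min(1, max(p, 1 / n_boot)),
    n_boot = n_boot
  )
}
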