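#' Within-neuron normalization of firing rates
#'
#' Converts spike counts to rates and normalizes within each neuron. All
#' analyses use z-scored rates except direct comparisons of total firing
#' rate, which center but do not scale. Zero-variance neurons cannot be
#' scaled and are centered only, with a message.
#'
#' @param spikes A spikes tibble (`neuron_id`, `spike_count`).
#' @param mode `"zscore"` or `"center"`.
#' @param epoch_duration Epoch length in seconds (taken from the table
#'   attribute when present).
#' @return `spikes` with added columns `rate` (spikes/s) and `z`.
#' @export
zscore_within_neuron <- function(spikes, mode = c("zscore", "center"),
                                 epoch_duration = NULL) {
  mode <- match.arg(mode)
  if (is.null(epoch_duration)) {
    epoch_duration <- attr(spikes, "epoch_duration") %||% 3.35
  }
  out <- spikes |>
    dplyr::mutate(rate = .data$spike_count / epoch_duration) |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::mutate(
      z = {
        s <- sd(.data$rate)
        centered <- .data$rate - mean(.data$rate)
        if (mode == "center" || !is.finite(s) || s == 0) centered
        else centered / s
      }
    ) |>
    dplyr::ungroup()
  if (mode == "zscore") {
    flat <- out |>
      dplyr::group_by(.data$neuron_id) |>
      dplyr::summarise(flat = sd(.data$rate) == 0, .groups = "drop")
    if (any(flat$flat)) {
      message(sum(flat$flat),
              " zero-variance neuron(s) centered without scaling")
    }
  }
  for (a in c("epoch_duration", "tuning_truth", "tuning_spec")) {
    attr(out, a) <- attr(spikes, a)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation test for a rate difference between trial classes
#'
#' Two-sided permutation test of the mean difference (rule-based minus
#' residual) against the null obtained by shuffling the class labels.
#'
#' @param x Numeric responses (counts, rates, or centered rates), one per
#'   trial.
#' @param rule_based Logical class labels.
#' @param n_perm Number of label shuffles.
#' @param seed Optional seed.
#' @param exact Enumerate all label assignments instead of sampling (only
#'   sensible for small trial counts).
#' @return A one-row tibble: `difference`, `p`, `n_perm`.
#' @export
rate_contrast_permutation <- function(x, rule_based, n_perm = 1000L,
                                      seed = NULL, exact = FALSE) {
  stopifnot(length(x) == length(rule_based), is.logical(rule_based))
  n1 <- sum(rule_based)
  n0 <- sum(!rule_based)
  if (n1 < 2 || n0 < 2) stop("each class needs at least 2 trials")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  total <- sum(x)
  obs <- mean(x[rule_based]) - mean(x[!rule_based])
  diff_from_sum1 <- function(s1) s1 / n1 - (total - s1) / n0

  if (exact) {
    sets <- combn(n, n1)
    perm <- diff_from_sum1(colSums(matrix(x[sets], nrow = n1)))
    p <- mean(abs(perm) >= abs(obs) - 1e-12)
    n_perm <- ncol(sets)
  } else {
    perm <- vapply(seq_len(n_perm), function(i) {
      diff_from_sum1(sum(x[sample.int(n, n1)]))
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  }
  tibble::tibble(difference = obs, p = p, n_perm = n_perm)
}

# one-way ANOVA p-value (and F), NA when not testable
.oneway_p <- function(y, g, min_per_level = 2L) {
  g <- factor(g)
  if (nlevels(g) < 2 || any(table(g) < min_per_level)) {
    return(c(F = NA_real_, p = NA_real_))
  }
  a <- anova(lm(y ~ g))
  c(F = a$`F value`[1], p = a$`Pr(>F)`[1])
}

#' Per-neuron tuning ANOVAs and population proportions
#'
#' One-way ANOVAs within each neuron for three factors: rule use (rule-based
#' versus residual), rule identity (the six rules, residual trials
#' excluded), and choice identity (the nine color-shape combinations). For
#' each region and factor, the proportion of neurons significant at
#' `alpha` is compared against the nominal false-positive rate with a
#' one-sided binomial test.
#'
#' @param spikes A spikes tibble.
#' @param trials The matching trials tibble.
#' @param state_labels Per-trial state labels (e.g. Viterbi path).
#' @param alpha Per-neuron significance threshold.
#' @return A list: `neurons` (neuron x factor p-values) and `summary`
#'   (region x factor proportions with binomial p).
#' @export
tuning_anova_suite <- function(spikes, trials, state_labels, alpha = 0.05) {
  stopifnot(length(state_labels) == nrow(trials))
  info <- tibble::tibble(
    trial_index = trials$trial_index,
    state = state_labels,
    rule_based = state_labels != "residual",
    identity = paste(trials$chosen_color, trials$chosen_shape, sep = "-")
  )
  df <- dplyr::inner_join(spikes, info, by = "trial_index")

  neurons <- df |>
    dplyr::group_by(.data$region, .data$neuron_id) |>
    dplyr::group_modify(function(d, key) {
      rule_use <- .oneway_p(d$spike_count, d$rule_based)
      rid <- d[d$rule_based, ]
      rule_identity <- .oneway_p(rid$spike_count, rid$state)
      choice_identity <- .oneway_p(d$spike_count, d$identity)
      tibble::tibble(
        factor = c("rule_use", "rule_identity", "choice_identity"),
        F = c(rule_use["F"], rule_identity["F"], choice_identity["F"]),
        p = c(rule_use["p"], rule_identity["p"], choice_identity["p"])
      )
    }) |>
    dplyr::ungroup()

  skipped <- sum(is.na(neurons$p))
  if (skipped > 0) {
    message(skipped, " neuron-factor test(s) skipped for missing levels")
  }

  summary <- neurons |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(.data$region, .data$factor) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_sig = sum(.data$p < alpha),
      proportion = .data$n_sig / .data$n,
      p_binomial = binom.test(.data$n_sig, .data$n, alpha,
                              alternative = "greater")$p.value,
      .groups = "drop"
    )
  list(neurons = neurons, summary = summary)
}

#' Gini index of population sparsity
#'
#' For a vector of non-negative responses (one per neuron), computes
#' `1 - 2 * sum_k (x_k / ||x||_1) * (N - k + 1/2) / N` over the ascending
#' sort. The index is invariant to scale and permutation and grows toward
#' `1 - 1/N` as spikes concentrate in fewer neurons; a perfectly uniform
#' vector evaluates to 0 under this form (one minus twice the area under the
#' Lorenz curve).
#'
#' @param x Non-negative numeric vector with at least one positive entry.
#' @return The Gini index.
#' @examples
#' gini_index(c(0, 0, 0, 1))  # 0.75
#' @export
gini_index <- function(x) {
  if (any(is.na(x)) || any(x < 0)) {
    stop("x must be non-negative with no missing values")
  }
  if (sum(x) == 0) {
    stop("Gini index is undefined for an all-zero vector")
  }
  x <- sort(x)
  N <- length(x)
  1 - 2 * sum(x / sum(x) * (N - seq_len(N) + 0.5) / N)
}

# plug-in mutual information (bits) from a joint contingency table
.mi_plugin <- function(tab) {
  p <- tab / sum(tab)
  pr <- rowSums(p)
  pc <- colSums(p)
  idx <- p > 0
  e <- outer(pr, pc)
  sum(p[idx] * log2(p[idx] / e[idx]))
}

# quantile binning with randomized tie-breaking so sparse counts split as
# evenly as possible
.quantile_bin <- function(x, n_bins) {
  r <- rank(x, ties.method = "random")
  as.integer(ceiling(r * n_bins / length(x)))
}

#' Mutual information between a neuron's firing and choice identity
#'
#' Plug-in mutual information (bits/trial) between quantile-binned spike
#' counts and choice identity, computed separately for rule-based and
#' residual trials. Rule-based trials are downsampled at random to the
#' residual trial count to equate the limited-sampling bias; a shuffle floor
#' (mean MI after shuffling identity labels) is reported alongside, and
#' information per spike divides the MI by the mean spike count within the
#' choice type.
#'
#' @param count Spike counts, one per trial.
#' @param identity Choice identity labels (typically 9 levels).
#' @param rule_based Logical per-trial class.
#' @param n_bins Firing-rate bins (default 2, so the minimum probability-cell
#'   count of the rule/residual contrast is 2 types x 9 identities x 2 bins
#'   = 36).
#' @param n_shuffle Label shuffles for the floor.
#' @param seed Optional seed (downsampling, tie-breaking, shuffles).
#' @return A tibble with one row per choice type: `n`, `mi`, `mi_shuffle`,
#'   `mean_count`, `bits_per_spike`.
#' @export
mutual_information <- function(count, identity, rule_based,
                               n_bins = 2L, n_shuffle = 100L, seed = NULL) {
  stopifnot(length(count) == length(identity),
            length(count) == length(rule_based))
  if (!is.null(seed)) set.seed(seed)
  n_res <- sum(!rule_based)
  keep <- !rule_based
  if (any(rule_based)) {
    rb <- which(rule_based)
    keep[sample(rb, min(n_res, length(rb)))] <- TRUE
  }
  count <- count[keep]
  identity <- identity[keep]
  rule_based <- rule_based[keep]

  bins <- .quantile_bin(count, n_bins)
  types <- list(rule_based = rule_based, residual = !rule_based)
  purrr::map_dfr(names(types), function(ty) {
    m <- types[[ty]]
    if (sum(m) < 2L * n_bins) {
      return(tibble::tibble(choice_type = ty, n = sum(m), mi = NA_real_,
                            mi_shuffle = NA_real_, mean_count = NA_real_,
                            bits_per_spike = NA_real_))
    }
    b <- bins[m]
    id <- identity[m]
    mi <- .mi_plugin(table(b, id))
    floor <- mean(vapply(seq_len(n_shuffle), function(i) {
      .mi_plugin(table(b, sample(id)))
    }, numeric(1)))
    mc <- mean(count[m])
    tibble::tibble(
      choice_type = ty, n = sum(m), mi = mi, mi_shuffle = floor,
      mean_count = mc,
      bits_per_spike = if (mc > 0) mi / mc else NA_real_
    )
  })
}

#' Mutual information across a population of neurons
#'
#' Maps [mutual_information()] over every neuron in a spikes table.
#'
#' @inheritParams tuning_anova_suite
#' @inheritParams mutual_information
#' @return A tibble with one row per neuron and choice type.
#' @export
neuron_information <- function(spikes, trials, state_labels, n_bins = 2L,
                               n_shuffle = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  info <- tibble::tibble(
    trial_index = trials$trial_index,
    rule_based = state_labels != "residual",
    identity = paste(trials$chosen_color, trials$chosen_shape, sep = "-")
  )
  dplyr::inner_join(spikes, info, by = "trial_index") |>
    dplyr::group_by(.data$region, .data$neuron_id) |>
    dplyr::group_modify(function(d, key) {
      mutual_information(d$spike_count, d$identity, d$rule_based,
                         n_bins = n_bins, n_shuffle = n_shuffle)
    }) |>
    dplyr::ungroup()
}

#' Identity versus category tuning index for one neuron
#'
#' Fits two models of trial responses: an identity model with a separate
#' mean for each of the nine color-shape combinations, and a category model
#' where color and shape contribute independently and additively. The index
#' is the ratio of the two overall ANOVA F statistics (`F_id / F_cat`);
#' values above 1 indicate tuning to specific conjunctions beyond what
#' additive category tuning explains.
#'
#' @param y Trial responses.
#' @param color,shape Chosen features per trial.
#' @return One-row tibble: `F_id`, `F_cat`, `index`.
#' @export
identity_category_index <- function(y, color, shape) {
  identity <- factor(paste(color, shape, sep = "-"))
  f_id <- summary(lm(y ~ identity))$fstatistic[["value"]]
  f_cat <- summary(lm(y ~ factor(color) + factor(shape)))$fstatistic[["value"]]
  tibble::tibble(F_id = f_id, F_cat = f_cat, index = f_id / f_cat)
}

#' Identity-category indices across neurons and choice types
#'
#' Computes [identity_category_index()] per neuron separately for rule-based
#' and residual trials (z-scored rates), skipping neurons that lack any of
#' the nine identities within a choice type, and runs a paired t-test of the
#' index across choice types within each region.
#'
#' @inheritParams tuning_anova_suite
#' @return A list: `neurons` (per neuron and type) and `contrast` (per
#'   region paired test, rule-based minus residual).
#' @export
identity_category_suite <- function(spikes, trials, state_labels) {
  info <- tibble::tibble(
    trial_index = trials$trial_index,
    rule_based = state_labels != "residual",
    color = trials$chosen_color,
    shape = trials$chosen_shape
  )
  df <- zscore_within_neuron(spikes) |>
    dplyr::inner_join(info, by = "trial_index")

  neurons <- df |>
    dplyr::group_by(.data$region, .data$neuron_id,
                    choice_type = ifelse(.data$rule_based,
                                         "rule_based", "residual")) |>
    dplyr::group_modify(function(d, key) {
      ids <- table(paste(d$color, d$shape, sep = "-"))
      if (length(ids) < 9 || any(ids < 2)) return(tibble::tibble())
      identity_category_index(d$z, d$color, d$shape)
    }) |>
    dplyr::ungroup()

  if (nrow(neurons) == 0 ||
      !all(c("rule_based", "residual") %in% neurons$choice_type)) {
    message("too few complete neurons for the identity-category contrast")
    return(list(neurons = neurons, contrast = tibble::tibble()))
  }
  paired <- neurons |>
    dplyr::select("region", "neuron_id", "choice_type", "index") |>
    tidyr::pivot_wider(names_from = "choice_type", values_from = "index") |>
    dplyr::filter(stats::complete.cases(dplyr::pick(dplyr::everything())))
  contrast <- paired |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rule_based = mean(.data$rule_based),
      mean_residual = mean(.data$residual),
      difference = mean(.data$rule_based - .data$residual),
      p = tryCatch(t.test(.data$rule_based, .data$residual,
                          paired = TRUE)$p.value,
                   error = function(e) NA_real_),
      .groups = "drop"
    )
  list(neurons = neurons, contrast = contrast)
}

#' Benjamini-Hochberg step-up false-discovery control
#'
#' @param p P-values.
#' @param q Family-wise FDR level.
#' @return A tibble: `p`, `p_adjusted`, `reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Rule-relevance modulation of single-neuron tuning
#'
#' Analyzes the three 400-ms presentation-epoch responses per trial.
#' Responses are z-scored within neurons, averaged within conditions, and
#' each neuron's features are ranked best (3) / intermediate (2) / worst (1)
#' per domain from all trials regardless of state. The condition means are
#' then modeled as `fr = b0 + b1 S + b2 R + b3 (S x R)` where `R` is 1 when
#' the feature's domain is relevant to the active rule; `b3` captures
#' sharpening of tuning under rule relevance. Tuning depth (best minus
#' worst) is also contrasted between relevance classes with paired t-tests.
#'
#' @param spikes A spikes tibble with `epoch1_count`..`epoch3_count`.
#' @param trials The matching trials tibble.
#' @param state_labels Per-trial state labels.
#' @param target Sort epoch responses by the `"stimulus"` presented in that
#'   epoch or by the `"choice"` ultimately made on the trial.
#' @return A list: `model` (coefficient tibble), `depths` (per neuron,
#'   domain and relevance class), `contrasts` (paired tests with BH
#'   adjustment).
#' @export
relevance_tuning_glm <- function(spikes, trials, state_labels,
                                 target = c("stimulus", "choice")) {
  target <- match.arg(target)
  if (!all(paste0("epoch", 1:3, "_count") %in% names(spikes))) {
    stop("spikes table lacks the three presentation-epoch count columns")
  }
  stopifnot(length(state_labels) == nrow(trials))

  rule_dom <- ifelse(state_labels == "residual", "residual",
                     feature_domain(replace(state_labels,
                                            state_labels == "residual",
                                            .features[1])))
  # feature shown in each presentation epoch
  ord <- cbind(trials$opt1_order, trials$opt2_order, trials$opt3_order)
  oc <- cbind(trials$opt1_color, trials$opt2_color, trials$opt3_color)
  os <- cbind(trials$opt1_shape, trials$opt2_shape, trials$opt3_shape)
  epoch_feats <- purrr::map(1:3, function(j) {
    slot <- apply(ord, 1, function(o) which(o == j))
    idx <- cbind(seq_len(nrow(trials)), slot)
    list(color = oc[idx], shape = os[idx])
  })
  tinfo <- tibble::tibble(
    trial_index = trials$trial_index,
    rule_domain = rule_dom,
    chosen_color = trials$chosen_color,
    chosen_shape = trials$chosen_shape,
    stim1_color = epoch_feats[[1]]$color, stim1_shape = epoch_feats[[1]]$shape,
    stim2_color = epoch_feats[[2]]$color, stim2_shape = epoch_feats[[2]]$shape,
    stim3_color = epoch_feats[[3]]$color, stim3_shape = epoch_feats[[3]]$shape
  )

  long <- dplyr::inner_join(spikes, tinfo, by = "trial_index") |>
    tidyr::pivot_longer(dplyr::matches("^epoch[123]_count$"),
                        names_to = "epoch", values_to = "count") |>
    dplyr::mutate(epoch = as.integer(sub("epoch(\\d)_count", "\\1",
                                         .data$epoch)))
  if (target == "stimulus") {
    long <- long |> dplyr::mutate(
      feat_color = dplyr::case_when(
        .data$epoch == 1 ~ .data$stim1_color,
        .data$epoch == 2 ~ .data$stim2_color,
        TRUE ~ .data$stim3_color),
      feat_shape = dplyr::case_when(
        .data$epoch == 1 ~ .data$stim1_shape,
        .data$epoch == 2 ~ .data$stim2_shape,
        TRUE ~ .data$stim3_shape)
    )
  } else {
    long <- long |> dplyr::mutate(feat_color = .data$chosen_color,
                                  feat_shape = .data$chosen_shape)
  }
  long <- long |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::mutate(z = {
      s <- sd(.data$count)
      if (is.finite(s) && s > 0) (.data$count - mean(.data$count)) / s
      else .data$count - mean(.data$count)
    }) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(c("feat_color", "feat_shape"),
                        names_to = "domain", values_to = "feature") |>
    dplyr::mutate(domain = sub("feat_", "", .data$domain))

  # best/intermediate/worst per neuron and domain, from all trials
  ranks <- long |>
    dplyr::group_by(.data$neuron_id, .data$domain, .data$feature) |>
    dplyr::summarise(m = mean(.data$z), .groups = "drop_last") |>
    dplyr::arrange(.data$m, match(.data$feature, rev(.features)),
                   .by_group = TRUE) |>
    dplyr::mutate(S = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("neuron_id", "domain", "feature", "S")

  cond <- long |>
    dplyr::mutate(relevance = dplyr::case_when(
      .data$rule_domain == "residual" ~ "residual",
      .data$rule_domain == .data$domain ~ "relevant",
      TRUE ~ "irrelevant")) |>
    dplyr::group_by(.data$neuron_id, .data$region, .data$domain,
                    .data$feature, .data$relevance) |>
    dplyr::summarise(fr = mean(.data$z), .groups = "drop") |>
    dplyr::left_join(ranks, by = c("neuron_id", "domain", "feature"))

  rule_rows <- cond |>
    dplyr::filter(.data$relevance != "residual") |>
    dplyr::mutate(R = as.integer(.data$relevance == "relevant"))
  fit <- lm(fr ~ S * R, data = rule_rows)
  sm <- summary(fit)$coefficients
  model <- tibble::tibble(
    term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
    statistic = sm[, 3], p = sm[, 4]
  )

  depths <- cond |>
    dplyr::group_by(.data$neuron_id, .data$region, .data$domain,
                    .data$relevance) |>
    dplyr::summarise(
      depth = .data$fr[which.max(.data$S)] - .data$fr[which.min(.data$S)],
      .groups = "drop"
    )
  wide <- depths |>
    tidyr::pivot_wider(names_from = "relevance", values_from = "depth")
  pair_test <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) return(tibble::tibble(difference = NA_real_,
                                           t = NA_real_, p = NA_real_,
                                           n = sum(ok)))
    tt <- t.test(a[ok], b[ok], paired = TRUE)
    tibble::tibble(difference = unname(tt$estimate), t = unname(tt$statistic),
                   p = tt$p.value, n = sum(ok))
  }
  contrasts <- dplyr::bind_rows(
    dplyr::mutate(pair_test(wide$relevant, wide$irrelevant),
                  contrast = "relevant_vs_irrelevant"),
    dplyr::mutate(pair_test(wide$relevant, wide$residual),
                  contrast = "relevant_vs_residual"),
    dplyr::mutate(pair_test(wide$irrelevant, wide$residual),
                  contrast = "irrelevant_vs_residual")
  ) |>
    dplyr::relocate("contrast")
  contrasts$p_adjusted <- p.adjust(contrasts$p, method = "BH")

  list(model = model, depths = depths, contrasts = contrasts)
}
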