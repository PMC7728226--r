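#' Ridge penalty grid for the coding-dimension classifiers
#'
#' Twenty-five penalty values: zero plus 24 log-spaced values spanning
#' `[1e-4, 1e4]` (a literal log-spacing cannot include zero).
#'
#' @return Numeric vector, ascending.
#' @export
default_lambda_grid <- function() {
  c(0, 10^seq(-4, 4, length.out = 24))
}

# stratified fold ids: rows of each stratum are spread over folds so every
# class appears in every fold whenever counts allow
.stratified_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    rows <- which(strata == s)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

# one-vs-rest ridge logistic bank over a pseudotrial matrix
.fit_ovr <- function(x, labels_list, strata, cv_folds, lambda,
                     per_class_lambda, seed) {
  if (!is.null(seed)) set.seed(seed)
  lambda <- sort(lambda, decreasing = TRUE)  # glmnet wants a decreasing path
  k <- cv_folds
  fold <- .stratified_folds(strata, k)
  feats <- names(labels_list)
  for (f in feats) {
    per_fold <- table(factor(labels_list[[f]], c(FALSE, TRUE)), fold)
    if (any(per_fold == 0)) {
      stop("class '", f, "' absent from a cross-validation fold even after ",
           "stratification; reduce cv_folds")
    }
  }

  acc <- array(NA_real_, c(length(lambda), length(feats), k),
               dimnames = list(NULL, feats, NULL))
  for (fd in seq_len(k)) {
    tr <- fold != fd
    for (f in feats) {
      y <- labels_list[[f]]
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], factor(y[tr]),
                            family = "binomial", alpha = 0,
                            lambda = lambda, standardize = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE], s = lambda,
                      type = "class")
      acc[, f, fd] <- colMeans(pred == as.character(y[!tr]))
    }
  }
  mean_acc <- apply(acc, c(1, 2), mean)

  pick <- function(a) {
    best <- max(a)
    min(lambda[a >= best - 1e-12])  # smallest penalty attaining the max
  }
  chosen <- if (per_class_lambda) {
    apply(mean_acc, 2, pick)
  } else {
    setNames(rep(pick(rowMeans(mean_acc)), length(feats)), feats)
  }

  beta <- matrix(0, ncol(x), length(feats),
                 dimnames = list(colnames(x), feats))
  intercept <- setNames(numeric(length(feats)), feats)
  for (f in feats) {
    fit <- glmnet::glmnet(x, factor(labels_list[[f]]), family = "binomial",
                          alpha = 0, lambda = lambda, standardize = FALSE)
    cf <- as.matrix(coef(fit, s = chosen[[f]]))
    intercept[f] <- cf[1, 1]
    beta[, f] <- cf[-1, 1]
  }
  n_lambda <- length(lambda)
  cv_tbl <- tibble::tibble(
    lambda = rep(lambda, length(feats)),
    feature = rep(feats, each = n_lambda),
    accuracy = as.vector(mean_acc)
  )
  list(beta = beta, intercept = intercept, lambda = chosen,
       cv_accuracy = cv_tbl,
       accuracy_at_chosen = vapply(feats, function(f) {
         mean_acc[match(chosen[[f]], lambda), f]
       }, numeric(1)))
}

#' Fit the choice-predictive classifier bank
#'
#' Targeted dimensionality reduction: six one-vs-rest ridge logistic
#' classifiers (one per feature: 3 colors + 3 shapes) fit to a per-rule
#' pseudotrial matrix whose rows span color rules, shape rules, and residual
#' states, so the choice axes marginalize over goals. The penalty is chosen
#' as the smallest grid value attaining maximal stratified cross-validated
#' accuracy (shared across the bank by default), then each classifier is
#' refit on all rows. Each coefficient vector is the normal of a separating
#' hyperplane; position along it is the log odds of that choice.
#'
#' @param pm A `pseudotrial_matrix` (the `"per_rule"` scheme).
#' @param cv_folds Number of stratified folds.
#' @param lambda Penalty grid (see [default_lambda_grid()]).
#' @param per_class_lambda Select the penalty per classifier instead of
#'   jointly.
#' @param seed Optional seed for fold assignment.
#' @return An object of class `coding_dimensions`: `beta` (neurons x 6),
#'   `intercept`, `lambda`, `cv_accuracy`, `accuracy_at_chosen`, `neurons`,
#'   `target` (`"choice"`).
#' @export
fit_choice_classifiers <- function(pm, cv_folds = 20L,
                                   lambda = default_lambda_grid(),
                                   per_class_lambda = FALSE, seed = NULL) {
  stopifnot(inherits(pm, "pseudotrial_matrix"))
  cond <- pm$conditions
  labels_list <- c(
    purrr::map(setNames(.colors, .colors),
               function(f) cond$chosen_color == f),
    purrr::map(setNames(.shapes, .shapes),
               function(f) cond$chosen_shape == f)
  )
  fit <- .fit_ovr(pm$values, labels_list, cond$condition, cv_folds, lambda,
                  per_class_lambda, seed)
  structure(c(fit, list(neurons = colnames(pm$values), target = "choice")),
            class = "coding_dimensions")
}

#' Fit the rule-identity classifier bank
#'
#' Same protocol as [fit_choice_classifiers()], but trained on rule-based
#' rows only and predicting the identity of the active rule rather than the
#' features of the choice.
#'
#' @inheritParams fit_choice_classifiers
#' @param rule_rows_only Restrict training to rule-based rows (default).
#' @return A `coding_dimensions` object with `target = "rule"`.
#' @export
fit_rule_classifiers <- function(pm, cv_folds = 20L,
                                 lambda = default_lambda_grid(),
                                 per_class_lambda = FALSE, seed = NULL,
                                 rule_rows_only = TRUE) {
  stopifnot(inherits(pm, "pseudotrial_matrix"))
  keep <- if (rule_rows_only) pm$conditions$type != "residual" else
    rep(TRUE, nrow(pm$conditions))
  cond <- pm$conditions[keep, ]
  if (!all(.features %in% cond$type)) {
    stop("rule classifier training rows must include every rule state")
  }
  labels_list <- purrr::map(setNames(.features, .features),
                            function(f) cond$type == f)
  fit <- .fit_ovr(pm$values[keep, , drop = FALSE], labels_list,
                  cond$condition, cv_folds, lambda, per_class_lambda, seed)
  structure(c(fit, list(neurons = colnames(pm$values), target = "rule")),
            class = "coding_dimensions")
}

#' Project pseudotrials onto the coding dimensions
#'
#' Each pseudotrial is re-represented by its positions along the six
#' coding dimensions (`x . beta_i + intercept_i`, the log odds of choice i).
#' Projections are tagged by whether their feature dimension matches the
#' chosen feature of that pseudotrial, and by rule relevance: under a rule,
#' the dimension whose domain matches the rule's domain is rule-relevant and
#' the other domain rule-irrelevant; residual rows carry the residual tag.
#'
#' @param pm A `pseudotrial_matrix`.
#' @param dims A `coding_dimensions` object fit on the same neuron roster.
#' @return A tibble of class `projection_table`, one row per pseudotrial and
#'   dimension.
#' @export
project_pseudotrials <- function(pm, dims) {
  stopifnot(inherits(pm, "pseudotrial_matrix"),
            inherits(dims, "coding_dimensions"))
  missing <- setdiff(dims$neurons, colnames(pm$values))
  extra <- setdiff(colnames(pm$values), dims$neurons)
  if (length(missing) || length(extra)) {
    stop("neuron roster mismatch; missing: ",
         paste(missing, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "))
  }
  proj <- pm$values[, dims$neurons, drop = FALSE] %*% dims$beta
  proj <- sweep(proj, 2, dims$intercept, `+`)
  cond <- pm$conditions
  out <- tidyr::expand_grid(
    row = seq_len(nrow(proj)),
    dimension = colnames(proj)
  ) |>
    dplyr::mutate(
      condition = cond$condition[.data$row],
      state = cond$type[.data$row],
      chosen_color = cond$chosen_color[.data$row],
      chosen_shape = cond$chosen_shape[.data$row],
      domain = feature_domain(.data$dimension),
      projection = proj[cbind(.data$row, match(.data$dimension,
                                               colnames(proj)))],
      chosen = .data$dimension == .data$chosen_color |
        .data$dimension == .data$chosen_shape,
      relevance = dplyr::case_when(
        .data$state == "residual" ~ "residual",
        feature_domain(replace(.data$state, .data$state == "residual",
                               .features[1])) == .data$domain ~
          "rule_relevant",
        TRUE ~ "rule_irrelevant"
      )
    )
  class(out) <- c("projection_table", class(out))
  out
}

#' Angle between two coding dimensions
#'
#' Arc-cosine of the normalized inner product of the coefficient vectors
#' (intercepts excluded), in degrees.
#'
#' @param v1,v2 Nonzero numeric vectors of equal length.
#' @return Angle in `[0, 180]` degrees.
#' @export
dimension_angle <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no direction")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Angles between rule axes and the matching choice axes
#'
#' @param choice_dims,rule_dims `coding_dimensions` banks over the same
#'   roster.
#' @return A tibble with one row per feature plus the mean angle as
#'   attribute `mean_angle`.
#' @export
rule_choice_angles <- function(choice_dims, rule_dims) {
  stopifnot(identical(choice_dims$neurons, rule_dims$neurons))
  out <- tibble::tibble(
    feature = .features,
    angle = vapply(.features, function(f) {
      dimension_angle(choice_dims$beta[, f], rule_dims$beta[, f])
    }, numeric(1))
  )
  attr(out, "mean_angle") <- mean(out$angle)
  out
}

#' ANOVA of chosen-feature projections by goal state
#'
#' Tests whether position along the chosen features' coding dimensions
#' depends on the goal: a main effect of residual versus rule-based
#' pseudotrials, and, nested within rule-based, whether the dimension was
#' relevant or irrelevant to the active rule. Pairwise two-sample t
#' contrasts between the three classes are BH-adjusted.
#'
#' @param proj A `projection_table` from [project_pseudotrials()].
#' @return A list: `anova` (term table), `means` (per class), `contrasts`.
#' @export
projection_anova <- function(proj) {
  dat <- dplyr::filter(proj, .data$chosen)
  if (!nrow(dat)) stop("no chosen-feature projections to analyze")
  counts <- table(dat$relevance)
  if (any(!c("residual", "rule_relevant", "rule_irrelevant") %in%
          names(counts))) {
    stop("projection table lacks one of the relevance classes")
  }
  dat <- dat |>
    dplyr::mutate(
      rb = as.integer(.data$relevance != "residual"),
      rb_rel = as.integer(.data$relevance == "rule_relevant")
    )
  a <- anova(lm(projection ~ rb + rb:rb_rel, data = dat))
  anova_tbl <- tibble::tibble(
    term = c("rule_based", "relevance_within_rule", "residuals"),
    df = a$Df, sumsq = a$`Sum Sq`, F = a$`F value`, p = a$`Pr(>F)`
  )
  means <- dat |>
    dplyr::group_by(.data$relevance) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$projection),
                     se = sd(.data$projection) / sqrt(dplyr::n()),
                     .groups = "drop")
  combos <- list(
    c("rule_relevant", "rule_irrelevant"),
    c("rule_relevant", "residual"),
    c("rule_irrelevant", "residual")
  )
  contrasts <- purrr::map_dfr(combos, function(cc) {
    res <- .t2(dat$projection[dat$relevance == cc[1]],
               dat$projection[dat$relevance == cc[2]])
    dplyr::mutate(res, contrast = paste(cc, collapse = "_vs_"))
  }) |>
    dplyr::relocate("contrast")
  contrasts$p_adjusted <- p.adjust(contrasts$p, method = "BH")
  list(anova = anova_tbl, means = means, contrasts = contrasts)
}
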