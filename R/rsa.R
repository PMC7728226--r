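#' Condition centroids of a pseudotrial matrix
#'
#' The mean choice representation for each condition: the centroid of that
#' condition's pseudotrial vectors in neuron-dimensional state space.
#' The default is the arithmetic centroid (a geometric mean is undefined for
#' signed, z-scored activity); a geometric option is available for strictly
#' positive inputs.
#'
#' @param pm A `pseudotrial_matrix`.
#' @param centroid `"arithmetic"` (default) or `"geometric"`.
#' @return A numeric matrix, one row per condition (rownames = condition
#'   labels), with the condition tibble attached as attribute `conditions`.
#' @export
condition_centroids <- function(pm, centroid = c("arithmetic", "geometric")) {
  centroid <- match.arg(centroid)
  stopifnot(inherits(pm, "pseudotrial_matrix"))
  conds <- unique(pm$conditions$condition)
  out <- t(vapply(conds, function(cn) {
    rows <- pm$conditions$condition == cn
    if (!any(rows)) stop("empty condition: ", cn)
    block <- pm$values[rows, , drop = FALSE]
    if (centroid == "arithmetic") colMeans(block)
    else {
      if (any(block <= 0)) stop("geometric centroid requires positive values")
      exp(colMeans(log(block)))
    }
  }, numeric(ncol(pm$values))))
  attr(out, "conditions") <- dplyr::distinct(
    pm$conditions[, setdiff(names(pm$conditions), "pseudotrial")])
  attr(out, "scheme") <- pm$scheme
  out
}

#' Representational similarity (distance) matrix
#'
#' Euclidean distances between every pair of condition centroids, z-scored
#' over the unique off-diagonal entries (the self-distance diagonal is
#' excluded from z-scoring and from every statistic). Distances can also be
#' computed across two matrices (e.g. split halves), in which case entry
#' (i, j) is the distance between condition i in the first and condition j
#' in the second, and the diagonal is the cross-validated self-distance.
#'
#' @param centroids A [condition_centroids()] matrix.
#' @param centroids_b Optional second centroid matrix with identical
#'   condition layout, for cross-validated distances.
#' @return An object of class `rsa_matrix`: `raw` and `z` distance matrices,
#'   `labels` (condition tibble), `scheme`, `degenerate` (flag set when the
#'   off-diagonal entries have zero spread), `cross_validated`.
#' @export
distance_matrix <- function(centroids, centroids_b = NULL) {
  labels <- attr(centroids, "conditions")
  n <- nrow(centroids)
  if (n < 3) stop("need at least 3 conditions")
  cross <- !is.null(centroids_b)
  if (cross) {
    stopifnot(identical(dim(centroids), dim(centroids_b)))
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      d[i, ] <- sqrt(colSums((t(centroids_b) - centroids[i, ])^2))
    }
    d <- (d + t(d)) / 2  # symmetrize the two fold orders
  } else {
    d <- as.matrix(stats::dist(centroids))
  }
  off <- d[upper.tri(d)]
  s <- sd(off)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) {
    message("degenerate distance matrix: off-diagonal spread is zero")
    z <- d * 0
  } else {
    z <- (d - mean(off)) / s
  }
  diag(z) <- NA_real_
  structure(
    list(raw = d, z = z, labels = labels, scheme = attr(centroids, "scheme"),
         degenerate = degenerate, cross_validated = cross),
    class = "rsa_matrix"
  )
}

# long tibble of unique off-diagonal pairs with condition attributes
.rsa_pairs <- function(rsam) {
  lab <- rsam$labels
  n <- nrow(lab)
  idx <- which(upper.tri(rsam$z), arr.ind = TRUE)
  tibble::tibble(
    cond_a = lab$condition[idx[, 1]],
    cond_b = lab$condition[idx[, 2]],
    color_a = lab$chosen_color[idx[, 1]],
    color_b = lab$chosen_color[idx[, 2]],
    shape_a = lab$chosen_shape[idx[, 1]],
    shape_b = lab$chosen_shape[idx[, 2]],
    type_a = lab$type[idx[, 1]],
    type_b = lab$type[idx[, 2]],
    raw_d = rsam$raw[idx],
    z_d = rsam$z[idx]
  ) |>
    dplyr::mutate(
      same_type = .data$type_a == .data$type_b,
      same_identity = .data$color_a == .data$color_b &
        .data$shape_a == .data$shape_b,
      share_color = .data$color_a == .data$color_b,
      share_shape = .data$shape_a == .data$shape_b,
      share_feature = (.data$share_color | .data$share_shape) &
        !.data$same_identity
    )
}

.t2 <- function(a, b) {
  tt <- t.test(a, b, var.equal = TRUE)
  tibble::tibble(mean_a = mean(a), mean_b = mean(b),
                 estimate = mean(a) - mean(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, method = "two-sample t")
}

.tpaired <- function(a, b) {
  tt <- t.test(a, b, paired = TRUE)
  tibble::tibble(mean_a = mean(a), mean_b = mean(b),
                 estimate = mean(a) - mean(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, method = "paired t")
}

#' Planned contrasts over a representational similarity matrix
#'
#' For the rule-versus-residual scheme: (1) between- versus within-type
#' distances (a representational shift between choice types); (2) total
#' spread within rule-based versus residual conditions (paired over matched
#' identity pairs); (3) shared-feature versus no-shared-feature distances
#' within each choice type (categorical organization). For the
#' color-rule-versus-shape-rule scheme: between- versus within-domain
#' distances, and within each rule domain, pairs sharing the rule-relevant
#' feature versus the rule-irrelevant feature.
#'
#' All contrasts are computed on the z-scored off-diagonal entries.
#'
#' @param rsam An `rsa_matrix`.
#' @return A tibble, one row per contrast.
#' @export
rsa_contrasts <- function(rsam) {
  stopifnot(inherits(rsam, "rsa_matrix"))
  pairs <- .rsa_pairs(rsam)
  scheme <- rsam$scheme

  if (scheme == "rule_vs_residual") {
    within <- dplyr::filter(pairs, .data$same_type)
    between <- dplyr::filter(pairs, !.data$same_type)
    spread <- within |>
      dplyr::mutate(pair_id = paste(pmin(paste(.data$color_a, .data$shape_a),
                                         paste(.data$color_b, .data$shape_b)),
                                    pmax(paste(.data$color_a, .data$shape_a),
                                         paste(.data$color_b, .data$shape_b)))) |>
      dplyr::select("pair_id", "type_a", "z_d") |>
      tidyr::pivot_wider(names_from = "type_a", values_from = "z_d")
    res <- dplyr::bind_rows(
      dplyr::mutate(.t2(between$z_d, within$z_d),
                    contrast = "between_vs_within_type"),
      dplyr::mutate(.tpaired(spread$rule_based, spread$residual),
                    contrast = "rule_vs_residual_spread"),
      purrr::map_dfr(c("rule_based", "residual"), function(ty) {
        w <- dplyr::filter(within, .data$type_a == ty)
        dplyr::mutate(
          .t2(w$z_d[w$share_feature], w$z_d[!w$share_feature]),
          contrast = paste0("shared_vs_unshared_", ty))
      })
    )
  } else if (scheme == "color_vs_shape_rule") {
    within <- dplyr::filter(pairs, .data$same_type)
    between <- dplyr::filter(pairs, !.data$same_type)
    res <- dplyr::bind_rows(
      dplyr::mutate(.t2(between$z_d, within$z_d),
                    contrast = "between_vs_within_domain"),
      purrr::map_dfr(c("color_rule", "shape_rule"), function(ty) {
        relevant_share <- if (ty == "color_rule") "share_color" else
          "share_shape"
        irrelevant_share <- setdiff(c("share_color", "share_shape"),
                                    relevant_share)
        w <- dplyr::filter(within, .data$type_a == ty, !.data$same_identity)
        dplyr::mutate(
          .t2(w$z_d[w[[relevant_share]]], w$z_d[w[[irrelevant_share]]]),
          contrast = paste0("shared_relevant_vs_shared_irrelevant_", ty))
      })
    )
  } else {
    stop("no planned contrasts defined for scheme ", scheme)
  }
  dplyr::relocate(res, "contrast")
}

#' Structure ANOVA over a representational similarity matrix
#'
#' Models the z-scored upper-triangle distances with categorical predictors:
#' within versus between choice types, the choice type nested within the
#' within-type pairs, and feature sharing, with all interactions. For the
#' color-versus-shape-rule scheme the sharing predictors are share-color and
#' share-shape, and pairs matching both features but differing in rule
#' domain are omitted (the design matrix is rank-deficient with them in).
#'
#' @param rsam An `rsa_matrix`.
#' @return A tibble: `term`, `df`, `sumsq`, `F`, `p`, plus the residual row.
#' @export
rsa_anova <- function(rsam) {
  stopifnot(inherits(rsam, "rsa_matrix"))
  pairs <- .rsa_pairs(rsam)
  scheme <- rsam$scheme

  if (scheme == "rule_vs_residual") {
    dat <- pairs |>
      dplyr::mutate(
        within = as.integer(.data$same_type),
        within_rule = as.integer(.data$same_type &
                                   .data$type_a == "rule_based"),
        share = as.integer(.data$share_feature)
      )
    fit <- lm(z_d ~ within + within_rule + share +
                within:share + within_rule:share, data = dat)
  } else if (scheme == "color_vs_shape_rule") {
    dat <- pairs |>
      dplyr::filter(!(.data$share_color & .data$share_shape &
                        !.data$same_type)) |>
      dplyr::mutate(
        within = as.integer(.data$same_type),
        within_color = as.integer(.data$same_type &
                                    .data$type_a == "color_rule"),
        sc = as.integer(.data$share_color),
        ss = as.integer(.data$share_shape)
      )
    fit <- lm(z_d ~ within + within_color + sc + ss +
                within:sc + within:ss + within_color:sc + within_color:ss,
              data = dat)
  } else {
    stop("no structure ANOVA defined for scheme ", scheme)
  }
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design matrix: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  a <- anova(fit)
  tibble::tibble(
    term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
    F = a$`F value`, p = a$`Pr(>F)`
  )
}
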