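#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted rule HMM
#'
#' @param x A `rule_hmm_fit`.
#' @param ... Unused.
#' @return One row per trial: Viterbi label and the full posterior.
#' @export
tidy.rule_hmm_fit <- function(x, ...) {
  g <- tibble::as_tibble(as.data.frame(x$inference$posteriors))
  names(g) <- paste0("p_", names(g))
  dplyr::bind_cols(
    tibbles <- tibble::tibble(
      trial_index = seq_len(x$inference$n_trials),
      hmm_state = x$viterbi_path
    ),
    g
  )
}

#' @rdname tidy.rule_hmm_fit
#' @export
glance.rule_hmm_fit <- function(x, ...) {
  tibble::tibble(
    a_rr = x$hmm$a_rr, a_oo = x$hmm$a_oo,
    log_likelihood = x$log_likelihood,
    n_trials = x$inference$n_trials,
    n_restarts = nrow(x$restarts),
    iterations = x$restarts$iterations[x$best_restart],
    converged = x$converged
  )
}

#' Tidy a representational similarity matrix
#'
#' @param x An `rsa_matrix`.
#' @param ... Unused.
#' @return Long tibble of unique condition pairs with raw and z-scored
#'   distances and the pair predicates used by the contrasts.
#' @export
tidy.rsa_matrix <- function(x, ...) {
  .rsa_pairs(x)
}

#' @rdname tidy.rsa_matrix
#' @export
glance.rsa_matrix <- function(x, ...) {
  off <- x$raw[upper.tri(x$raw)]
  tibble::tibble(
    scheme = x$scheme, n_conditions = nrow(x$labels),
    n_pairs = length(off), mean_distance = mean(off),
    sd_distance = sd(off), degenerate = x$degenerate,
    cross_validated = x$cross_validated
  )
}

#' Tidy a coding-dimension bank
#'
#' @param x A `coding_dimensions` object.
#' @param ... Unused.
#' @return Long tibble of classifier coefficients per neuron and feature.
#' @export
tidy.coding_dimensions <- function(x, ...) {
  tibble::tibble(
    neuron_id = rep(rownames(x$beta), ncol(x$beta)),
    feature = rep(colnames(x$beta), each = nrow(x$beta)),
    coefficient = as.vector(x$beta)
  )
}

#' @rdname tidy.coding_dimensions
#' @export
glance.coding_dimensions <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    n_neurons = nrow(x$beta),
    n_classifiers = ncol(x$beta),
    lambda = if (length(unique(x$lambda)) == 1) unique(x$lambda) else
      NA_real_,
    mean_cv_accuracy = mean(x$accuracy_at_chosen)
  )
}

#' @export
print.rule_hmm <- function(x, ...) {
  cat("Constrained rule-state HMM (7 states, 2 free parameters)\n")
  cat(sprintf("  a_rr = %.4f, a_oo = %.4f\n", x$a_rr, x$a_oo))
  invisible(x)
}

#' @export
print.rule_hmm_fit <- function(x, ...) {
  cat("Baum-Welch fit of the rule-state HMM\n")
  cat(sprintf("  a_rr = %.4f, a_oo = %.4f, logLik = %.2f (%d trials)\n",
              x$hmm$a_rr, x$hmm$a_oo, x$log_likelihood,
              x$inference$n_trials))
  cat(sprintf("  %d restart(s), best converged: %s\n",
              nrow(x$restarts), x$converged))
  invisible(x)
}

#' @export
print.pseudotrial_matrix <- function(x, ...) {
  cat(sprintf("Pseudotrial matrix (%s): %d rows x %d neurons, %d conditions\n",
              x$scheme, nrow(x$values), ncol(x$values),
              dplyr::n_distinct(x$conditions$condition)))
  excl <- sum(x$roster$status == "excluded")
  if (excl) cat(sprintf("  %d neuron(s) excluded\n", excl))
  invisible(x)
}
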