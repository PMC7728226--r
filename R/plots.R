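#' Plot posterior state probabilities across a session
#'
#' Trial-by-trial posterior probability of the residual state and of the
#' pooled rule states, with block boundaries marked.
#'
#' @param fit A `rule_hmm_fit`.
#' @param trials The trials tibble the model was fit to (for block marks).
#' @return A ggplot object.
#' @export
plot_state_posterior <- function(fit, trials = NULL) {
  g <- fit$inference$posteriors
  df <- tibble::tibble(
    trial_index = rep(seq_len(nrow(g)), 2),
    state = rep(c("residual", "rule (pooled)"), each = nrow(g)),
    probability = c(g[, 1], rowSums(g[, -1, drop = FALSE]))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$trial_index,
                                        .data$probability,
                                        color = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = "posterior probability", color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(trials)) {
    changes <- trials$trial_index[c(FALSE, diff(trials$block_index) > 0)]
    if (length(changes)) {
      p <- p + ggplot2::geom_vline(xintercept = changes, linetype = 3,
                                   alpha = 0.5)
    }
  }
  p
}

#' @export
autoplot.rule_hmm_fit <- function(object, ...) plot_state_posterior(object)

#' Heatmap of a representational similarity matrix
#'
#' @param rsam An `rsa_matrix`.
#' @param what `"z"` (default) or `"raw"` distances.
#' @return A ggplot object.
#' @export
plot_rsa_matrix <- function(rsam, what = c("z", "raw")) {
  what <- match.arg(what)
  m <- rsam[[what]]
  labs <- rsam$labels$condition
  df <- tibble::tibble(
    a = factor(rep(labs, times = length(labs)), levels = labs),
    b = factor(rep(labs, each = length(labs)), levels = rev(labs)),
    d = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$d)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (what == "z") "z(distance)" else "distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @export
autoplot.rsa_matrix <- function(object, ...) plot_rsa_matrix(object, ...)

#' Chosen-feature projections by relevance class
#'
#' Mean position along the chosen features' coding dimensions for residual,
#' rule-relevant, and rule-irrelevant pseudotrials.
#'
#' @param proj A `projection_table`.
#' @return A ggplot object.
#' @export
plot_projection_summary <- function(proj) {
  df <- proj |>
    dplyr::filter(.data$chosen) |>
    dplyr::group_by(.data$relevance) |>
    dplyr::summarise(mean = mean(.data$projection),
                     se = sd(.data$projection) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(relevance = factor(
      .data$relevance,
      levels = c("rule_relevant", "residual", "rule_irrelevant")))
  ggplot2::ggplot(df, ggplot2::aes(.data$relevance, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "projection (log odds of choice)") +
    ggplot2::theme_minimal()
}

#' Residual choice-relation profile against the ideal-observer model
#'
#' Observed frequency of each choice-relation class among residual choices,
#' its chance availability, and the model's expected information gain.
#'
#' @param profile Output of [choice_class_profile()].
#' @return A ggplot object.
#' @export
plot_choice_profile <- function(profile) {
  df <- profile |>
    tidyr::pivot_longer(c("freq", "chance"), names_to = "series",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$relation), .data$value,
                                   fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "feature dimensions changed from last choice",
                  y = "probability", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
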