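#' The CSST feature space
#'
#' The cognitive set-shifting task (CSST) presents three options on every
#' trial, each a unique pairing of one of three colors with one of three
#' shapes. The six features (3 colors + 3 shapes) are the possible "correct
#' features": within a block, exactly one of them determines reward.
#'
#' @return A list with components `colors`, `shapes`, `features` (the
#'   6-element union, colors first), and `n_options` (always 3).
#' @examples
#' feature_space()$features
#' @export
feature_space <- function() {
  list(
    colors = .colors,
    shapes = .shapes,
    features = .features,
    n_options = 3L
  )
}

#' Feature domain of a feature label
#'
#' @param feature Character vector of feature labels.
#' @return `"color"` or `"shape"` per element.
#' @export
feature_domain <- function(feature) {
  stopifnot(all(feature %in% .features))
  ifelse(feature %in% .colors, "color", "shape")
}

# the 6 color<->shape bijections, one row per permutation of the shapes
.perms3 <- rbind(
  c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
)

#' Generate randomized CSST option sets
#'
#' Each option set pairs the three colors with the three shapes in a uniformly
#' random bijection, and assigns random screen positions and presentation
#' orders (each a uniform permutation of 1:3). Options are indexed 1:3 in the
#' slot order used by `choice_index`; by construction every feature matches
#' exactly one option.
#'
#' @param n Number of option sets (trials) to generate.
#' @return A tibble with `n` rows and columns `opt{1,2,3}_color`,
#'   `opt{1,2,3}_shape`, `opt{1,2,3}_position`, `opt{1,2,3}_order`.
#' @examples
#' set.seed(1)
#' generate_option_set(2)
#' @export
generate_option_set <- function(n = 1L) {
  stopifnot(n >= 1)
  shape_perm <- .perms3[sample.int(6L, n, replace = TRUE), , drop = FALSE]
  pos_perm <- .perms3[sample.int(6L, n, replace = TRUE), , drop = FALSE]
  ord_perm <- .perms3[sample.int(6L, n, replace = TRUE), , drop = FALSE]
  out <- tibble::tibble(.rows = n)
  for (j in 1:3) {
    out[[paste0("opt", j, "_color")]] <- .colors[j]
    out[[paste0("opt", j, "_shape")]] <- .shapes[shape_perm[, j]]
    out[[paste0("opt", j, "_position")]] <- pos_perm[, j]
    out[[paste0("opt", j, "_order")]] <- ord_perm[, j]
  }
  out
}

#' Is a choice correct under the current rule?
#'
#' A choice is rewarded when either of its features (color or shape) equals
#' the block's correct feature.
#'
#' @param chosen_color,chosen_shape Features of the chosen option.
#' @param correct_feature The block's correct feature.
#' @return Integer vector of 0/1.
#' @export
is_correct <- function(chosen_color, chosen_shape, correct_feature) {
  if (!all(correct_feature %in% .features)) {
    stop("correct_feature must be one of: ", paste(.features, collapse = ", "))
  }
  as.integer(chosen_color == correct_feature | chosen_shape == correct_feature)
}

#' Choice-relation class between consecutive choices
#'
#' Counts the feature dimensions (color, shape) on which the current choice
#' differs from the previous one. Class 2 is a "novel" option that matches
#' neither feature of the last choice.
#'
#' @param prev_color,prev_shape Features of the previous choice.
#' @param color,shape Features of the current choice.
#' @return Integer vector in 0:2.
#' @examples
#' choice_relation("cyan", "star", "cyan", "circle")  # 1
#' @export
choice_relation <- function(prev_color, prev_shape, color, shape) {
  stopifnot(
    all(prev_color %in% .colors), all(color %in% .colors),
    all(prev_shape %in% .shapes), all(shape %in% .shapes)
  )
  as.integer(prev_color != color) + as.integer(prev_shape != shape)
}

#' Block schedule for the CSST
#'
#' Blocks end after a criterion number of correct choices, after which a new
#' correct feature is drawn. The experiment used criteria of 10, 15, 20, or
#' 30 correct responses; in practice it was almost always 15, the default
#' here. Because the rule "changed" at block boundaries, the default draw
#' policy excludes the current feature when drawing the next one; a uniform
#' draw over all six is available for sensitivity checks.
#'
#' @param criterion Correct-choice count that ends a block.
#' @param rule_draw_policy `"exclude_current"` (default) or `"uniform"`.
#' @return A list of class `block_schedule`.
#' @export
block_schedule <- function(criterion = 15L,
                           rule_draw_policy = c("exclude_current", "uniform")) {
  criterion <- as.integer(criterion)
  stopifnot(length(criterion) == 1L, criterion > 0L)
  structure(
    list(criterion = criterion,
         rule_draw_policy = match.arg(rule_draw_policy)),
    class = "block_schedule"
  )
}

#' Draw the next correct feature at a block change
#'
#' @param current Current correct feature, or `NULL` at session start.
#' @param schedule A [block_schedule()].
#' @return A feature label.
#' @export
draw_correct_feature <- function(current = NULL, schedule = block_schedule()) {
  pool <- .features
  if (!is.null(current) && schedule$rule_draw_policy == "exclude_current") {
    pool <- setdiff(pool, current)
  }
  sample(pool, 1L)
}

#' Advance the within-block correct counter
#'
#' Rewarded trials increment the counter; reaching the criterion flags a block
#' change, resets the counter, and draws the next correct feature under the
#' schedule's draw policy.
#'
#' @param correct_count Correct choices so far this block (< criterion).
#' @param reward 0/1 outcome of the current trial.
#' @param schedule A [block_schedule()].
#' @param current_feature The block's correct feature.
#' @return A list with `correct_count`, `block_changed`, and `correct_feature`
#'   (the next block's feature when changed, otherwise unchanged).
#' @export
advance_block <- function(correct_count, reward, schedule, current_feature) {
  stopifnot(correct_count < schedule$criterion, reward %in% c(0L, 1L))
  count <- correct_count + as.integer(reward)
  if (count >= schedule$criterion) {
    list(
      correct_count = 0L,
      block_changed = TRUE,
      correct_feature = draw_correct_feature(current_feature, schedule)
    )
  } else {
    list(
      correct_count = count,
      block_changed = FALSE,
      correct_feature = current_feature
    )
  }
}

# option features of a trial row as a 3 x 2 character matrix (color, shape)
.option_features <- function(trial_row) {
  cbind(
    color = c(trial_row$opt1_color, trial_row$opt2_color, trial_row$opt3_color),
    shape = c(trial_row$opt1_shape, trial_row$opt2_shape, trial_row$opt3_shape)
  )
}

#' Validate a trials table against the task invariants
#'
#' Checks the structural invariants of generated sessions: distinct colors and
#' shapes within every option set, permutation positions and orders, chosen
#' features consistent with the chosen option, and rewards equal to
#' [is_correct()].
#'
#' @param trials A trials tibble (see [simulate_behavior()]).
#' @return Invisibly `TRUE`; errors with the first violated invariant.
#' @export
validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  cols <- cbind(trials$opt1_color, trials$opt2_color, trials$opt3_color)
  shps <- cbind(trials$opt1_shape, trials$opt2_shape, trials$opt3_shape)
  if (!all(apply(cols, 1, function(x) setequal(x, .colors)))) {
    stop("option colors are not a permutation of the three colors")
  }
  if (!all(apply(shps, 1, function(x) setequal(x, .shapes)))) {
    stop("option shapes are not a permutation of the three shapes")
  }
  pos <- cbind(trials$opt1_position, trials$opt2_position, trials$opt3_position)
  ord <- cbind(trials$opt1_order, trials$opt2_order, trials$opt3_order)
  if (!all(apply(pos, 1, function(x) setequal(x, 1:3)))) {
    stop("option positions are not a permutation of 1:3")
  }
  if (!all(apply(ord, 1, function(x) setequal(x, 1:3)))) {
    stop("presentation orders are not a permutation of 1:3")
  }
  idx <- cbind(seq_len(nrow(trials)), trials$choice_index)
  if (!all(trials$chosen_color == cols[idx]) ||
      !all(trials$chosen_shape == shps[idx])) {
    stop("chosen features do not match the chosen option")
  }
  expected <- is_correct(trials$chosen_color, trials$chosen_shape,
                         trials$correct_feature)
  if (!all(trials$reward == expected)) {
    stop("rewards are inconsistent with the correct feature")
  }
  invisible(TRUE)
}
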