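#' Read and write the tabular interchange formats
#'
#' Trials and spikes tables travel as UTF-8 TSV with headers. The trials
#' layout is one row per trial: `session_id`, `trial_index`, `block_index`,
#' `correct_feature`, `opt{1,2,3}_color`, `opt{1,2,3}_shape`,
#' `opt{1,2,3}_position`, `opt{1,2,3}_order`, `choice_index`, `chosen_color`,
#' `chosen_shape`, `reward` (plus any extra columns, e.g. `true_state` for
#' synthetic data). The spikes layout is one row per neuron and trial:
#' `neuron_id`, `region`, `session_id`, `trial_index`, `spike_count` and
#' optional `epoch{1,2,3}_count` columns.
#'
#' @param path File path.
#' @param trials,spikes Tibbles to write.
#' @return Tibbles, for the readers; the input (invisibly) for the writers.
#' @name table_io
NULL

.trials_required <- c(
  "session_id", "trial_index", "block_index", "correct_feature",
  paste0("opt", rep(1:3, each = 4), "_",
         rep(c("color", "shape", "position", "order"), 3)),
  "choice_index", "chosen_color", "chosen_shape", "reward"
)

#' @rdname table_io
#' @export
read_trials <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.trials_required, names(out))
  if (length(missing)) {
    stop("trials table is missing columns: ", paste(missing, collapse = ", "))
  }
  out
}

#' @rdname table_io
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials, path, progress = FALSE)
  invisible(trials)
}

#' @rdname table_io
#' @export
read_spikes <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("neuron_id", "region", "session_id", "trial_index",
                "spike_count")
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop("spikes table is missing columns: ", paste(missing, collapse = ", "))
  }
  out
}

#' @rdname table_io
#' @export
write_spikes <- function(spikes, path) {
  readr::write_tsv(spikes, path, progress = FALSE)
  invisible(spikes)
}
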