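#' Relative premature stop-codon readthrough
#'
#' Averages replicate endpoint signals, then divides each mutant's signal
#' by the wild-type signal of the *same* reporter construct (stop codon x
#' amino-acid position), so wild-type readthrough is normalized to 1 on
#' every construct.
#'
#' @param signals Tibble `sample_id`, `stop_codon`, `aa_position`,
#'   `replicate` (optional), `signal` (endpoint fluorescence).
#' @param wt_id Wild-type sample id (default `"WT"`).
#' @return Tibble `sample_id`, `stop_codon`, `aa_position`,
#'   `relative_readthrough`.
#' @export
relative_readthrough <- function(signals, wt_id = "WT") {
  stopifnot(is.data.frame(signals),
            all(c("sample_id", "stop_codon", "aa_position", "signal") %in% names(signals)))
  if (any(signals$signal < 0)) ptc_abort("Signals must be non-negative")
  avg <- signals |>
    dplyr::group_by(.data$sample_id, .data$stop_codon, .data$aa_position) |>
    dplyr::summarise(signal = mean(.data$signal), .groups = "drop")
  wt <- avg |>
    dplyr::filter(.data$sample_id == wt_id) |>
    dplyr::select("stop_codon", "aa_position", wt_signal = "signal")
  if (nrow(wt) == 0) ptc_abort(sprintf("Wild-type sample '%s' not found", wt_id))
  out <- dplyr::inner_join(avg, wt, by = c("stop_codon", "aa_position"))
  if (nrow(out) < nrow(avg)) {
    ptc_abort("Construct(s) without a wild-type reference signal")
  }
  if (any(out$wt_signal <= 0)) {
    ptc_abort("Non-positive wild-type signal for at least one construct",
              class = "ptcflex_invalid_wt_signal")
  }
  out |>
    dplyr::mutate(relative_readthrough = .data$signal / .data$wt_signal) |>
    dplyr::select("sample_id", "stop_codon", "aa_position", "relative_readthrough")
}

#' Normalize readthrough by translation activity
#'
#' Divides relative readthrough by the mutant's relative translation
#' activity, so a mutant that translates poorly but still reads through
#' stop codons is credited accordingly. Below an activity floor the
#' normalization amplifies noise without bound, so such records are
#' flagged and returned as `NA` (never infinity); the raw ratio is
#' retained in `relative_readthrough`.
#'
#' @param readthrough Output of [relative_readthrough()].
#' @param activity Tibble `sample_id`, `relative_activity`, e.g. from
#'   [activity_records()].
#' @param floor Minimum relative activity for a defined normalization
#'   (default 0.02, i.e. 2% of wild type).
#' @return Input tibble plus `relative_activity`,
#'   `normalized_readthrough` (`NA` below floor) and
#'   `below_activity_floor`.
#' @export
normalize_by_activity <- function(readthrough, activity, floor = 0.02) {
  stopifnot(is.data.frame(readthrough), is.data.frame(activity),
            all(c("sample_id", "relative_activity") %in% names(activity)))
  if (any(activity$relative_activity < 0)) ptc_abort("Relative activity must be >= 0")
  out <- dplyr::left_join(
    readthrough,
    dplyr::distinct(activity[, c("sample_id", "relative_activity")]),
    by = "sample_id"
  )
  if (anyNA(out$relative_activity)) {
    ptc_abort(sprintf("No activity record for sample(s): %s",
                      paste(unique(out$sample_id[is.na(out$relative_activity)]), collapse = ", ")))
  }
  out |>
    dplyr::mutate(
      below_activity_floor = .data$relative_activity < floor,
      normalized_readthrough = dplyr::if_else(
        .data$below_activity_floor, NA_real_,
        .data$relative_readthrough / .data$relative_activity
      )
    )
}
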