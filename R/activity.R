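#' Fit a linear fluorescence-to-concentration standard curve
#'
#' Ordinary least squares of concentration (uM) on fluorescence (RFU),
#' the in-house calibration used to convert reporter fluorescence into
#' protein yield.
#'
#' @param points Data frame with columns `rfu` and `um`; at least two
#'   distinct RFU values.
#' @return An object of class `standard_curve` with elements `slope`
#'   (uM/RFU), `intercept` (uM), `r_squared` and the underlying `lm` fit.
#'   Has [tidy()] and [glance()] methods.
#' @examples
#' fit_standard_curve(data.frame(rfu = c(0, 100, 200), um = c(0, 1, 2)))
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points), all(c("rfu", "um") %in% names(points)))
  if (dplyr::n_distinct(points$rfu) < 2) {
    ptc_abort("Standard curve needs at least 2 distinct RFU values",
              class = "ptcflex_degenerate_curve")
  }
  fit <- stats::lm(um ~ rfu, data = points)
  slope <- unname(coef(fit)[["rfu"]])
  if (slope <= 0) rlang::warn("Standard-curve slope is not positive")
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = summary(fit)$r.squared,
      fit = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: uM = %.6g * RFU + %.6g (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, n = stats::nobs(x$fit))
}

#' Convert fluorescence traces to concentration
#'
#' Applies the standard curve pointwise (`um = slope * rfu + intercept`).
#' Negative concentrations, which arise from noise near the blank, are
#' floored at zero and the number of floored points is reported as a
#' warning.
#'
#' @param traces Long-format tibble with columns `sample_id`, `time_h`,
#'   `signal` and `unit` (all `"RFU"`); a `replicate` column is carried
#'   through if present.
#' @param curve A [fit_standard_curve()] object (or list with `slope` and
#'   `intercept`).
#' @return The same tibble with `signal` in uM and `unit = "uM"`.
#' @export
convert_trace <- function(traces, curve) {
  stopifnot(is.data.frame(traces), all(c("sample_id", "time_h", "signal", "unit") %in% names(traces)))
  if (!all(traces$unit == "RFU")) {
    ptc_abort("convert_trace() expects traces in RFU", class = "ptcflex_unit_mismatch")
  }
  um <- curve$slope * traces$signal + curve$intercept
  n_floored <- sum(um < 0)
  if (n_floored > 0) {
    rlang::warn(sprintf("%d concentration value(s) below 0 floored at 0", n_floored))
  }
  dplyr::mutate(traces, signal = pmax(um, 0), unit = "uM")
}

## validate one kinetic trace (single sample, averaged replicates)
check_trace <- function(time_h, signal, min_points = 4) {
  if (length(time_h) < min_points) {
    ptc_abort(sprintf("Kinetic trace needs >= %d time points", min_points))
  }
  if (any(time_h < 0) || any(diff(time_h) <= 0)) {
    ptc_abort("Trace times must be non-negative and strictly increasing")
  }
  invisible(TRUE)
}

#' Bulk translation rate from a kinetic trace
#'
#' OLS slope of concentration versus time over an early-reaction window
#' (default 0-2 h), the bulk rate in uM protein/h reported for translation
#' kinetics curves.
#'
#' @param traces Tibble with `sample_id`, `time_h`, `signal` (uM). Multiple
#'   samples are handled by group.
#' @param window Numeric `(t_start, t_end)` in hours; points with
#'   `t_start <= time_h <= t_end` are used, at least 3 required.
#' @return Tibble `sample_id`, `bulk_rate` (uM/h).
#' @export
estimate_bulk_rate <- function(traces, window = c(0, 2)) {
  stopifnot(is.data.frame(traces), length(window) == 2, window[1] < window[2])
  traces |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(bulk_rate = {
      keep <- .data$time_h >= window[1] & .data$time_h <= window[2]
      if (sum(keep) < 3) {
        ptc_abort(sprintf("Fewer than 3 points in rate window for '%s'",
                          dplyr::cur_group()$sample_id))
      }
      unname(coef(stats::lm(y ~ t, data = list(y = .data$signal[keep], t = .data$time_h[keep])))[["t"]])
    }, .groups = "drop")
}

#' Endpoint protein yield of a kinetic trace
#'
#' Default summary is the plateau estimate: the mean signal over the final
#' 10% of the time axis, robust to noise in a saturated trace monitored for
#' 16-20 h. `method = "last"` takes the final point instead.
#'
#' @inheritParams estimate_bulk_rate
#' @param method `"plateau"` (default) or `"last"`.
#' @param tail_frac Fraction of the time axis averaged by the plateau
#'   method (default 0.1).
#' @return Tibble `sample_id`, `yield` (uM).
#' @export
endpoint_yield <- function(traces, method = c("plateau", "last"), tail_frac = 0.1) {
  method <- match.arg(method)
  stopifnot(is.data.frame(traces), nrow(traces) > 0)
  traces |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(yield = {
      t <- .data$time_h
      s <- .data$signal
      check_trace(t, s)
      if (method == "last") s[length(s)] else mean(s[t >= (1 - tail_frac) * max(t)])
    }, .groups = "drop")
}

#' Relative translation activity
#'
#' Mutant yield divided by wild-type yield, with the wild type normalized
#' to one.
#'
#' @param mutant_yield Numeric vector of mutant yields (uM).
#' @param wt_yield Positive wild-type yield (uM).
#' @return Dimensionless relative activity (vectorised).
#' @export
relative_activity <- function(mutant_yield, wt_yield) {
  if (length(wt_yield) != 1 || !is.finite(wt_yield) || wt_yield <= 0) {
    ptc_abort("Wild-type yield must be a single positive value",
              class = "ptcflex_invalid_wt_yield")
  }
  if (any(mutant_yield < 0)) ptc_abort("Yields must be non-negative")
  mutant_yield / wt_yield
}

#' Full activity scoring of a mutant panel
#'
#' Converts traces through the standard curve when given in RFU, averages
#' replicates pointwise, then computes endpoint yield, bulk rate and
#' relative activity (wild type = 1) for every sample.
#'
#' @param traces Long tibble `sample_id`, `replicate` (optional), `time_h`,
#'   `signal`, `unit`.
#' @param curve Standard curve; required when traces are in RFU.
#' @param wt_id Sample id of the wild type (default `"WT"`).
#' @param rate_window Window passed to [estimate_bulk_rate()].
#' @param yield_method Passed to [endpoint_yield()].
#' @return Tibble `sample_id`, `endpoint_yield`, `yield_sd`, `bulk_rate`,
#'   `relative_activity`.
#' @export
activity_records <- function(traces, curve = NULL, wt_id = "WT",
                             rate_window = c(0, 2),
                             yield_method = c("plateau", "last")) {
  yield_method <- match.arg(yield_method)
  stopifnot(is.data.frame(traces))
  if (!"unit" %in% names(traces)) traces$unit <- "uM"
  if (all(traces$unit == "RFU")) {
    if (is.null(curve)) ptc_abort("Traces are in RFU: a standard curve is required")
    traces <- convert_trace(traces, curve)
  } else if (!all(traces$unit == "uM")) {
    ptc_abort("Traces must be uniformly RFU or uM", class = "ptcflex_unit_mismatch")
  }
  ## pointwise replicate average; sd carried for error propagation
  avg <- traces |>
    dplyr::group_by(.data$sample_id, .data$time_h) |>
    dplyr::summarise(signal_sd = if (dplyr::n() > 1) stats::sd(.data$signal) else 0,
                     signal = mean(.data$signal), .groups = "drop") |>
    dplyr::arrange(.data$sample_id, .data$time_h)
  if (!wt_id %in% avg$sample_id) {
    ptc_abort(sprintf("Wild-type sample '%s' not found", wt_id))
  }
  yields <- endpoint_yield(avg, method = yield_method)
  sds <- avg |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(yield_sd = mean(.data$signal_sd[.data$time_h >= 0.9 * max(.data$time_h)]),
                     .groups = "drop")
  rates <- estimate_bulk_rate(avg, window = rate_window)
  wt_yield <- yields$yield[yields$sample_id == wt_id]
  yields |>
    dplyr::left_join(sds, by = "sample_id") |>
    dplyr::left_join(rates, by = "sample_id") |>
    dplyr::mutate(relative_activity = relative_activity(.data$yield, wt_yield)) |>
    dplyr::rename(endpoint_yield = "yield")
}

#' Per-position mutational flexibility scores
#'
#' The mutational flexibility score of a position is the sum of the
#' relative activities of its three possible point mutants: 3 means all
#' three substitutions retain wild-type activity, 0 means none supports
#' protein synthesis. Two classification flags follow the study's
#' annotations: `flag_flex_ge_1` (score >= 1) and `flag_any_ge_75pct`
#' (best single mutant >= 0.75 of wild type).
#'
#' @param activity Tibble with `sample_id` (canonical mutant names such as
#'   `A2451C`) and `relative_activity`, e.g. from [activity_records()].
#'   The wild-type row (`wt_id`) is ignored if present.
#' @param wt_id Wild-type sample id to drop (default `"WT"`).
#' @return Tibble `position`, `wt_base`, `act_A`, `act_C`, `act_G`,
#'   `act_U` (wild-type base column `NA`), `score`, `max_relative_activity`,
#'   `flag_flex_ge_1`, `flag_any_ge_75pct`, sorted by position.
#' @examples
#' flexibility_scores(tibble::tibble(
#'   sample_id = c("A2451C", "A2451G", "A2451U"),
#'   relative_activity = c(1, 1, 1)
#' ))
#' @export
flexibility_scores <- function(activity, wt_id = "WT") {
  stopifnot(is.data.frame(activity),
            all(c("sample_id", "relative_activity") %in% names(activity)))
  act <- dplyr::filter(activity, .data$sample_id != wt_id)
  if (any(act$relative_activity < 0)) ptc_abort("Relative activities must be >= 0")
  parsed <- parse_mutant_id(act$sample_id)
  act <- dplyr::bind_cols(act["relative_activity"], parsed)
  dup <- act |>
    dplyr::count(.data$position, .data$mut_base) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    ptc_abort(sprintf("Duplicate mutant record(s) at position(s): %s",
                      paste(unique(dup$position), collapse = ", ")),
              class = "ptcflex_duplicate_mutant")
  }
  counts <- dplyr::count(act, .data$position)
  if (any(counts$n != 3)) {
    ptc_abort(sprintf("Position(s) without exactly 3 mutants: %s",
                      paste(counts$position[counts$n != 3], collapse = ", ")),
              class = "ptcflex_incomplete_position")
  }
  act |>
    dplyr::group_by(.data$position, .data$wt_base) |>
    dplyr::summarise(
      act_A = .data$relative_activity[match("A", .data$mut_base)],
      act_C = .data$relative_activity[match("C", .data$mut_base)],
      act_G = .data$relative_activity[match("G", .data$mut_base)],
      act_U = .data$relative_activity[match("U", .data$mut_base)],
      score = sum(.data$relative_activity),
      max_relative_activity = max(.data$relative_activity),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      flag_flex_ge_1 = .data$score >= 1,
      flag_any_ge_75pct = .data$max_relative_activity >= 0.75
    ) |>
    dplyr::arrange(.data$position)
}
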