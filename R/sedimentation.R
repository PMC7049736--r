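#' Default sucrose-gradient species boundaries
#'
#' Gradient-distance windows (mm) assigning A254 signal to 30S and 50S
#' subunits, 70S monosomes and polysomes. The defaults follow the
#' approximate boundaries used for Riemann-sum quantification of iSAT
#' gradient traces (30S ~13-21 mm, 50S ~22-28 mm, 70S ~30-40 mm,
#' polysomes ~42-59 mm) and may be overridden per instrument.
#'
#' @return Tibble `species`, `start`, `end`.
#' @export
default_boundaries <- function() {
  tibble::tribble(
    ~species,    ~start, ~end,
    "30S",         13,    21,
    "50S",         22,    28,
    "70S",         30,    40,
    "polysomes",   42,    59
  )
}

check_gradient_trace <- function(trace, min_points = 2) {
  stopifnot(is.data.frame(trace), all(c("distance_mm", "a254") %in% names(trace)))
  if (nrow(trace) < min_points) ptc_abort("Gradient trace has too few points")
  if (any(diff(trace$distance_mm) <= 0)) {
    ptc_abort("Gradient distance axis must be strictly increasing",
              class = "ptcflex_nonmonotone_axis")
  }
  invisible(trace)
}

## interpolate a control trace onto the sample grid; extrapolation forbidden
interp_onto <- function(control, xout, what) {
  check_gradient_trace(control)
  if (min(control$distance_mm) > min(xout) || max(control$distance_mm) < max(xout)) {
    ptc_abort(sprintf("%s trace does not span the sample trace; extrapolation is not allowed", what),
              class = "ptcflex_span_mismatch")
  }
  stats::approx(control$distance_mm, control$a254, xout = xout)$y
}

#' Baseline- and background-correct a gradient trace
#'
#' Subtracts a blank-sucrose baseline trace and a no-operon background
#' trace (each linearly interpolated onto the sample grid) from the sample
#' A254 readings. Negative results are floored at zero — absorbance cannot
#' be negative — and the number of clipped points is attached as attribute
#' `n_clipped` and reported.
#'
#' @param sample Tibble `distance_mm`, `a254` with strictly increasing
#'   distances.
#' @param blank,background Optional control traces on an overlapping span;
#'   `NULL` skips that subtraction. The background trace is assumed to be
#'   already baseline-corrected (blank-subtracted).
#' @return Corrected tibble `distance_mm`, `a254` on the sample grid.
#' @export
correct_trace <- function(sample, blank = NULL, background = NULL) {
  check_gradient_trace(sample)
  corrected <- sample$a254
  if (!is.null(blank)) corrected <- corrected - interp_onto(blank, sample$distance_mm, "Blank")
  if (!is.null(background)) corrected <- corrected - interp_onto(background, sample$distance_mm, "Background")
  n_clipped <- sum(corrected < 0)
  if (n_clipped > 0) {
    rlang::inform(sprintf("correct_trace: %d point(s) clipped at 0", n_clipped))
  }
  out <- tibble::tibble(distance_mm = sample$distance_mm, a254 = pmax(corrected, 0))
  attr(out, "n_clipped") <- n_clipped
  out
}

## left-endpoint Riemann sum of (x, y) over the half-open window [start, end)
riemann_left <- function(x, y, start, end) {
  n <- length(x)
  dx <- diff(x)
  idx <- which(x >= start & x < end)
  idx <- idx[idx < n]
  if (length(idx) == 0) {
    ptc_abort(sprintf("No grid points in window [%g, %g)", start, end),
              class = "ptcflex_empty_window")
  }
  sum(y[idx] * dx[idx])
}

## trapezoidal alternative over points inside [start, end]
trapezoid_area <- function(x, y, start, end) {
  idx <- which(x >= start & x <= end)
  if (length(idx) < 2) ptc_abort(sprintf("Too few grid points in window [%g, %g]", start, end))
  xs <- x[idx]; ys <- y[idx]
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Integrate a gradient trace into ribosomal species areas
#'
#' Area under the corrected A254 curve inside each species window, by
#' left-endpoint Riemann sum on the measured grid over half-open windows
#' `[start, end)` (so adjacent windows never double-count a point);
#' `rule = "trapezoid"` is available as an alternative. Signal between
#' windows is reported separately as attribute `unassigned_area` rather
#' than attributed to any species.
#'
#' @param trace Corrected tibble `distance_mm`, `a254`.
#' @param boundaries Tibble `species`, `start`, `end`; default
#'   [default_boundaries()]. Windows must be pairwise non-overlapping and
#'   lie inside the trace span.
#' @param rule `"left"` (default) or `"trapezoid"`.
#' @return Tibble `species`, `area` (absorbance x mm), `fraction`
#'   (of the summed species areas), with attribute `unassigned_area`.
#' @export
integrate_species <- function(trace, boundaries = default_boundaries(),
                              rule = c("left", "trapezoid")) {
  rule <- match.arg(rule)
  check_gradient_trace(trace)
  stopifnot(all(c("species", "start", "end") %in% names(boundaries)))
  if (any(boundaries$start >= boundaries$end)) ptc_abort("Boundary start must be < end")
  srt <- boundaries[order(boundaries$start), ]
  if (nrow(srt) > 1 && any(srt$start[-1] < srt$end[-nrow(srt)])) {
    ptc_abort("Species windows overlap", class = "ptcflex_invalid_boundaries")
  }
  span <- range(trace$distance_mm)
  if (any(boundaries$start < span[1]) || any(boundaries$end > span[2])) {
    ptc_abort("Species window(s) outside the trace span",
              class = "ptcflex_span_mismatch")
  }
  area_fun <- if (rule == "left") riemann_left else trapezoid_area
  areas <- purrr::map2_dbl(boundaries$start, boundaries$end,
                           ~ area_fun(trace$distance_mm, trace$a254, .x, .y))
  total <- sum(areas)
  out <- tibble::tibble(
    species = boundaries$species,
    area = areas,
    fraction = if (total > 0) areas / total else NA_real_
  )
  whole <- area_fun(trace$distance_mm, trace$a254, min(boundaries$start), max(boundaries$end))
  attr(out, "unassigned_area") <- whole - total
  out
}

#' Ribosome assembly ratios from species areas
#'
#' The two summary ratios used to compare assembly states: free subunits
#' (30S + 50S) over assembled particles (70S + polysomes), and 70S over
#' polysomes. Both are invariant under global scaling of the trace.
#'
#' @param areas Tibble from [integrate_species()] (must contain the four
#'   species `30S`, `50S`, `70S`, `polysomes`).
#' @return One-row tibble `ratio_subunits_to_70s_polysomes`,
#'   `ratio_70s_to_polysomes`.
#' @export
assembly_ratios <- function(areas) {
  stopifnot(is.data.frame(areas), all(c("species", "area") %in% names(areas)))
  get <- function(sp) {
    a <- areas$area[areas$species == sp]
    if (length(a) != 1) ptc_abort(sprintf("Missing species '%s' in areas", sp))
    a
  }
  assembled <- get("70S") + get("polysomes")
  tibble::tibble(
    ratio_subunits_to_70s_polysomes =
      if (assembled > 0) (get("30S") + get("50S")) / assembled else NA_real_,
    ratio_70s_to_polysomes =
      if (get("polysomes") > 0) get("70S") / get("polysomes") else NA_real_
  )
}
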