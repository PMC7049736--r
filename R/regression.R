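#' Simple linear regression with slope test
#'
#' Ordinary least squares of `y` on `x` for the study's correlational
#' questions (mutational flexibility against Shannon entropy, flexibility
#' against distance from the tRNA reference points). Reports the slope,
#' intercept, R-squared and a two-sided t test on the slope with n - 2
#' degrees of freedom.
#'
#' @param data Data frame holding the variables.
#' @param x,y Unquoted column names (tidy evaluation).
#' @return Object of class `flex_lm`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, plus the underlying `lm` fit. Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' d <- data.frame(x = 1:5, y = 2 * (1:5) + 1)
#' linear_regression(d, x, y)
#' @export
linear_regression <- function(data, x, y) {
  stopifnot(is.data.frame(data))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) ptc_abort("Regression needs at least 3 complete observations")
  if (stats::var(xv) == 0) {
    ptc_abort("Predictor is constant; slope is undefined",
              class = "ptcflex_constant_predictor")
  }
  fit <- stats::lm(y ~ x, data = list(x = xv, y = yv))
  sm <- summary(fit)
  ## a constant response carries no explainable variance: slope and R^2 are
  ## exactly 0 and the slope test is vacuous (p = 1), independent of
  ## floating-point residue in the solver
  if (stats::var(yv) == 0) {
    slope <- 0; r2 <- 0; p <- 1
  } else {
    slope <- unname(coef(fit)[["x"]])
    r2 <- sm$r.squared
    p <- sm$coefficients["x", 4]
    if (is.nan(p)) p <- 1
  }
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      p_value = p,
      n = n,
      fit = fit
    ),
    class = "flex_lm"
  )
}

#' @export
print.flex_lm <- function(x, ...) {
  cat(sprintf("Linear regression (n = %d): slope %.4g, intercept %.4g, R^2 = %.3f, P = %.3g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' @method tidy flex_lm
#' @export
tidy.flex_lm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @method glance flex_lm
#' @export
glance.flex_lm <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value,
                 slope = x$slope, intercept = x$intercept, n = x$n)
}
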