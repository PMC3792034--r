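# Adult survivorship from destructive daily harvests: cubic fits of the
# fraction alive versus day, and LT50 as the smallest crossing of 0.5.

#' Survivorship series from daily-harvest observations
#'
#' One whole well is harvested per day, so each day's fraction alive is an
#' independent cohort: fraction = live recovered / initially added, with no
#' smoothing. Unequal initial counts between wells are handled per well.
#'
#' @param observations validated longevity table for a single treatment.
#' @return data frame with columns \code{day} and \code{fraction}, in day
#'   order.
#' @export
survivorship_series <- function(observations) {
  validate_longevity(observations)
  if (length(unique(observations$treatment_id)) != 1)
    stop("mixed treatments: build one series at a time", call. = FALSE)
  out <- data.frame(day = observations$day,
                    fraction = observations$n_live / observations$n_initial)
  out[order(out$day), , drop = FALSE]
}

#' Construct a survivorship fit object
#'
#' Usually produced by [fit_survivorship()]; constructing one directly is
#' useful to evaluate published coefficient sets.
#'
#' @param coefficients cubic coefficients (a, b, c, d) for
#'   a day^3 + b day^2 + c day + d, on the fraction-alive scale.
#' @param r_squared coefficient of determination on the raw fractions.
#' @param treatment_id optional label.
#' @param window observed day range c(day_min, day_max).
#' @return an object of class \code{survivorship_fit}.
#' @export
survivorship_fit <- function(coefficients, r_squared = NA_real_,
                             treatment_id = NA_character_,
                             window = c(1, 22)) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 4)
    stop("survivorship cubic needs 4 coefficients", call. = FALSE)
  structure(list(treatment_id = treatment_id, coefficients = coefficients,
                 r_squared = r_squared, window = window),
            class = "survivorship_fit")
}

#' @export
print.survivorship_fit <- function(x, ...) {
  cat("Survivorship cubic",
      if (!is.na(x$treatment_id)) paste0(" (", x$treatment_id, ")"), "\n",
      sep = "")
  cat("  ", format_curve(x), "\n", sep = "")
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Evaluate a survivorship cubic
#'
#' @param fit a \code{survivorship_fit}.
#' @param day days.
#' @return fitted fraction alive (unclamped; values slightly outside [0, 1]
#'   are a diagnostic of the polynomial approximation, not an error).
#' @export
survivorship_value <- function(fit, day) {
  co <- fit$coefficients
  co[1] * day^3 + co[2] * day^2 + co[3] * day + co[4]
}

#' Fit a cubic survivorship curve
#'
#' Ordinary least squares of the fraction alive on day, day^2 and day^3;
#' R-squared is computed on the raw fractions.
#'
#' @param series data frame with \code{day} and \code{fraction}, e.g. from
#'   [survivorship_series()]; at least 4 distinct days.
#' @param treatment_id optional label carried into the fit.
#' @return a \code{survivorship_fit}.
#' @export
fit_survivorship <- function(series, treatment_id = NA_character_) {
  d <- series$day
  y <- series$fraction
  if (length(unique(d)) < 4)
    stop("need at least 4 distinct days for a cubic fit", call. = FALSE)
  ls <- stats::lm.fit(cbind(d^3, d^2, d, 1), y)
  sse <- sum(ls$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    if (sse < 1e-12) 1 else stop("zero variance in fractions with non-zero residuals",
                                 call. = FALSE)
  } else 1 - sse / sst
  survivorship_fit(unname(ls$coefficients), r_squared = r2,
                   treatment_id = treatment_id,
                   window = range(d))
}

#' Estimate the 50%-survival day (LT50)
#'
#' The smallest positive day at which the fitted cubic equals 0.5, by
#' bracketed numeric root-finding to an absolute tolerance of 1e-4 day.
#' Cubics are non-monotone, so later re-crossings are ignored. The search
#' is restricted to the observation window; if the curve never reaches 0.5
#' inside it, \code{NA} is returned ("beyond window") with any extrapolated
#' crossing out to 10x the window recorded in the
#' \code{"extrapolated_lt50"} attribute.
#'
#' @param fit a \code{survivorship_fit}.
#' @param day_max upper bound of the search, default the fitted window's
#'   last day.
#' @return LT50 in days, or \code{NA} when beyond the window.
#' @export
lt50 <- function(fit, day_max = fit$window[2]) {
  stopifnot(inherits(fit, "survivorship_fit"))
  f <- function(x) survivorship_value(fit, x) - 0.5
  root <- smallest_positive_root(f, day_max, tol = 1e-9)
  if (is.na(root)) {
    extra <- smallest_positive_root(f, 10 * day_max, tol = 1e-9)
    return(structure(NA_real_, extrapolated_lt50 = extra))
  }
  root
}
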