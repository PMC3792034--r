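# Concentration-response fitting and LC50 estimation.
#
# Four curve families are fitted to live P0 recovery (animals/well) versus
# sediment nickel concentration (TR-Ni, ug/g dry weight): quadratic and
# cubic polynomials ("binomial"/"trinomial" in the ecotoxicology reporting
# convention), a logarithmic curve a*ln(x) + b, and a shifted exponential
# A*e^(kx) fitted to y + 1 so that an exponential decay never has to cross
# zero. The LC50 is the smallest positive concentration at which the fitted
# curve crosses the half-of-control recovery line; for the shifted
# exponential the target line is raised by 1 onto the fitting scale.

#' The supported concentration-response curve families
#'
#' @return character vector of family names.
#' @export
dose_response_families <- function() {
  c("quadratic", "cubic", "logarithmic", "exponential_shifted")
}

# Reporting-convention aliases accepted wherever a family is named.
resolve_family <- function(family) {
  aliases <- c(binomial = "quadratic", quad = "quadratic",
               trinomial = "cubic", log = "logarithmic",
               exp = "exponential_shifted", exponential = "exponential_shifted")
  family <- as.character(family)
  if (family %in% names(aliases)) family <- unname(aliases[family])
  if (!family %in% dose_response_families())
    stop("unknown curve family '", family, "'", call. = FALSE)
  family
}

n_coefficients <- function(family) {
  switch(family, quadratic = 3L, cubic = 4L,
         logarithmic = 2L, exponential_shifted = 2L)
}

#' Construct a concentration-response fit object
#'
#' Usually produced by [fit_dose_response()]; constructing one directly is
#' useful to evaluate published coefficient sets.
#'
#' @param family curve family: \code{"quadratic"}, \code{"cubic"},
#'   \code{"logarithmic"} or \code{"exponential_shifted"} (aliases
#'   \code{"binomial"}, \code{"trinomial"}, \code{"log"}, \code{"exp"}).
#' @param coefficients numeric vector, highest-order term first: quadratic
#'   (a, b, c) for a x^2 + b x + c; cubic (a, b, c, d); logarithmic (a, b)
#'   for a ln(x) + b; exponential_shifted (A, k) for A e^(kx) on the y + 1
#'   scale, A > 0.
#' @param r_squared coefficient of determination on the fitting scale.
#' @param n number of points fitted.
#' @param x_max largest concentration in the fitted data (used for the
#'   default root-search bound).
#' @return an object of class \code{dose_response_fit}.
#' @export
dose_response_fit <- function(family, coefficients, r_squared = NA_real_,
                              n = NA_integer_, x_max = NA_real_) {
  family <- resolve_family(family)
  k <- n_coefficients(family)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != k)
    stop(family, " family needs ", k, " coefficients", call. = FALSE)
  if (family == "exponential_shifted" && coefficients[1] <= 0)
    stop("exponential_shifted needs A > 0", call. = FALSE)
  if (!is.na(r_squared) && r_squared > 1 + 1e-12)
    stop("r_squared cannot exceed 1", call. = FALSE)
  structure(list(family = family, coefficients = coefficients,
                 r_squared = r_squared, n = n, x_max = x_max,
                 y_target = NA_real_, lc50 = NA_real_),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Concentration-response fit (", x$family, ")\n", sep = "")
  cat("  ", format_curve(x), "\n", sep = "")
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared (fitting scale): %.4f\n", x$r_squared))
  if (!is.na(x$y_target)) cat(sprintf("  target: y = %g\n", x$y_target))
  if (!is.na(x$y_target))
    cat("  LC50: ", if (is.na(x$lc50)) "not attained"
        else sprintf("%.2f ug/g", x$lc50), "\n", sep = "")
  invisible(x)
}

#' Format a fitted curve as an equation string
#'
#' @param fit a \code{dose_response_fit} or \code{survivorship_fit}.
#' @return character scalar, e.g. \code{"y = 5e-07x^2 - 0.0049x + 10.426"}.
#' @export
format_curve <- function(fit) {
  co <- fit$coefficients
  fam <- if (inherits(fit, "survivorship_fit")) "cubic" else fit$family
  poly_str <- function(co) {
    deg <- length(co) - 1
    terms <- vapply(seq_along(co), function(i) {
      p <- deg - i + 1
      v <- co[i]
      s <- if (i == 1) ifelse(v < 0, "-", "") else ifelse(v < 0, " - ", " + ")
      t <- format(abs(v), digits = 6)
      if (p > 1) paste0(s, t, "x^", p) else if (p == 1) paste0(s, t, "x")
      else paste0(s, t)
    }, character(1))
    paste0("y = ", paste(terms, collapse = ""))
  }
  switch(fam,
    quadratic = poly_str(co), cubic = poly_str(co),
    logarithmic = sprintf("y = %sln(x) %s %s", format(co[1], digits = 6),
                          ifelse(co[2] < 0, "-", "+"),
                          format(abs(co[2]), digits = 6)),
    exponential_shifted = sprintf("y + 1 = %se^(%sx)",
                                  format(co[1], digits = 6),
                                  format(co[2], digits = 6)))
}

#' Evaluate a fitted curve on its fitting scale
#'
#' For polynomials and the logarithmic family this is the predicted recovery
#' (animals/well); for the shifted exponential it is the predicted value on
#' the y + 1 scale, \code{A e^(kx)}.
#'
#' @param fit a \code{dose_response_fit}.
#' @param x concentrations (ug/g), > 0 for the logarithmic family.
#' @return numeric vector of fitted values.
#' @export
curve_value <- function(fit, x) {
  co <- fit$coefficients
  switch(fit$family,
    quadratic = co[1] * x^2 + co[2] * x + co[3],
    cubic = co[1] * x^3 + co[2] * x^2 + co[3] * x + co[4],
    logarithmic = co[1] * log(x) + co[2],
    exponential_shifted = co[1] * exp(co[2] * x))
}

#' Build concentration-response points from wells and treatments
#'
#' Joins each well's live-adult count to its treatment's measured TR-Ni.
#' Controls enter at their measured background concentration, so \code{ln(x)}
#' is defined at every dose. Per-well points are used (each well one point),
#' matching the per-well scatter the fits describe; set
#' \code{means = TRUE} for a sensitivity check on treatment means.
#'
#' @param wells validated well table (single species).
#' @param treatments validated treatment table with \code{tr_ni}.
#' @param means fit treatment means instead of per-well points.
#' @return data frame with columns \code{concentration} and \code{response}.
#' @export
dose_response_points <- function(wells, treatments, means = FALSE) {
  validate_wells(wells, treatments)
  conc <- treatments$tr_ni[match(wells$treatment_id, treatments$treatment_id)]
  pts <- data.frame(concentration = conc, response = wells$n_live_adults)
  if (means)
    pts <- stats::aggregate(response ~ concentration, data = pts, FUN = mean)
  if (any(pts$concentration <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  pts
}

#' Fit one concentration-response curve family by least squares
#'
#' Polynomials and the logarithmic curve are ordinary least squares on the
#' raw responses (design in x, or in ln x); the shifted exponential is
#' log-linear least squares of \code{ln(y + 1)} on x, back-transformed to
#' \code{A = e^intercept}, \code{k = slope} — the spreadsheet-trendline
#' convention, on which the raised-by-1 target rule is coherent.
#' \code{r_squared} is computed on the fitting scale (raw y, or
#' \code{ln(y + 1)} for the exponential).
#'
#' @param points data frame with columns \code{concentration} (> 0) and
#'   \code{response} (>= 0), e.g. from [dose_response_points()].
#' @param family curve family, see [dose_response_fit()].
#' @return a \code{dose_response_fit} with LC50 unset.
#' @export
fit_dose_response <- function(points, family) {
  family <- resolve_family(family)
  x <- points$concentration
  y <- points$response
  if (any(x <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (any(y < 0)) stop("responses must be >= 0", call. = FALSE)
  k <- n_coefficients(family)
  if (length(unique(x)) < k)
    stop("need at least ", k, " distinct concentrations for the ",
         family, " family", call. = FALSE)
  design <- switch(family,
    quadratic = cbind(x^2, x, 1),
    cubic = cbind(x^3, x^2, x, 1),
    logarithmic = cbind(log(x), 1),
    exponential_shifted = cbind(x, 1))
  z <- if (family == "exponential_shifted") log(y + 1) else y
  ls <- stats::lm.fit(design, z)
  co <- ls$coefficients
  if (anyNA(co)) stop("singular design: concentrations too degenerate",
                      call. = FALSE)
  sse <- sum(ls$residuals^2)
  sst <- sum((z - mean(z))^2)
  r2 <- if (sst == 0) {
    if (sse < 1e-12) 1 else stop("zero variance in response with non-zero residuals",
                                 call. = FALSE)
  } else 1 - sse / sst
  if (family == "exponential_shifted") co <- c(exp(co[2]), co[1])
  dose_response_fit(family, unname(co), r_squared = r2,
                    n = length(y), x_max = max(x))
}

#' Half-of-control survival target
#'
#' The LC50 target line: half the mean live P0 recovery per control well.
#' With \code{round_target = TRUE} (replication of the published analysis)
#' the target is rounded half-away-from-zero to the nearest whole animal,
#' giving integer target lines such as y = 5, y = 4 or y = 3.
#'
#' @param control_wells validated well table of control wells only.
#' @param round_target round to the nearest integer.
#' @return target recovery, animals/well.
#' @export
control_target <- function(control_wells, round_target = FALSE) {
  validate_wells(control_wells)
  if (nrow(control_wells) < 1) stop("need at least one control well", call. = FALSE)
  m <- mean(control_wells$n_live_adults)
  if (m == 0)
    stop("LC50 undefined without surviving controls", call. = FALSE)
  t <- 0.5 * m
  if (round_target) t <- floor(t + 0.5)  # half away from zero (t > 0 here)
  t
}

smallest_positive_root <- function(f, search_max, tol = 1e-9, grid_n = 8192L) {
  xs <- seq(search_max / grid_n, search_max, length.out = grid_n)
  fx <- f(xs)
  zero <- which(fx == 0)
  hit <- which(fx[-1] * fx[-grid_n] < 0)
  cand <- c(if (length(zero)) xs[zero[1]],
            if (length(hit)) stats::uniroot(f, c(xs[hit[1]], xs[hit[1] + 1]),
                                            tol = tol)$root)
  if (length(cand) == 0) return(NA_real_)
  min(cand)
}

#' Estimate the LC50 by intersection with the target line
#'
#' Returns the smallest positive concentration at which the fitted curve
#' equals \code{y_target}, searching \code{(0, search_max]}. For the shifted
#' exponential the intersection is computed on the fitting scale, i.e.
#' \code{A e^(kx) = y_target + 1}. Quadratic, logarithmic and exponential
#' intersections use closed forms; the cubic uses bracketed numeric
#' root-finding to an absolute tolerance of 1e-6 ug/g.
#'
#' @param fit a \code{dose_response_fit}.
#' @param y_target target recovery (animals/well), e.g. from
#'   [control_target()]; do not pre-shift for the exponential family.
#' @param search_max upper bound of the root search; defaults to 1.5 times
#'   the largest fitted concentration.
#' @return the fit, with \code{y_target} and \code{lc50} set (\code{lc50} is
#'   \code{NA} when the target is not attained in range).
#' @export
lc50 <- function(fit, y_target, search_max = 1.5 * fit$x_max) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (is.na(search_max) || search_max <= 0)
    stop("search_max must be a positive concentration", call. = FALSE)
  co <- fit$coefficients
  root <- switch(fit$family,
    quadratic = {
      roots <- quadratic_roots(co[1], co[2], co[3] - y_target)
      pick_smallest_in_range(roots, search_max)
    },
    cubic = smallest_positive_root(function(x) curve_value(fit, x) - y_target,
                                   search_max, tol = 1e-9),
    logarithmic = {
      x <- exp((y_target - co[2]) / co[1])
      pick_smallest_in_range(x, search_max)
    },
    exponential_shifted = {
      teff <- y_target + 1
      x <- if (teff <= 0 || co[2] == 0) NA_real_ else log(teff / co[1]) / co[2]
      pick_smallest_in_range(x, search_max)
    })
  fit$y_target <- y_target
  fit$lc50 <- root
  fit
}

quadratic_roots <- function(a, b, c) {
  if (a == 0) {
    if (b == 0) return(numeric(0))
    return(-c / b)
  }
  disc <- b^2 - 4 * a * c
  if (disc < 0) return(numeric(0))  # complex roots only: not attained
  sq <- sqrt(disc)
  c((-b - sq) / (2 * a), (-b + sq) / (2 * a))
}

pick_smallest_in_range <- function(x, search_max) {
  x <- x[!is.na(x) & x > 0 & x <= search_max]
  if (length(x) == 0) NA_real_ else min(x)
}

#' Range of polynomial LC50 estimates
#'
#' The reported LC50 range is based on the quadratic and cubic fits only,
#' the families that consistently fit best.
#'
#' @param fits list of \code{dose_response_fit} objects with LC50 set.
#' @return numeric c(low, high) over attained polynomial LC50s, or
#'   \code{c(NA, NA)} when none is attained.
#' @export
lc50_range <- function(fits) {
  vals <- vapply(fits, function(f) {
    if (f$family %in% c("quadratic", "cubic")) f$lc50 else NA_real_
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(c(low = NA_real_, high = NA_real_))
  c(low = min(vals), high = max(vals))
}

#' Screen sediment covariates against mean recovery
#'
#' Ordinary-least-squares fits of per-treatment mean recovery on every
#' subset of up to \code{max_factors} physicochemical covariates, used to
#' ask whether any sediment property beyond the nickel dose tracks recovery.
#' Collinear subsets are flagged and skipped.
#'
#' @param recovery data frame with \code{treatment_id} and a recovery column
#'   (\code{mean_p0_recovery}, as produced by [summarize_endpoints()], or
#'   \code{value}).
#' @param treatments validated treatment table carrying the covariates.
#' @param max_factors largest subset size, 1-3.
#' @param covariates covariate columns to screen.
#' @return data frame of (factors, n_factors, r_squared, flagged), sorted by
#'   r_squared descending; flagged collinear subsets sort last.
#' @export
covariate_screen <- function(recovery, treatments, max_factors = 3,
                             covariates = c("toc", "avs", "cec", "ph", "orp",
                                            "clay", "silt", "sand")) {
  stopifnot(max_factors >= 1, max_factors <= 3)
  ycol <- intersect(c("mean_p0_recovery", "value"), names(recovery))[1]
  if (is.na(ycol)) stop("no recovery column found", call. = FALSE)
  covariates <- intersect(covariates, names(treatments))
  dat <- merge(recovery[, c("treatment_id", ycol)],
               treatments[, c("treatment_id", covariates)],
               by = "treatment_id")
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < max_factors + 2)
    stop("need at least max_factors + 2 treatments with complete covariates",
         call. = FALSE)
  y <- dat[[ycol]]
  rows <- list()
  for (m in seq_len(max_factors)) {
    for (idx in utils::combn(length(covariates), m, simplify = FALSE)) {
      vars <- covariates[idx]
      X <- cbind(1, as.matrix(dat[, vars, drop = FALSE]))
      ls <- stats::lm.fit(X, y)
      flagged <- anyNA(ls$coefficients) || ls$rank < ncol(X)
      r2 <- if (flagged) NA_real_ else {
        sst <- sum((y - mean(y))^2)
        if (sst == 0) 1 else 1 - sum(ls$residuals^2) / sst
      }
      rows[[length(rows) + 1]] <-
        data.frame(factors = paste(vars, collapse = "+"), n_factors = m,
                   r_squared = r2, flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$flagged, -ifelse(is.na(out$r_squared), -Inf, out$r_squared)), ,
      drop = FALSE]
}
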