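# Concentration-response fitting and LC50 estimation.

wb_doses <- c(59.7, 156, 369, 1040, 2680, 7660)
wb_quad <- c(5e-07, -0.0049, 10.426)     # reported high-organic-series fit
wb_cubic <- c(2e-10, -1e-06, -0.0014, 9.6338)

test_that("noiseless points on a known quadratic are recovered exactly", {
  y <- wb_quad[1] * wb_doses^2 + wb_quad[2] * wb_doses + wb_quad[3]
  fit <- fit_dose_response(data.frame(concentration = wb_doses, response = y),
                           "quadratic")
  expect_equal(fit$coefficients, wb_quad, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("every family matches an explicit normal-equations oracle", {
  set.seed(101)
  for (i in 1:10) {
    x <- sort(stats::runif(30, 10, 8000))
    y <- pmax(0, 10 - 0.001 * x + stats::rnorm(30, sd = 1.5))
    pts <- data.frame(concentration = x, response = y)
    expect_equal(fit_dose_response(pts, "quadratic")$coefficients,
                 normal_equations(cbind(x^2, x, 1), y), tolerance = 1e-9)
    expect_equal(fit_dose_response(pts, "cubic")$coefficients,
                 normal_equations(cbind(x^3, x^2, x, 1), y), tolerance = 1e-9)
    expect_equal(fit_dose_response(pts, "logarithmic")$coefficients,
                 normal_equations(cbind(log(x), 1), y), tolerance = 1e-9)
    ce <- normal_equations(cbind(x, 1), log(y + 1))
    expect_equal(fit_dose_response(pts, "exponential_shifted")$coefficients,
                 c(exp(ce[2]), ce[1]), tolerance = 1e-9)
  }
})

test_that("a flat response fits with R-squared 1 and zero slope terms", {
  pts <- data.frame(concentration = wb_doses, response = 7)
  fit <- fit_dose_response(pts, "cubic")
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$coefficients[1:3], rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$coefficients[4], 7, tolerance = 1e-9)
})

test_that("too few distinct concentrations are rejected", {
  pts <- data.frame(concentration = c(10, 10, 20), response = c(5, 6, 7))
  expect_error(fit_dose_response(pts, "cubic"), "at least 4 distinct")
  expect_error(fit_dose_response(pts, "quadratic"), "at least 3 distinct")
})

test_that("reporting-convention family aliases are accepted", {
  pts <- data.frame(concentration = wb_doses, response = 10 - 0.001 * wb_doses)
  expect_equal(fit_dose_response(pts, "binomial")$family, "quadratic")
  expect_equal(fit_dose_response(pts, "trinomial")$family, "cubic")
  expect_equal(fit_dose_response(pts, "log")$family, "logarithmic")
  expect_equal(fit_dose_response(pts, "exp")$family, "exponential_shifted")
})

test_that("the control target is half the mean control recovery", {
  expect_equal(control_target(make_wells(rep(10, 6))), 5)
  # mean 7.9 live/well rounds to a target of 4 in replication mode
  w <- make_wells(c(rep(8, 9), 7))
  expect_equal(mean(w$n_live_adults), 7.9)
  expect_equal(control_target(w, round_target = TRUE), 4)
  # mean 6.2 with rounding off stays 3.1
  w2 <- make_wells(c(8, 8, 8, 8, 6, 6, 6, 6, 3, 3))
  expect_equal(control_target(w2), 3.1)
  expect_error(control_target(make_wells(rep(0, 6))),
               "without surviving controls")
})

test_that("LC50 intersections reproduce the published estimates", {
  q <- lc50(dose_response_fit("quadratic", wb_quad), 5, search_max = 11490)
  expect_equal(q$lc50, 1272.60, tolerance = 1e-5)
  cu <- lc50(dose_response_fit("cubic", wb_cubic), 5, search_max = 11490)
  expect_equal(cu$lc50, 1813.16, tolerance = 1e-5)
  ex <- lc50(dose_response_fit("exponential_shifted", c(8.8914, -3e-04)),
             5, search_max = 11490)  # target raised to 6 internally
  expect_equal(ex$lc50, 1311.08, tolerance = 1e-4)
  lo <- lc50(dose_response_fit("logarithmic", c(-2.314, 20.796)),
             5, search_max = 11490)
  expect_equal(lo$lc50, 921.75, tolerance = 1e-5)
})

test_that("a target equal to the curve at the lowest dose returns that dose", {
  fit <- dose_response_fit("quadratic", wb_quad)
  expect_equal(lc50(fit, curve_value(fit, 59.7), search_max = 11490)$lc50,
               59.7, tolerance = 1e-6)
  lfit <- dose_response_fit("logarithmic", c(-2.314, 20.796))
  expect_equal(lc50(lfit, curve_value(lfit, 100), search_max = 11490)$lc50,
               100, tolerance = 1e-9)
})

test_that("unattainable targets come back as not attained", {
  # upward-opening quadratic that never reaches the target: complex roots
  fit <- dose_response_fit("quadratic", c(1e-6, 0, 8))
  expect_true(is.na(lc50(fit, 5, search_max = 1e4)$lc50))
  # crossing beyond the search range
  fit2 <- dose_response_fit("logarithmic", c(-2.314, 20.796))
  expect_true(is.na(lc50(fit2, 5, search_max = 500)$lc50))
})

test_that("cubic LC50 agrees with an exhaustive grid-scan oracle", {
  for (co in list(wb_cubic, c(-1e-11, 5e-07, -0.0042, 8.0417))) {
    fit <- dose_response_fit("cubic", co)
    tgt <- if (identical(co, wb_cubic)) 5 else 4
    oracle <- grid_root(function(x) curve_value(fit, x) - tgt, 11490,
                        step = 1e-4)
    expect_equal(lc50(fit, tgt, search_max = 11490)$lc50, oracle,
                 tolerance = 1e-3 / oracle)
  }
})

test_that("raising the target lowers the LC50 on a decreasing curve", {
  fit <- dose_response_fit("logarithmic", c(-2.314, 20.796))
  targets <- c(3, 4, 5, 6, 7)
  est <- vapply(targets,
                function(t) lc50(fit, t, search_max = 11490)$lc50, numeric(1))
  expect_true(all(diff(est) < 0))
  qfit <- dose_response_fit("quadratic", wb_quad)
  est_q <- vapply(targets,
                  function(t) lc50(qfit, t, search_max = 11490)$lc50, numeric(1))
  expect_true(all(diff(est_q) < 0))
})

test_that("shifting responses and target by +1 leaves polynomial LC50 unchanged", {
  set.seed(7)
  x <- rep(wb_doses, each = 12)
  y <- stats::rbinom(length(x), 10,
                     pmin(1, pmax(0, 1 - x / 8000)))
  f1 <- fit_dose_response(data.frame(concentration = x, response = y),
                          "quadratic")
  f2 <- fit_dose_response(data.frame(concentration = x, response = y + 1),
                          "quadratic")
  l1 <- lc50(f1, 5, search_max = 11490)$lc50
  l2 <- lc50(f2, 6, search_max = 11490)$lc50
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("the LC50 range covers the polynomial families only", {
  mk <- function(family, co, tgt) lc50(dose_response_fit(family, co), tgt,
                                       search_max = 11490)
  fits <- list(mk("quadratic", wb_quad, 5),
               mk("cubic", wb_cubic, 5),
               mk("logarithmic", c(-2.314, 20.796), 5),
               mk("exponential_shifted", c(8.8914, -3e-04), 5))
  r <- lc50_range(fits)
  expect_equal(unname(r), c(1272.60, 1813.16), tolerance = 1e-5)
  # single fit: degenerate range
  r1 <- lc50_range(fits[1])
  expect_equal(r1[["low"]], r1[["high"]])
  # min/max against a sort oracle over synthetic roots
  synth <- lapply(c(400, 150, 900, 620), function(root)
    lc50(dose_response_fit("quadratic", c(0, -1, 1000 + root)), 1000,
         search_max = 2000))
  expect_equal(unname(lc50_range(synth)), range(c(400, 150, 900, 620)))
  # no attained polynomial LC50
  expect_true(all(is.na(lc50_range(fits[3:4]))))
})

test_that("the covariate screen finds planted signals and flags collinearity", {
  tr <- read_treatment_table(system.file("extdata", "treatments_table1.csv",
                                         package = "nematox"))
  # recovery constructed as an exact linear function of TOC
  rec <- data.frame(treatment_id = tr$treatment_id,
                    value = 2 + 0.7 * tr$toc)
  scr <- covariate_screen(rec, tr, max_factors = 1)
  expect_equal(scr$r_squared[scr$factors == "toc"], 1, tolerance = 1e-9)
  expect_equal(scr$factors[1], "toc")

  # single-factor CEC fit equals the normal-equations oracle
  set.seed(5)
  rec2 <- data.frame(treatment_id = tr$treatment_id,
                     value = 5 + 0.1 * tr$cec + stats::rnorm(8))
  scr2 <- covariate_screen(rec2, tr, max_factors = 1)
  X <- cbind(1, tr$cec)
  beta <- normal_equations(X, rec2$value)
  pred <- X %*% beta
  r2_oracle <- 1 - sum((rec2$value - pred)^2) /
    sum((rec2$value - mean(rec2$value))^2)
  expect_equal(scr2$r_squared[scr2$factors == "cec"], r2_oracle,
               tolerance = 1e-9)

  # permuting the response destroys the planted signal's fit
  set.seed(9)
  best_planted <- max(scr$r_squared, na.rm = TRUE)
  perm_best <- replicate(20, {
    recp <- data.frame(treatment_id = tr$treatment_id,
                       value = sample(rec$value))
    max(covariate_screen(recp, tr, max_factors = 1)$r_squared, na.rm = TRUE)
  })
  expect_true(stats::median(perm_best) < best_planted)

  # an exactly collinear pair is flagged and skipped
  tr2 <- tr; tr2$silt <- 2 * tr2$clay
  scr3 <- covariate_screen(rec, tr2, max_factors = 2)
  expect_true(scr3$flagged[scr3$factors == "clay+silt"])
  expect_true(is.na(scr3$r_squared[scr3$factors == "clay+silt"]))
})
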