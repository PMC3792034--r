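# Stochastic assay simulator with closed-form ground truth.
#
# Emulates the design of the whole-sediment tests: 10 synchronized larvae
# per well, 6 replicate wells per trial and 2 trials per treatment (12
# wells), concentration-dependent binomial developmental survival,
# overdispersed per-adult progeny counts, and destructive daily harvests of
# one well per treatment per day over 22 days for the longevity assays.

#' Simulation configuration
#'
#' The defaults are shaped like the high-organic nickel-spiked sediment
#' series: the dose grid is that series' measured TR-Ni values, 12 wells of
#' 10 larvae per dose, near-complete control survival with a logistic
#' decline around an LC50 of ~1273 ug/g, a modest per-adult progeny rate
#' (sediment assays recover few F1 larvae), and longevity hazards giving
#' 50% survival near days 16/16/7/3 for the four tested treatments.
#'
#' @param seed integer; one global seed, with per-well substreams derived
#'   deterministically from (seed, well index) so records do not depend on
#'   generation order.
#' @param doses TR-Ni concentrations, ug/g dry weight.
#' @param wells_per_dose wells per dose (split into two trials).
#' @param n_added P0 larvae added per well.
#' @param species species label stamped on the wells.
#' @param duration_h test duration stamped on the wells (96 for
#'   C. elegans, 120 for P. pacificus).
#' @param survival_curve list describing P(larva survives to adult) versus
#'   dose. Either \code{list(family = "logistic", p0, lc50, slope)} for
#'   \code{p0 / (1 + (dose/lc50)^slope)}, or \code{list(family =
#'   "polynomial", coefficients)} with coefficients (highest order first) on
#'   the probability scale. Values are clamped to [0, 1]; a curve that
#'   leaves [-0.05, 1.05] at a configured dose is rejected.
#' @param progeny_mean_per_adult expected F1 larvae per recovered live
#'   adult at zero dose.
#' @param progeny_multiplier function(dose) scaling the per-adult rate;
#'   defaults to 1 everywhere (fecundity indices statistically flat across
#'   sediment doses).
#' @param progeny_dispersion variance-to-mean ratio of progeny counts;
#'   1 gives Poisson, the default 2 moderate overdispersion.
#' @param corpse_recovery probability that a dead P0 is recovered (corpse
#'   recovery is incomplete in sediment washes).
#' @param longevity list for the daily-harvest simulator: \code{treatments}
#'   (labels), \code{hazard} (constant daily hazard per treatment, so
#'   S(day) = exp(-h day)), \code{n_initial} (animals loaded per well, per
#'   treatment), \code{days}.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(seed,
                              doses = c(59.7, 156, 369, 1040, 2680, 7660),
                              wells_per_dose = 12L,
                              n_added = 10L,
                              species = "C_elegans",
                              duration_h = 96L,
                              survival_curve = list(family = "logistic",
                                                    p0 = 1.0, lc50 = 1273,
                                                    slope = 1.5),
                              progeny_mean_per_adult = 2.5,
                              progeny_multiplier = function(dose) 1,
                              progeny_dispersion = 2,
                              corpse_recovery = 0.75,
                              longevity = list(
                                treatments = c("WB-0", "WB-2", "WB-3", "WB-5"),
                                hazard = log(2) / c(16, 16, 7, 3),
                                n_initial = c(55, 75, 75, 55),
                                days = 1:22)) {
  stopifnot(length(seed) == 1, seed == round(seed),
            all(doses > 0), wells_per_dose >= 1, n_added >= 1,
            progeny_mean_per_adult >= 0, progeny_dispersion >= 1,
            corpse_recovery >= 0, corpse_recovery <= 1)
  cfg <- list(seed = as.integer(seed), doses = doses,
              wells_per_dose = as.integer(wells_per_dose),
              n_added = as.integer(n_added), species = species,
              duration_h = duration_h, survival_curve = survival_curve,
              progeny_mean_per_adult = progeny_mean_per_adult,
              progeny_multiplier = progeny_multiplier,
              progeny_dispersion = progeny_dispersion,
              corpse_recovery = corpse_recovery,
              longevity = longevity)
  class(cfg) <- "simulation_config"
  # reject curves that leave the probability scale at configured doses
  invisible(vapply(doses, function(d) survival_prob(cfg, d), numeric(1)))
  cfg
}

#' Survival probability at a dose
#'
#' Evaluates the configured survival curve, clamped to [0, 1]. Raw values
#' outside [-0.05, 1.05] indicate a mis-specified curve and are rejected.
#'
#' @param config a \code{simulation_config}.
#' @param dose TR-Ni, ug/g.
#' @return probability in [0, 1].
#' @export
survival_prob <- function(config, dose) {
  sc <- config$survival_curve
  raw <- switch(sc$family,
    logistic = sc$p0 / (1 + (dose / sc$lc50)^sc$slope),
    polynomial = {
      co <- sc$coefficients
      deg <- length(co) - 1
      sum(co * dose^(deg:0))
    },
    stop("unknown survival curve family '", sc$family, "'", call. = FALSE))
  if (raw < -0.05 || raw > 1.05)
    stop(sprintf("survival curve leaves [0, 1] at dose %g (value %.3f)",
                 dose, raw), call. = FALSE)
  min(max(raw, 0), 1)
}

# Deterministic per-stream seed below 2^31, derived from (seed, indices).
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (i in idx) s <- (s * 48271 + i * 97003 + 1) %% 2147483647
  as.integer(s)
}

#' Simulate a whole-sediment assay
#'
#' Per well: live adults ~ Binomial(n_added, p(dose)); recovered dead ~
#' Binomial(n_added - live, corpse_recovery); progeny drawn with mean =
#' live x per-adult rate and the configured variance-to-mean ratio
#' (negative binomial; Poisson when the ratio is 1). The first half of each
#' dose's wells is tagged trial "t1", the second "t2". Fully reproducible
#' from the seed.
#'
#' @param config a \code{simulation_config}.
#' @return validated well table (see [read_well_table()] for the columns).
#' @export
simulate_sediment_assay <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lambda0 <- config$progeny_mean_per_adult
  phi <- config$progeny_dispersion
  wpd <- config$wells_per_dose
  n_wells <- length(config$doses) * wpd
  live <- dead <- progeny <- integer(n_wells)
  widx <- 0L
  for (di in seq_along(config$doses)) {
    dose <- config$doses[di]
    p <- survival_prob(config, dose)
    lam <- lambda0 * config$progeny_multiplier(dose)
    for (wi in seq_len(wpd)) {
      widx <- widx + 1L
      set.seed(substream_seed(config$seed, widx))
      live[widx] <- stats::rbinom(1, config$n_added, p)
      dead[widx] <- stats::rbinom(1, config$n_added - live[widx],
                                  config$corpse_recovery)
      mu <- live[widx] * lam
      progeny[widx] <- if (mu == 0) 0L else if (phi == 1)
        stats::rpois(1, mu) else
        as.integer(stats::rnbinom(1, size = mu / (phi - 1), mu = mu))
    }
  }
  di <- rep(seq_along(config$doses), each = wpd)
  wi <- rep(seq_len(wpd), times = length(config$doses))
  wells <- data.frame(
    well_id = sprintf("d%02dw%02d", di, wi),
    treatment_id = sprintf("D%d", di),
    species = config$species,
    trial_id = ifelse(wi <= ceiling(wpd / 2), "t1", "t2"),
    n_added = config$n_added, n_live_adults = live, n_dead = dead,
    n_progeny = progeny, duration_h = config$duration_h,
    stringsAsFactors = FALSE)
  validate_wells(wells)
  wells
}

#' Treatment table matching a simulated assay
#'
#' One sediment treatment per configured dose, labelled as the simulator
#' labels its wells, with TR-Ni equal to the dose. Dose 1 is the un-spiked
#' control (its dose plays the role of measured background TR-Ni).
#'
#' @param config a \code{simulation_config}.
#' @return validated treatment table.
#' @export
simulated_treatments <- function(config) {
  tr <- data.frame(
    treatment_id = sprintf("D%d", seq_along(config$doses)),
    sediment_id = "SIM",
    spike_level = pmin(seq_along(config$doses) - 1L, 5L),
    medium = "sediment",
    tr_ni = config$doses,
    stringsAsFactors = FALSE)
  validate_treatments(tr)
  tr
}

#' Simulate destructive daily-harvest longevity series
#'
#' Each day's well is an independent cohort: live recovered ~
#' Binomial(n_initial, exp(-hazard x day)). Reproducible from the seed.
#'
#' @param config a \code{simulation_config}.
#' @return validated longevity table.
#' @export
simulate_longevity <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lg <- config$longevity
  rows <- list()
  for (ti in seq_along(lg$treatments)) {
    for (day in lg$days) {
      set.seed(substream_seed(config$seed, 1000L + ti, day))
      s <- exp(-lg$hazard[ti] * day)
      rows[[length(rows) + 1]] <- data.frame(
        treatment_id = lg$treatments[ti], day = day,
        n_initial = lg$n_initial[ti],
        n_live = stats::rbinom(1, lg$n_initial[ti], s),
        stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, rows)
  validate_longevity(obs)
  obs
}

#' Ground-truth LC50 of a simulation configuration
#'
#' The dose at which the configured survival curve falls to half its dose-0
#' value. For the logistic family this inverts algebraically to the curve's
#' \code{lc50} parameter; for a polynomial curve the target (half the
#' intercept) is handed to the same root-finder the analysis uses, applied
#' to the true coefficients.
#'
#' @param config a \code{simulation_config}.
#' @param search_max upper bound for the polynomial root search; defaults
#'   to 1.5x the largest configured dose.
#' @return dose in ug/g, or \code{NA} if the half-of-control level is never
#'   attained.
#' @export
true_lc50 <- function(config, search_max = 1.5 * max(config$doses)) {
  sc <- config$survival_curve
  if (sc$family == "logistic") return(sc$lc50)
  co <- sc$coefficients
  family <- switch(as.character(length(co)), "3" = "quadratic", "4" = "cubic",
                   stop("polynomial truth needs 3 or 4 coefficients",
                        call. = FALSE))
  fit <- dose_response_fit(family, co, x_max = max(config$doses))
  lc50(fit, y_target = 0.5 * co[length(co)], search_max = search_max)$lc50
}
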