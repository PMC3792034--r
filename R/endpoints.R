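# Per-well and per-treatment assay endpoints: P0 recovery, F1 progeny,
# fecundity index. The well, not the animal, is the unit of replication.

#' Per-well fecundity index
#'
#' Recovered F1 progeny per recovered live P0 adult, one ratio per well.
#' Wells with no surviving adults and no progeny score 0 (nothing was
#' produced); wells with progeny but no recovered adults have no denominator
#' and are undefined (\code{NA}) — they are excluded from downstream group
#' tests rather than treated as infinite.
#'
#' @param wells validated well table, or a data frame with columns
#'   \code{n_progeny} and \code{n_live_adults}.
#' @param zero_recovery how to score wells with 0 live adults and 0 progeny:
#'   \code{"zero"} (default) contributes an index of 0, \code{"exclude"}
#'   drops them (\code{NA}).
#' @return numeric vector of per-well indices, \code{NA} where undefined.
#' @export
fecundity_index <- function(wells, zero_recovery = c("zero", "exclude")) {
  zero_recovery <- match.arg(zero_recovery)
  live <- wells$n_live_adults
  prog <- wells$n_progeny
  idx <- ifelse(live > 0, prog / live, NA_real_)
  both_zero <- live == 0 & prog == 0
  if (zero_recovery == "zero") idx[both_zero] <- 0
  n_undef <- sum(live == 0 & prog > 0)
  if (n_undef > 0)
    message(n_undef, " well(s) with progeny but no recovered adults: ",
            "fecundity index undefined, excluded from group tests")
  idx
}

#' Summarize one treatment's endpoint values
#'
#' Means are taken over wells; the per-well fecundity indices are retained
#' so that downstream ANOVA uses n = number of wells, each well a single
#' data point.
#'
#' @param wells validated well table, all rows one treatment and species.
#' @param zero_recovery passed to [fecundity_index()].
#' @return an object of class \code{endpoint_summary}: a list with
#'   \code{treatment_id}, \code{species}, \code{n_wells},
#'   \code{mean_p0_recovery} (live adults/well), \code{mean_p0_fraction}
#'   (proportion of added larvae recovered live), \code{mean_progeny}
#'   (larvae/well) and \code{fecundity_indices} (one ratio per well).
#' @export
summarize_treatment <- function(wells, zero_recovery = c("zero", "exclude")) {
  validate_wells(wells)
  if (nrow(wells) < 1) stop("need at least one well", call. = FALSE)
  if (length(unique(wells$treatment_id)) != 1)
    stop("mixed treatments: summarize one treatment at a time", call. = FALSE)
  if (length(unique(wells$species)) != 1)
    stop("mixed species: summarize one species at a time", call. = FALSE)
  out <- list(
    treatment_id = wells$treatment_id[1],
    species = wells$species[1],
    n_wells = nrow(wells),
    mean_p0_recovery = mean(wells$n_live_adults),
    mean_p0_fraction = mean(wells$n_live_adults / wells$n_added),
    mean_progeny = mean(wells$n_progeny),
    fecundity_indices = suppressMessages(fecundity_index(wells, zero_recovery))
  )
  class(out) <- "endpoint_summary"
  out
}

#' @export
print.endpoint_summary <- function(x, ...) {
  cat(sprintf("Endpoint summary: %s, %s (%d wells)\n",
              x$treatment_id, x$species, x$n_wells))
  cat(sprintf("  mean P0 recovery : %.3f live adults/well (fraction %.3f)\n",
              x$mean_p0_recovery, x$mean_p0_fraction))
  cat(sprintf("  mean F1 progeny  : %.3f larvae/well\n", x$mean_progeny))
  def <- x$fecundity_indices[!is.na(x$fecundity_indices)]
  cat(sprintf("  fecundity index  : mean %.3f over %d defined wells\n",
              if (length(def)) mean(def) else NA_real_, length(def)))
  invisible(x)
}

#' Summarize endpoints for every treatment-by-species group
#'
#' @param wells validated well table.
#' @param zero_recovery passed to [fecundity_index()].
#' @return data frame, one row per treatment x species, with the summary
#'   means plus \code{mean_fecundity_index} over defined wells.
#' @export
summarize_endpoints <- function(wells, zero_recovery = c("zero", "exclude")) {
  validate_wells(wells)
  groups <- unique(wells[, c("treatment_id", "species")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- wells[wells$treatment_id == groups$treatment_id[i] &
                 wells$species == groups$species[i], ]
    s <- summarize_treatment(sub, zero_recovery)
    def <- s$fecundity_indices[!is.na(s$fecundity_indices)]
    data.frame(treatment_id = s$treatment_id, species = s$species,
               n_wells = s$n_wells, mean_p0_recovery = s$mean_p0_recovery,
               mean_p0_fraction = s$mean_p0_fraction,
               mean_progeny = s$mean_progeny,
               mean_fecundity_index = if (length(def)) mean(def) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-well endpoint values grouped by treatment
#'
#' Extracts the per-well values of one endpoint for group comparisons.
#' Undefined fecundity indices are dropped listwise.
#'
#' @param wells validated well table (single species).
#' @param endpoint one of \code{"p0_recovery"} (live adults/well),
#'   \code{"progeny"} (F1 larvae/well) or \code{"fecundity_index"}.
#' @param zero_recovery passed to [fecundity_index()].
#' @return data frame with columns \code{treatment_id} and \code{value}.
#' @export
endpoint_values <- function(wells,
                            endpoint = c("p0_recovery", "progeny",
                                         "fecundity_index"),
                            zero_recovery = c("zero", "exclude")) {
  endpoint <- match.arg(endpoint)
  validate_wells(wells)
  value <- switch(endpoint,
    p0_recovery = wells$n_live_adults,
    progeny = wells$n_progeny,
    fecundity_index = suppressMessages(fecundity_index(wells, zero_recovery)))
  out <- data.frame(treatment_id = wells$treatment_id, value = value,
                    stringsAsFactors = FALSE)
  out[!is.na(out$value), ]
}
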