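# Domain tables: well-level bioassay counts, treatment chemistry,
# daily-harvest longevity series. All readers validate on load and fail
# naming the offending row and field.

#' @keywords internal
species_levels <- function() c("C_elegans", "P_pacificus")

well_table_columns <- function() {
  c("well_id", "treatment_id", "species", "trial_id", "n_added",
    "n_live_adults", "n_dead", "n_progeny", "duration_h")
}

longevity_columns <- function() {
  c("treatment_id", "day", "n_initial", "n_live")
}

stop_row <- function(row, field, msg) {
  stop(sprintf("row %d, field '%s': %s", row, field, msg), call. = FALSE)
}

check_count <- function(x, row, field) {
  if (is.na(x)) stop_row(row, field, "count is missing or malformed")
  if (x < 0) stop_row(row, field, "count is negative")
  if (x != round(x)) stop_row(row, field, "count is not an integer")
  invisible(TRUE)
}

#' Validate a table of well outcomes
#'
#' Checks the invariants of well-level assay records: all counts are
#' non-negative integers, no more live adults are recovered than larvae were
#' added, and live plus dead recovered never exceeds the number added (corpse
#' recovery is incomplete, so the sum may fall short). Species labels must be
#' one of \code{"C_elegans"} or \code{"P_pacificus"}.
#'
#' @param wells data frame with columns \code{well_id}, \code{treatment_id},
#'   \code{species}, \code{trial_id}, \code{n_added}, \code{n_live_adults},
#'   \code{n_dead}, \code{n_progeny}, \code{duration_h}.
#' @param treatments optional treatment table (see
#'   \code{\link{read_treatment_table}}); when supplied, every
#'   \code{treatment_id} must appear in it.
#' @return `wells`, invisibly, if valid; otherwise an error naming the first
#'   offending row and field.
#' @export
validate_wells <- function(wells, treatments = NULL) {
  missing_cols <- setdiff(well_table_columns(), names(wells))
  if (length(missing_cols) > 0)
    stop("well table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(wells))) {
    sp <- wells$species[i]
    if (!sp %in% species_levels())
      stop_row(i, "species", paste0("unknown species '", sp, "'"))
    for (f in c("n_added", "n_live_adults", "n_dead", "n_progeny"))
      check_count(wells[[f]][i], i, f)
    if (wells$n_live_adults[i] > wells$n_added[i])
      stop_row(i, "n_live_adults", "live exceeds added")
    if (wells$n_live_adults[i] + wells$n_dead[i] > wells$n_added[i])
      stop_row(i, "n_dead", "live + dead exceeds added")
    if (!is.null(treatments) &&
        !wells$treatment_id[i] %in% treatments$treatment_id)
      stop_row(i, "treatment_id",
               paste0("unknown treatment '", wells$treatment_id[i], "'"))
  }
  invisible(wells)
}

#' Read a well-outcome table from CSV
#'
#' One row per test well: counts of P0 larvae added, live P0 adults
#' recovered, dead P0 recovered and F1 progeny recovered, plus identifying
#' labels. Row order is preserved.
#'
#' @inheritParams validate_wells
#' @param path path to a CSV file with a header row.
#' @return validated data frame of well outcomes.
#' @export
read_well_table <- function(path, treatments = NULL) {
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_wells(wells, treatments)
  wells
}

#' Write a well-outcome table to CSV
#'
#' Writes the canonical CSV dialect read by \code{\link{read_well_table}}
#' (header row, no quoting, no row names). \code{write_well_table} followed
#' by \code{read_well_table} round-trips byte-identically.
#'
#' @param wells validated well table.
#' @param path output path.
#' @export
write_well_table <- function(wells, path) {
  validate_wells(wells)
  utils::write.csv(wells[, well_table_columns()], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export validated records as JSON
#'
#' @param x a validated data frame (well, treatment or longevity table).
#' @param path output path.
#' @export
write_records_json <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a treatment chemistry table
#'
#' A treatment is one sediment or water condition: an identifying label, the
#' nickel spike level (0 = un-spiked control), measured total-recoverable
#' nickel (TR-Ni, ug/g dry weight), optionally pore-water or overlying-water
#' nickel (ug/L), and optional physicochemical covariates (TOC, AVS, CEC,
#' pH, ORP, particle-size fractions, log Kd). Invariants: sediment
#' treatments carry a strictly positive TR-Ni — un-spiked controls carry
#' their measured background concentration, never 0, so logarithmic
#' concentration-response fits are defined at every dose — and particle-size
#' fractions sum to 98--102 when all three are present.
#'
#' @param treatments data frame with at least \code{treatment_id},
#'   \code{medium} (\code{"sediment"} or \code{"water"}), \code{spike_level}
#'   and \code{tr_ni}.
#' @return `treatments`, invisibly, if valid.
#' @export
validate_treatments <- function(treatments) {
  for (col in c("treatment_id", "medium", "spike_level", "tr_ni"))
    if (!col %in% names(treatments))
      stop("treatment table is missing column: ", col, call. = FALSE)
  for (i in seq_len(nrow(treatments))) {
    if (!treatments$medium[i] %in% c("sediment", "water"))
      stop_row(i, "medium", "must be 'sediment' or 'water'")
    sl <- treatments$spike_level[i]
    if (is.na(sl) || sl != round(sl) || sl < 0 || sl > 5)
      stop_row(i, "spike_level", "must be an integer 0-5")
    if (treatments$medium[i] == "sediment" &&
        (is.na(treatments$tr_ni[i]) || treatments$tr_ni[i] <= 0))
      stop_row(i, "tr_ni",
               "sediment treatments need TR-Ni > 0 (controls carry measured background)")
    psf <- c(treatments$clay[i], treatments$silt[i], treatments$sand[i])
    if (length(psf) == 3 && !anyNA(psf)) {
      s <- sum(psf)
      if (s < 98 || s > 102)
        stop_row(i, "clay", sprintf("particle-size fractions sum to %.1f, outside [98, 102]", s))
    }
  }
  invisible(treatments)
}

#' Read a treatment chemistry table from CSV
#'
#' Numeric fields are parsed; missing optional covariates are kept as
#' \code{NA} (explicitly absent, never 0).
#'
#' @param path path to a CSV file with a header row.
#' @return validated data frame of treatment specifications.
#' @seealso [validate_treatments()] for the fields and invariants;
#'   packaged fixtures \code{treatments_table1.csv} (un-spiked sediments)
#'   and \code{treatments_table4.csv} (nickel-spiked series) under
#'   \code{system.file("extdata", package = "nematox")}.
#' @export
read_treatment_table <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_treatments(tr)
  tr
}

#' Is a treatment an un-spiked control?
#'
#' @param treatments treatment table.
#' @return logical vector, \code{TRUE} where \code{spike_level == 0}.
#' @export
is_control <- function(treatments) treatments$spike_level == 0

#' Read a supporting chemistry table (pore-water constituents, trace elements)
#'
#' These tables carry censored cells printed as \code{"<limit"} and absent
#' cells printed as \code{"-"}. Both parse to \code{NA}; censored cells are
#' additionally recorded in the \code{"censored"} attribute as a data frame
#' of (row, column, detection limit).
#'
#' @param path path to a CSV file; first column is the sample label.
#' @return data frame of numeric values with a \code{"censored"} attribute.
#' @export
read_chemistry_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  out <- raw
  cens <- data.frame(row = integer(), column = character(),
                     limit = numeric(), stringsAsFactors = FALSE)
  for (j in seq_along(raw)[-1]) {
    v <- trimws(raw[[j]])
    num <- suppressWarnings(as.numeric(v))
    below <- grepl("^<", v)
    if (any(below)) {
      lim <- as.numeric(sub("^<", "", v[below]))
      cens <- rbind(cens, data.frame(row = which(below),
                                     column = names(raw)[j],
                                     limit = lim, stringsAsFactors = FALSE))
    }
    num[below | v == "-" | v == ""] <- NA_real_
    bad <- is.na(num) & !(below | v == "-" | v == "")
    if (any(bad))
      stop_row(which(bad)[1], names(raw)[j], "malformed numeric cell")
    out[[j]] <- num
  }
  attr(out, "censored") <- cens
  out
}

#' Validate a longevity (destructive daily harvest) table
#'
#' One whole well is harvested per treatment per day, so each (treatment,
#' day) pair appears at most once and each day's fraction alive comes from
#' an independent cohort. Days run 1--22; recovered live counts cannot
#' exceed the number initially added to that well.
#'
#' @param observations data frame with columns \code{treatment_id},
#'   \code{day}, \code{n_initial}, \code{n_live}.
#' @return `observations`, invisibly, if valid.
#' @export
validate_longevity <- function(observations) {
  missing_cols <- setdiff(longevity_columns(), names(observations))
  if (length(missing_cols) > 0)
    stop("longevity table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  key <- paste(observations$treatment_id, observations$day)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (treatment, day) observation: ", d,
         " - destructive sampling allows one well per day", call. = FALSE)
  }
  for (i in seq_len(nrow(observations))) {
    d <- observations$day[i]
    if (is.na(d) || d != round(d) || d < 1 || d > 22)
      stop_row(i, "day", "must be an integer 1-22")
    check_count(observations$n_initial[i], i, "n_initial")
    check_count(observations$n_live[i], i, "n_live")
    if (observations$n_live[i] > observations$n_initial[i])
      stop_row(i, "n_live", "live exceeds initially added")
  }
  invisible(observations)
}

#' Read a longevity table from CSV
#'
#' @param path path to a CSV file with a header row.
#' @return validated data frame of daily-harvest observations.
#' @export
read_longevity_table <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_longevity(obs)
  obs
}
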