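# Readers, writers and validation for the three input tables.

test_that("well rows map directly onto validated records", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well_id,treatment_id,species,trial_id,n_added,n_live_adults,n_dead,n_progeny,duration_h",
               "w1,WB-0,C_elegans,t1,10,10,0,25,96"), path)
  wells <- read_well_table(path)
  expect_equal(nrow(wells), 1)
  expect_equal(wells$n_added, 10)
  expect_equal(wells$n_live_adults, 10)
  expect_equal(wells$n_progeny, 25)
  expect_equal(wells$species, "C_elegans")
})

test_that("invariant violations are rejected naming row and field", {
  expect_error(validate_wells(make_wells(11, n_added = 10)),
               "live exceeds added")
  expect_error(validate_wells(make_wells(8, n_added = 10, n_dead = 4)),
               "live \\+ dead exceeds added")
  expect_error(validate_wells(make_wells(-1)), "negative")
  expect_error(validate_wells(make_wells(2.5)), "not an integer")
  w <- make_wells(5); w$species <- "C_briggsae"
  expect_error(validate_wells(w), "unknown species")
  # error messages locate the offender
  w2 <- make_wells(c(3, 11, 2))
  expect_error(validate_wells(w2), "row 2, field 'n_live_adults'")
})

test_that("treatment cross-check rejects unknown treatment ids", {
  tr <- read_treatment_table(system.file("extdata", "treatments_table4.csv",
                                         package = "nematox"))
  ok <- make_wells(c(10, 9), treatment_id = "WB-0")
  expect_silent(validate_wells(ok, tr))
  bad <- make_wells(5, treatment_id = "XX-9")
  expect_error(validate_wells(bad, tr), "unknown treatment 'XX-9'")
})

test_that("a 12-well treatment file loads as 12 records under one treatment", {
  wells <- make_wells(rep(c(6, 7, 5, 6, 8, 6), 2), treatment_id = "SR-0",
                      species = "P_pacificus",
                      trial_id = rep(c("t1", "t2"), each = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_well_table(wells, path)
  got <- read_well_table(path)
  expect_equal(nrow(got), 12)
  expect_equal(unique(got$treatment_id), "SR-0")
  expect_equal(got$n_live_adults, wells$n_live_adults)
})

test_that("well tables round-trip byte-identically through write/read/write", {
  wells <- make_wells(c(10, 9, 10, 8), n_progeny = c(25, 12, 30, 0),
                      treatment_id = "WB-2")
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_well_table(wells, p1)
  write_well_table(read_well_table(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("packaged spiked-series fixture reproduces the reported chemistry", {
  tr <- read_treatment_table(system.file("extdata", "treatments_table4.csv",
                                         package = "nematox"))
  expect_equal(nrow(tr), 12)
  wb5 <- tr[tr$treatment_id == "WB-5", ]
  expect_equal(wb5$tr_ni, 7660)
  expect_equal(wb5$ow_ni, 122)
  sr0 <- tr[tr$treatment_id == "SR-0", ]
  expect_equal(sr0$tr_ni, 8.9)
  expect_equal(sr0$ow_ni, 1.70)
  # controls carry measured background TR-Ni, never zero
  expect_true(all(tr$tr_ni[is_control(tr)] > 0))
  expect_equal(tr$tr_ni[tr$treatment_id == "WB-0"], 59.7)
  # spike levels double roughly; spot-check WB series ordering
  wb <- tr[tr$sediment_id == "WB", ]
  expect_true(all(diff(wb$tr_ni) > 0))
  # particle-size fractions close on every row
  expect_true(all(abs(tr$clay + tr$silt + tr$sand - 100) <= 2))
})

test_that("packaged un-spiked fixture covers all eight sediments", {
  tr <- read_treatment_table(system.file("extdata", "treatments_table1.csv",
                                         package = "nematox"))
  expect_equal(nrow(tr), 8)
  expect_setequal(tr$sediment_id,
                  c("SR", "STJ", "P30", "DOW", "RR2", "STM", "RR3", "WB"))
  expect_equal(tr$toc[tr$sediment_id == "WB"], 10.40)
  expect_equal(tr$avs[tr$sediment_id == "STM"], 24.70)
  expect_equal(tr$cec[tr$sediment_id == "WB"], 44.1)
  expect_equal(tr$tr_ni[tr$sediment_id == "DOW"], 6)
  expect_true(all(is_control(tr)))
})

test_that("non-positive TR-Ni and bad spike levels are rejected", {
  tr <- read_treatment_table(system.file("extdata", "treatments_table1.csv",
                                         package = "nematox"))
  bad <- tr; bad$tr_ni[1] <- 0
  expect_error(validate_treatments(bad), "TR-Ni > 0")
  bad2 <- tr; bad2$spike_level[2] <- 7
  expect_error(validate_treatments(bad2), "integer 0-5")
  bad3 <- tr; bad3$clay[1] <- 50
  expect_error(validate_treatments(bad3), "outside \\[98, 102\\]")
})

test_that("chemistry tables parse absent and censored cells as explicit NA", {
  el <- read_chemistry_table(system.file("extdata", "elements_table3.csv",
                                         package = "nematox"))
  # absent barium for the SR sediment is NA, not 0
  expect_true(is.na(el$ba[el$sample == "SR"]))
  expect_equal(el$al[el$sample == "STJ"], 7212)
  expect_equal(el$zn[el$sample == "WB"], 141.1)
  cens <- attr(el, "censored")
  expect_true(all(cens$limit == 1000))
  expect_true(all(cens$column == "na"))
  pw <- read_chemistry_table(system.file("extdata", "porewater_table2.csv",
                                         package = "nematox"))
  expect_equal(pw$ca[pw$sample == "STM"], 348)
  expect_true(is.na(pw$no3[pw$sample == "SR"]))
  expect_equal(sum(attr(pw, "censored")$limit == 0.08), nrow(attr(pw, "censored")))
})

test_that("longevity tables enforce destructive-sampling uniqueness and bounds", {
  obs <- data.frame(treatment_id = "WB-0", day = c(1, 2, 2),
                    n_initial = 55, n_live = c(55, 50, 49))
  expect_error(validate_longevity(obs), "duplicate \\(treatment, day\\)")
  obs2 <- data.frame(treatment_id = "WB-0", day = c(1, 23),
                     n_initial = 55, n_live = c(55, 1))
  expect_error(validate_longevity(obs2), "integer 1-22")
  obs3 <- data.frame(treatment_id = "WB-0", day = 1:2,
                     n_initial = 55, n_live = c(56, 3))
  expect_error(validate_longevity(obs3), "live exceeds initially added")
})
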