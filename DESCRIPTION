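Package: nematox
Title: Nickel Toxicity Analysis for Whole-Sediment Nematode Bioassays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-sediment and water-only nickel
    toxicity bioassays with the nematodes Caenorhabditis elegans and
    Pristionchus pacificus. Validates well-level assay records, computes
    developmental-survival and fecundity endpoints, fits quadratic, cubic,
    logarithmic and shifted-exponential concentration-response curves with
    LC50 estimation by intersection with half-of-control survival, fits
    cubic survivorship-versus-day curves from destructive daily harvests
    with LT50 estimation, compares treatment groups by one-way ANOVA with
    Tukey HSD and compact letter displays, and simulates assay data with
    known ground truth for parameter-recovery checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
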