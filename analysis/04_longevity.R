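#!/usr/bin/env Rscript
# Adult survivorship: cubic fits of fraction alive versus day for each
# simulated longevity treatment, with the 50%-survival day.

suppressPackageStartupMessages(library(nematox))

obs <- read_longevity_table("results/sim_longevity.csv")

tab <- do.call(rbind, lapply(split(obs, obs$treatment_id), function(o) {
  fit <- fit_survivorship(survivorship_series(o), o$treatment_id[1])
  day50 <- lt50(fit)
  data.frame(treatment = fit$treatment_id, formula = format_curve(fit),
             day_at_50pct = if (is.na(day50)) NA else round(day50, 3),
             r_squared = round(fit$r_squared, 4), stringsAsFactors = FALSE)
}))
utils::write.csv(tab, "results/survivorship_fits.csv", row.names = FALSE)
print(tab, right = FALSE, row.names = FALSE)
cat("wrote results/survivorship_fits.csv\n")
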