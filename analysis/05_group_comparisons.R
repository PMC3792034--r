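#!/usr/bin/env Rscript
# Treatment group comparisons on the simulated campaign: one-way ANOVA with
# Tukey HSD and compact letter displays for each endpoint.

suppressPackageStartupMessages(library(nematox))

treatments <- read_treatment_table("results/sim_treatments.csv")
wells <- read_well_table("results/sim_wells.csv", treatments)

letters_out <- list()
for (ep in c("p0_recovery", "progeny", "fecundity_index")) {
  gc <- compare_groups(wells, ep, alpha = 0.05)
  print(gc)
  utils::write.csv(as.data.frame(gc$pairwise),
                   sprintf("results/tukey_%s.csv", ep))
  letters_out[[ep]] <- as.list(gc$letters)
}
jsonlite::write_json(letters_out, "results/group_letters.json",
                     auto_unbox = TRUE, pretty = TRUE)
cat("wrote results/tukey_<endpoint>.csv and results/group_letters.json\n")
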