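#!/usr/bin/env Rscript
# Stage 1: simulate a measurement cohort in the deposited raw layout.
#
# Generates an H460-preset cohort of 300 cells at the default acquisition
# settings (200 fps camera, 25 points/s impedance, 0.5-1.2 kPa pressure,
# 1% amplitude noise, 0.25 um length noise), writes one seven-column CSV
# per cell under results/raw/H460/ plus the ground-truth table used later
# for parameter-recovery scoring. Draws whose pressure-to-modulus ratio
# falls outside the entry model's ordered-length domain are skipped with a
# reason, mirroring cells a real experiment cannot analyse.

suppressPackageStartupMessages(library(squeezecyto))

cfg <- cohort_config(n_cells = 300, seed = 20170215, line = "H460")
sim <- simulate_cohort(cfg)

dir.create("results/raw/H460", showWarnings = FALSE, recursive = TRUE)
write_raw_records(sim$cells, "results/raw/H460")
data.table::fwrite(sim$truth, "results/truth_H460.csv")
data.table::fwrite(sim$skipped, "results/skipped_H460.csv")

cat(sprintf("simulated %d cells (%d draws infeasible under the entry model)\n",
            length(sim$cells), nrow(sim$skipped)))
if (nrow(sim$skipped) > 0)
  print(table(sub(":.*$", "", sim$skipped$reason)))
cat("raw streams in results/raw/H460/, ground truth in results/truth_H460.csv\n")
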