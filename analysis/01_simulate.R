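#!/usr/bin/env Rscript
# Step 1: generate the synthetic study.
#
# Emulates the full measurement campaign on the breathing simulator: four
# dry powder inhalers, 12 repeated maneuvers each, with a characterization
# arm (no airway model in the path) and a respiration arm (upper-airway
# filter + lung retention), plus ambient background spectra. Every file is
# delimited text indexed by manifest.csv; the tree is byte-reproducible for
# a fixed seed.

library(aerodepo)

seed <- 1
dir <- "results/study"

design <- default_study_design(seed = seed)
manifest <- generate_study(design, dir)

cat(sprintf("Generated %d files under %s (seed %d):\n", nrow(manifest), dir,
            seed))
print(table(manifest$mode, manifest$kind))
cat("\nDevices and calibrated presets:\n")
for (p in design$devices) {
  cat(sprintf(
    "  %-10s R = %.4f kPa^1/2/(L/min), CMD = %.2f um, GSD = %.1f, t_inh = %.1f s%s\n",
    p$name, p$resistance, p$cmd, p$gsd, p$t_inh,
    if (p$capsule_flutter) ", capsule flutter" else ""))
}
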