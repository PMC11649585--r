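#!/usr/bin/env Rscript
# Step 1 — simulate the study landscape.
#
# Generates the synthetic Mojave-style landscape used throughout the
# workflow: four correlated environmental layers at 1 km resolution, a
# logistic habitat surface, 60 sampling locations of 12 diploid plants,
# and 780 neutral + 40 adaptive SNPs whose neutral covariance decays with
# habitat-resistance distance (isolation by resistance) and whose adaptive
# loci carry logistic clines (beta = 2) along the environmental layers.
# Writes plain-text fixtures (VCF, coords.csv, .asc rasters, truth.json)
# that the later steps read back from disk.

suppressMessages(library(genoscaper))

out <- "results/landscape"
cfg <- sim_config(seed = 42)
sim <- simulate_landscape(cfg)
paths <- write_fixture(sim, out)

cat("Simulated landscape written to", out, "\n")
cat(sprintf("  %d locations x %d plants; %d SNPs (%d adaptive)\n",
            cfg$n_populations, cfg$n_individuals,
            cfg$n_neutral + cfg$n_adaptive, cfg$n_adaptive))
cat(sprintf("  habitat suitable (>= 0.2): %d of %d cells\n",
            sum(sim$habitat$values >= 0.2), length(sim$habitat$values)))
cat(sprintf("  neutral covariance scale phi = %.1f (resistance units)\n",
            sim$truth$phi))
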