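#!/usr/bin/env Rscript
# Step 1: generate the synthetic repertoire used by the downstream analyses.
#
# The default configuration emulates a cloned shark TcR-alpha V-region
# repertoire: ~90% within-family germline identity, VJ joins diversified by
# trimming and N/P addition, clonal families of 2-9 members, per-nucleotide
# SHM rate 0.02 with 4x G:C targeting to DGYW/WRCH, 2x A:T targeting to
# WA/TW, 2x CDR elevation, and 2:1 transition bias.

suppressPackageStartupMessages(library(shmscope))

out_dir <- file.path("results", "simdata")
cfg <- simulation_config(seed = 20260927L)
sim <- generate_dataset(cfg, out_dir)

cat("Simulated repertoire written to", out_dir, "\n")
cat("  founders:", nrow(sim$truth$founders),
    " clones:", nrow(sim$repertoire$sequences),
    " families:", length(unique(sim$repertoire$sequences$family_id)), "\n")
cat("  true mutation events:", nrow(sim$truth$mutations),
    " insertions:", nrow(sim$truth$insertions), "\n")
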