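#!/usr/bin/env Rscript

# Step 1: generate the study cohort.
#
# Produces a 54-animal herd (6 boars in 4 sire lines, 23 sired sows, 25
# founder sows) genotyped on a ~50k evenly spaced SNP panel over 18
# autosomes, with implanted autozygous tracts and 2% missingness, and
# writes it as PLINK text plus truth tables under results/sim/.

suppressPackageStartupMessages(library(herdchar))

seed <- 1L
sim <- run_simulate("results/sim", seed = seed)

cat("cohort:", n_samples(sim$dataset), "animals x",
    n_loci(sim$dataset), "loci\n")
cat("implanted tracts:", nrow(sim$truth$roh_plan), "\n")
cat("files under results/sim/: herd.ped herd.map pedigree.tsv",
    "roh_truth.tsv family_truth.tsv\n")
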