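#!/usr/bin/env Rscript

# Step 5: runs of homozygosity and genomic inbreeding.
#
# Sliding-window ROH detection (50-SNP windows, at most 1 heterozygous and
# 1 missing call per window; segments longer than 1 Mb with more than 30
# SNPs) on the lenient QC track, then per-individual and population-mean
# F_ROH over the simulated autosome length.

suppressPackageStartupMessages(library(herdchar))

ds <- read_plink_text("results/qc/roh.ped", "results/qc/roh.map")

# total autosome length of the simulated genome (18 x 136 Mb), in kb
autosome_length_kb <- 18 * 136e3

segs <- detect_roh(ds, roh_params())
ft <- froh_table(segs, ds$samples$sample_id,
                 autosome_length_kb = autosome_length_kb)
smry <- roh_summary(segs)

dir.create("results/roh", showWarnings = FALSE, recursive = TRUE)
write.table(segs, "results/roh/segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(ft, "results/roh/froh.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(smry$per_individual, "results/roh/per_individual.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d segments; mean F_ROH = %.4f (range %.4f-%.4f)\n",
            nrow(segs), population_mean_froh(ft), min(ft$f_roh),
            max(ft$f_roh)))
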