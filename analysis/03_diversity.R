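#!/usr/bin/env Rscript

# Step 3: diversity parameters and effective population size.
#
# P_N comes from the polymorphism track (no MAF filter, so monomorphic
# loci stay in the denominator); H_o and H_e from the core track; Ne from
# binned LD decay (squared dosage correlation, Sved's relation, harmonic
# mean over 5 cM of distance bins, 1/n sample-size correction).

suppressPackageStartupMessages(library(herdchar))

pn_ds <- read_plink_text("results/qc/pn.ped", "results/qc/pn.map")
core_ds <- read_plink_text("results/qc/core.ped", "results/qc/core.map")

div_pn <- diversity_summary(pn_ds)
div_core <- diversity_summary(core_ds)

ld <- pairwise_r2(core_ds, max_distance_bp = 5e6, cm_per_mb = 1,
                  thin = 0.1, thin_seed = 1L)
ne <- estimate_ne(ld, bins = seq(0.005, 0.05, by = 0.005),
                  n_samples = n_samples(core_ds), correction = "1/n")

dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)
write.table(ne$table, "results/diversity/ne_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(p_n = div_pn$p_n, h_o = div_core$h_o, h_e = div_core$h_e,
       ne = ne$summary_ne),
  "results/diversity/diversity.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("P_N = %.3f  H_o = %.3f  H_e = %.3f  Ne = %.1f\n",
            div_pn$p_n, div_core$h_o, div_core$h_e, ne$summary_ne))
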