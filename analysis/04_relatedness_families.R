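#!/usr/bin/env Rscript

# Step 4: genomic relatedness and family structure.
#
# VanRaden G and its normalized kinship (KS) on the core QC track, the
# KS relationship-class distribution, IBS allele-sharing distances, a
# neighbor-joining tree, and the boar families (single-linkage components
# of the boars at KS >= 0.1, with sows attached to the closest qualifying
# family).

suppressPackageStartupMessages(library(herdchar))

ds <- read_plink_text("results/qc/core.ped", "results/qc/core.map")
ped <- read.delim("results/sim/pedigree.tsv")
sexes <- ped$sex[match(ds$samples$sample_id, ped$id)]
boar_ids <- ds$samples$sample_id[sexes == "male"]
sow_ids <- ds$samples$sample_id[sexes == "female"]

g <- vanraden_g(ds)
ks <- kinship_from_g(g)
ibs <- ibs_distance(ds)
rel <- relationship_distribution(ks)

dir.create("results/relatedness", showWarnings = FALSE, recursive = TRUE)
write_matrix_tsv(g, "results/relatedness/g_matrix.tsv")
write_matrix_tsv(ks, "results/relatedness/ks_matrix.tsv")
write_matrix_tsv(ibs, "results/relatedness/ibs_matrix.tsv")
write.table(rel$table, "results/relatedness/ks_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tree <- neighbor_joining(ibs)
write_newick(tree, "results/relatedness/tree.nwk")

fam <- build_boar_families(ks, boar_ids, threshold = 0.1)
fam <- assign_sows(ks, fam, sow_ids, threshold = 0.1)
write.table(family_table(fam, ks), "results/relatedness/families.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("mean KS = %.4f, %d boar families: %s\n", rel$mean_ks,
            length(fam$families),
            paste(sprintf("%s(%d)", names(fam$families),
                          lengths(fam$families)), collapse = " ")))
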