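#!/usr/bin/env Rscript

# Step 2: quality control.
#
# Loads the simulated genotypes and runs the three QC tracks used by the
# downstream modules:
#   polymorphism track: call rates + HWE      (for P_N)
#   core track:         call rates + HWE + MAF (diversity, kinship, Ne)
#   ROH track:          call rates only        (ROH detection keeps
#                                               monomorphic/rare loci)
# Post-QC genotypes are written back as PLINK text under results/qc/.

suppressPackageStartupMessages(library(herdchar))

ds <- read_plink_text("results/sim/herd.ped", "results/sim/herd.map")

tracks <- list(pn = qc_preset("pn_track"), core = qc_preset("core_track"),
               roh = qc_preset("roh_track"))
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
for (name in names(tracks)) {
  res <- apply_qc(ds, tracks[[name]])
  print(res$report)
  write_plink_text(res$dataset, file.path("results/qc", name))
}
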