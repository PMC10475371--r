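Package: herdchar
Title: Genomic Characterization of Small Conserved Livestock Herds from SNP Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the genetic state of a small conserved
    livestock population genotyped on a medium-density SNP array. Implements
    quality control (call rates, exact Hardy-Weinberg test, minor allele
    frequency), genetic-diversity parameters (proportion of polymorphic loci,
    observed and Nei-unbiased expected heterozygosity, linkage-disequilibrium
    based effective population size via Sved's relation), genomic relatedness
    (VanRaden genomic relationship matrix, its kinship normalization, and
    identity-by-state distances), neighbor-joining family construction with a
    kinship threshold, and runs-of-homozygosity detection with ROH-based
    inbreeding coefficients. A gene-dropping simulator generates chip-like
    genotype panels with known pedigree, linkage-disequilibrium and
    autozygosity truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
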