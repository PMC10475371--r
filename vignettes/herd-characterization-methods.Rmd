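---
title: "Methods: genomic characterization of a small conserved herd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic characterization of a small conserved herd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`herdchar` characterizes a small, closed livestock population from SNP
array genotypes: marker quality control, diversity parameters, LD-based
effective population size, genomic kinship, family reconstruction, and
runs of homozygosity (ROH). It also ships a genotype generator so every
method can be exercised, and its statistical calibration checked, without
access to proprietary chip data. This vignette records the exact
estimators and the reasoning behind every default.

```{r setup}
library(herdchar)
```

## Data model

A `genotype_dataset` holds an `n x N` integer matrix of B-allele dosages
(0/1/2, `NA` for missing) plus locus and sample tables. Loci are sorted
by chromosome (numeric labels in numeric order) and position; PLINK
text (`.ped`/`.map`) and VCF loaders orient each locus so that
`allele_b` is the minor allele (ties broken lexicographically).
Multiallelic VCF records are skipped and counted.

## Quality control

`apply_qc()` applies, in order: sample call rate, locus call rate, an
exact Hardy-Weinberg test, and a MAF filter; each removed locus is
attributed to the first filter it fails. The HWE test is the standard
exact conditional test on heterozygote counts (two-sided by probability
summation, no mid-p correction), with the conventional chip-QC rejection
threshold of 1e-6.

Different downstream statistics need different marker sets, so three
presets are provided (`qc_preset()`):

* `pn_track` - call rates + HWE. The proportion of polymorphic loci
  (P_N) needs monomorphic and rare loci in the denominator, so no MAF
  filter.
* `core_track` - call rates + HWE + MAF >= 0.01. Used for H_o/H_e,
  kinship, LD and Ne.
* `roh_track` - call rates only. ROH detection relies on long stretches
  of homozygosity, which MAF and HWE filters would bias by removing the
  very loci (rare/monomorphic, HWE-distorted in inbred material) that
  carry the signal.

Defaults: locus and sample call rate 0.90, HWE p >= 1e-6, MAF >= 0.01.

## Diversity parameters

* P_N: fraction of loci with MAF strictly above a criterion (default 0,
  i.e. segregating at all; `inclusive = TRUE` switches to >=).
* H_o: mean fraction of heterozygous calls per locus, averaged over loci.
* H_e: unbiased expected heterozygosity, per locus
  `(2n / (2n - 1)) * 2 p (1 - p)` with `n` the number of typed samples,
  averaged over loci.

## Effective population size from LD

`pairwise_r2()` computes the squared Pearson correlation of unphased
dosages for locus pairs within a physical window (default 10 Mb; the
analysis scripts use 5 Mb so the largest distance bin is 5 cM), using
pairwise-complete observations; zero-variance loci are skipped and
counted. Physical distance maps to genetic distance at a uniform rate
(default 1 cM/Mb, the usual genome-wide average for livestock arrays).

`estimate_ne()` bins pairs by genetic distance and inverts Sved's
relation per bin,

    E[r^2] = 1 / (1 + 4 Ne c)   =>   Ne = (1 / (4c)) (1 / r^2 - 1),

with `c` in Morgans at the bin midpoint. With unphased dosages from `n`
samples, the sample r^2 carries an additive bias of about `1/n`, so a
`correction` of `"1/n"` (subtracted before inversion) is applied in the
analysis scripts; `"1/2n"` and `"none"` are available. The summary Ne
is the harmonic mean over bins, which weights against the small-`c` bins
where the estimator is noisiest. A `unit = "centimorgan"` switch exists
because some legacy reports state Sved's `c` in cM; everything here
works in Morgans, the unit in which the relation is derived.

## Genomic kinship and distances

`vanraden_g()` is VanRaden's first method: dosages centered by `2p`
(`p` the B-allele frequency of the analyzed cohort), missing values
mean-imputed (centered to 0), and `G = Z Z' / (2 sum p (1 - p))`.
`kinship_from_g()` normalizes to `KS_jk = G_jk / sqrt(G_jj G_kk)`, a
correlation-like kinship with unit diagonal; samples with `G_jj = 0`
yield undefined pairs, which are reported rather than silently dropped.
Under this normalization non-inbred full sibs have expected KS 0.5 and
paternal half sibs 0.25 - the calibration targets used by the
acceptance experiment (`sibpair_ks_experiment()`).
`relationship_distribution()` tabulates the upper triangle into the
conventional classes (< 0.125, 0.125-0.25, 0.25-0.5, > 0.5).

`ibs_distance()` is the allele-sharing distance
`1 - sum(2 - |d_i - d_j|) / (2 * n_joint)`, an identity-by-state
dissimilarity on jointly typed loci.

## Family construction

`neighbor_joining()` (delegating to `ape::nj`) builds an unrooted tree
from the IBS distance matrix; on additive distances NJ recovers the tree
exactly, which the test suite verifies on random binary trees.

`build_boar_families()` reads the rule "boars with kinship at or above
0.1 belong to one family" as single-linkage components: boars are
connected whenever their KS >= 0.1, and families are the connected
components, labeled A, B, ... by decreasing size. Single linkage is the
natural reading because half sibs of half sibs can fall below 0.1 with
each other while sharing a sire line. `assign_sows()` then attaches
each sow to the family with the highest mean KS to its boars, provided
at least one boar in it reaches the threshold; otherwise the sow is
`unassigned`. Realized (as opposed to expected) half-sib kinship
scatters around 0.25, so sows near the 0.1 threshold can legitimately
land on either side of it; the synthetic truth tables make such cases
visible instead of hiding them.

## Runs of homozygosity

`detect_roh()` follows the PLINK sliding-window procedure: 50-SNP
windows (truncated windows at chromosome ends are not scanned), a window
is homozygous if it has at most 1 heterozygous and at most 1 missing
call, and a SNP is eligible if at least 5% of the windows covering it
are homozygous. Eligible SNPs are chained into segments, splitting at
gaps above 1 Mb; segments are kept only if strictly more than 30 SNPs,
strictly longer than 1 Mb, and at most 1000 kb/SNP in density. The
strict inequalities match the conventional "more than 30 SNPs / longer
than 1 Mb" phrasing of chip-based ROH reports.

`froh()` merges overlapping segments per chromosome and divides total
ROH length by the autosome length L (default 2,450,462.292 kb, a porcine
autosome total; the simulated genome uses its own L of 18 x 136 Mb).
`population_mean_froh()` is the arithmetic mean over individuals.

## The genotype generator

`simulate_founders()` draws founders in linkage equilibrium with
B-allele frequencies uniform on 0.05-0.95. `gene_drop()` phases
founders at random and drops haplotypes through a `pedigree()`; with
`linkage = "map"` crossovers fall as a Poisson process at the configured
cM/Mb, with `linkage = "unlinked"` every locus segregates freely (the
idealized mode used for the sib-pair expectations, where between-locus
linkage would only add variance). `implant_roh()` overwrites planned
spans with homozygous genotypes (random allele per locus) to create
ROH with known truth. `simulate_ld_panel()` builds independent locus
pairs whose haplotype alleles are correlated at exactly
`rho = sqrt(1 / (1 + 4 Ne c))` - the second allele copies the first
with probability `rho`, else is drawn fresh - so the panel's expected
r^2 sits on Sved's curve at a known Ne, giving the Ne estimator a
controlled recovery target.

`simulate_herd()` composes these into a herd-shaped preset: 54 genotyped
animals - one sire line of three paternal half-sib boars, three
singleton boars, 23 sows sired by the four sires, 25 unrelated founder
sows - on a ~49.5k-SNP panel over 18 x 136 Mb autosomes, with 35-60
implanted tracts of 3-8 Mb per animal and 2% missingness. What it
emulates is the family structure, the ROH burden and the marker
geometry; what it does not emulate is drift-driven allele-frequency
spectra, so on synthetic data P_N is close to 1 and the LD-based Ne
reflects the linkage-equilibrium founders rather than a small-herd
history. The Ne estimator is therefore validated on
`simulate_ld_panel()` panels, where truth is known, not on the herd
preset.

## Scale

The full pipeline (54 x 49,500 after QC) runs in a few minutes on one
CPU; the acceptance experiments use 20,000 unlinked SNPs through 400-800
individuals. `run_characterize()` stamps every table with the package
version, seed and a configuration hash, and is byte-identical across
reruns at a fixed seed.
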