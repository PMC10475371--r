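#' QC configuration
#'
#' Thresholds for the three-tier quality control: call rates, an exact
#' Hardy-Weinberg equilibrium test, and minor allele frequency.
#'
#' @param min_locus_call_rate minimum fraction of non-missing calls per
#'   locus (default 0.90).
#' @param min_sample_call_rate minimum fraction of non-missing calls per
#'   sample (default 0.90).
#' @param hwe_p_threshold loci with exact HWE p-value below this are
#'   removed when `enable_hwe` (default 1e-6).
#' @param min_maf minimum minor allele frequency when `enable_maf`
#'   (default 0.01).
#' @param enable_hwe,enable_maf logical switches for the two optional tiers.
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_locus_call_rate = 0.90, min_sample_call_rate = 0.90,
                      hwe_p_threshold = 1e-6, min_maf = 0.01,
                      enable_hwe = TRUE, enable_maf = TRUE) {
  vals <- c(min_locus_call_rate, min_sample_call_rate, hwe_p_threshold, min_maf)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("QC thresholds must lie in [0, 1]")
  }
  structure(list(min_locus_call_rate = min_locus_call_rate,
                 min_sample_call_rate = min_sample_call_rate,
                 hwe_p_threshold = hwe_p_threshold, min_maf = min_maf,
                 enable_hwe = isTRUE(enable_hwe),
                 enable_maf = isTRUE(enable_maf)),
            class = "qc_config")
}

#' Named QC presets for the three analysis tracks
#'
#' `"pn_track"` (call rates + HWE) feeds the polymorphic-proportion
#' estimate; `"core_track"` (call rates + HWE + MAF) feeds heterozygosity,
#' effective population size, relatedness and clustering; `"roh_track"`
#' (call rates only) feeds runs-of-homozygosity detection, which must keep
#' monomorphic and HWE-atypical loci.
#'
#' @param name one of `"pn_track"`, `"core_track"`, `"roh_track"`.
#' @return a `qc_config`.
#' @export
qc_preset <- function(name = c("core_track", "pn_track", "roh_track")) {
  name <- match.arg(name)
  switch(name,
    pn_track = qc_config(enable_hwe = TRUE, enable_maf = FALSE),
    core_track = qc_config(enable_hwe = TRUE, enable_maf = TRUE),
    roh_track = qc_config(enable_hwe = FALSE, enable_maf = FALSE))
}

#' Per-locus and per-sample call rates
#'
#' @param dataset a `genotype_dataset`.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
locus_call_rate <- function(dataset) {
  if (n_samples(dataset) < 1) stop("need at least one sample")
  colMeans(!is.na(dataset$dosages))
}

#' @rdname locus_call_rate
#' @export
sample_call_rate <- function(dataset) {
  if (n_loci(dataset) < 1) stop("need at least one locus")
  rowMeans(!is.na(dataset$dosages))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test on one biallelic locus: given the
#' allele counts, the p-value sums the probabilities of every heterozygote
#' count whose conditional probability does not exceed that of the observed
#' count (no mid-p adjustment), following the standard fast recurrence.
#'
#' @param n_aa,n_ab,n_bb genotype counts (AA homozygote, heterozygote,
#'   BB homozygote). Vectors are accepted and recycled to a common length.
#' @return p-value(s) in `[0, 1]`.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  nn <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(n_aa, nn); n_ab <- rep_len(n_ab, nn); n_bb <- rep_len(n_bb, nn)
  vapply(seq_len(nn), function(i) hwe_exact_one(n_aa[i], n_ab[i], n_bb[i]),
         numeric(1))
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("need at least one genotyped individual")
  rare <- 2L * min(n_aa, n_bb) + n_ab   # copies of the rarer allele
  if (rare == 0L) return(1)             # monomorphic: single configuration
  # heterozygote counts share the parity of the rare-allele count
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if ((mid %% 2L) != (rare %% 2L)) mid <- mid + 1L
  mid <- min(max(mid, rare %% 2L), rare)
  hets <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  names(probs) <- hets
  probs[as.character(mid)] <- 1
  # descend from the mode in both directions with the ratio recurrence
  h <- mid
  while (h >= 2L) {
    p_lo <- probs[as.character(h)] * h * (h - 1) /
      (4 * ((rare - h) / 2 + 1) * ((2 * n - rare - h) / 2 + 1))
    probs[as.character(h - 2L)] <- p_lo
    h <- h - 2L
  }
  h <- mid
  while (h <= rare - 2L) {
    p_hi <- probs[as.character(h)] * 4 * ((rare - h) / 2) *
      ((2 * n - rare - h) / 2) / ((h + 2) * (h + 1))
    probs[as.character(h + 2L)] <- p_hi
    h <- h + 2L
  }
  probs <- probs / sum(probs)
  obs <- as.character(n_ab)
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

#' Apply quality control to a dataset
#'
#' Filter order is fixed: (1) samples below the sample call rate are
#' dropped; (2) loci below the locus call rate; (3) loci failing the exact
#' HWE test at `hwe_p_threshold` (if enabled); (4) loci below `min_maf`
#' (if enabled). Each removed locus is attributed to the first filter it
#' fails.
#'
#' @param dataset a `genotype_dataset`.
#' @param config a [qc_config()].
#' @return a list with elements `dataset` (the filtered data) and `report`
#'   (a `qc_report` with input/pass counts, per-filter removal counts and
#'   removed ids).
#' @export
apply_qc <- function(dataset, config = qc_config()) {
  if (!inherits(config, "qc_config")) stop("config must be a qc_config")
  n_loci_input <- n_loci(dataset)
  n_samples_input <- n_samples(dataset)

  scr <- sample_call_rate(dataset)
  keep_s <- scr >= config$min_sample_call_rate
  removed_samples <- dataset$samples$sample_id[!keep_s]
  ds <- subset_dataset(dataset, samples = keep_s)
  if (n_samples(ds) == 0) stop("all samples removed by sample call-rate filter")

  lcr <- locus_call_rate(ds)
  fail_cr <- lcr < config$min_locus_call_rate
  removed <- list(call_rate = ds$loci$locus_id[fail_cr])
  ds <- subset_dataset(ds, loci = !fail_cr)

  if (config$enable_hwe) {
    d <- ds$dosages
    p <- hwe_exact_test(colSums(d == 0L, na.rm = TRUE),
                        colSums(d == 1L, na.rm = TRUE),
                        colSums(d == 2L, na.rm = TRUE))
    fail_hwe <- p < config$hwe_p_threshold
    removed$hwe <- ds$loci$locus_id[fail_hwe]
    ds <- subset_dataset(ds, loci = !fail_hwe)
  } else removed$hwe <- character(0)

  if (config$enable_maf) {
    maf <- allele_frequencies(ds)
    fail_maf <- is.na(maf) | maf < config$min_maf
    removed$maf <- ds$loci$locus_id[fail_maf]
    ds <- subset_dataset(ds, loci = !fail_maf)
  } else removed$maf <- character(0)

  report <- structure(list(
    n_loci_input = n_loci_input,
    n_loci_pass = n_loci(ds),
    n_samples_input = n_samples_input,
    n_samples_removed = length(removed_samples),
    removed_samples = removed_samples,
    n_removed_call_rate = length(removed$call_rate),
    n_removed_hwe = length(removed$hwe),
    n_removed_maf = length(removed$maf),
    removed_loci = removed,
    config = config), class = "qc_report")
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_loci_input, "loci in,", x$n_loci_pass, "pass\n")
  cat("  samples removed:", x$n_samples_removed, "\n")
  cat("  loci removed - call rate:", x$n_removed_call_rate,
      " HWE:", x$n_removed_hwe, " MAF:", x$n_removed_maf, "\n")
  invisible(x)
}
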