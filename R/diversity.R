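#' Minor allele frequency per locus
#'
#' MAF = min(p, 1 - p) where p is the frequency of `allele_b` among
#' non-missing calls. Loci with no non-missing call get `NA`.
#'
#' @param dataset a `genotype_dataset`.
#' @return numeric vector, one MAF per locus (named by locus id).
#' @export
allele_frequencies <- function(dataset) {
  d <- dataset$dosages
  nm <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nm)
  p[nm == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  names(maf) <- dataset$loci$locus_id
  maf
}

# frequency of allele_b (not folded to minor); used for G centering
alt_allele_freq <- function(dataset) {
  d <- dataset$dosages
  nm <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nm)
  p[nm == 0] <- NA_real_
  p
}

#' Proportion of polymorphic loci
#'
#' P_N = M / N where M counts loci whose MAF exceeds `maf_threshold`
#' (strictly greater than 0 by default, i.e. any observed polymorphism)
#' and N is the total number of loci supplied. `NA` MAFs (untyped loci)
#' count as non-polymorphic.
#'
#' @param maf numeric vector of minor allele frequencies.
#' @param maf_threshold polymorphism criterion; a locus is polymorphic when
#'   `maf > maf_threshold` (default 0) or, if `inclusive`, `maf >= maf_threshold`.
#' @param inclusive use `>=` instead of `>` (for criteria like MAF >= 0.01).
#' @return fraction in `[0, 1]`.
#' @export
proportion_polymorphic <- function(maf, maf_threshold = 0, inclusive = FALSE) {
  if (length(maf) == 0) stop("empty MAF vector")
  poly <- if (inclusive) maf >= maf_threshold else maf > maf_threshold
  sum(poly, na.rm = TRUE) / length(maf)
}

#' Observed heterozygosity
#'
#' Mean over loci of the heterozygote fraction: H_o = (1/N) sum_k H_k / n_k,
#' with H_k the heterozygote count and n_k the non-missing sample count at
#' locus k. Loci with no calls are excluded from the average.
#'
#' @param dataset a `genotype_dataset`.
#' @return fraction in `[0, 1]`.
#' @export
observed_heterozygosity <- function(dataset) {
  if (n_loci(dataset) < 1 || n_samples(dataset) < 1) stop("empty dataset")
  d <- dataset$dosages
  nm <- colSums(!is.na(d))
  het <- colSums(d == 1L, na.rm = TRUE)
  mean((het / nm)[nm > 0])
}

#' Expected heterozygosity (Nei's unbiased gene diversity)
#'
#' Per locus, (2n/(2n-1)) * (1 - sum_i p_i^2) with n the non-missing sample
#' count at that locus and p_i the allele frequencies; the per-locus values
#' are averaged over loci. Loci with no calls are excluded.
#'
#' @param dataset a `genotype_dataset`.
#' @return fraction in `[0, 1]`.
#' @export
expected_heterozygosity <- function(dataset) {
  if (n_loci(dataset) < 1 || n_samples(dataset) < 1) stop("empty dataset")
  d <- dataset$dosages
  nm <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nm)
  he_k <- (2 * nm / (2 * nm - 1)) * (1 - p^2 - (1 - p)^2)
  mean(he_k[nm > 0])
}

#' Cohort diversity summary
#'
#' Convenience wrapper computing MAF, P_N, H_o and H_e on one dataset.
#'
#' @param dataset a `genotype_dataset`.
#' @param pn_maf_threshold,pn_inclusive polymorphism criterion passed to
#'   [proportion_polymorphic()].
#' @return a list with `p_n`, `h_o`, `h_e`, `m_polymorphic`, `n_total_loci`
#'   and the `maf` vector.
#' @export
diversity_summary <- function(dataset, pn_maf_threshold = 0,
                              pn_inclusive = FALSE) {
  maf <- allele_frequencies(dataset)
  p_n <- proportion_polymorphic(maf, pn_maf_threshold, pn_inclusive)
  list(p_n = p_n,
       h_o = observed_heterozygosity(dataset),
       h_e = expected_heterozygosity(dataset),
       m_polymorphic = round(p_n * length(maf)),
       n_total_loci = length(maf),
       maf = maf)
}

#' Pairwise linkage disequilibrium (r-squared) within chromosomes
#'
#' For every same-chromosome locus pair closer than `max_distance_bp`,
#' r2 is the squared Pearson correlation of the unphased dosage vectors
#' over samples non-missing at both loci (composite LD). Map distance in
#' Morgans is derived from physical distance via `cm_per_mb`.
#'
#' @param dataset a `genotype_dataset` with loci sorted by position.
#' @param max_distance_bp only pairs within this physical distance are kept.
#' @param cm_per_mb genetic-map scaling, centimorgan per megabase
#'   (default 1).
#' @param thin optional fraction in (0, 1]: keep a random subsample of the
#'   pairs (seeded by `thin_seed`); useful on dense panels.
#' @param thin_seed RNG seed used only when `thin < 1`.
#' @return data.frame with columns `locus_i`, `locus_j`, `chromosome`,
#'   `dist_bp`, `dist_morgans`, `r_squared`. The number of pairs skipped
#'   because a locus had zero variance is attached as attribute
#'   `"n_skipped_zero_variance"`.
#' @export
pairwise_r2 <- function(dataset, max_distance_bp = 10e6, cm_per_mb = 1.0,
                        thin = 1, thin_seed = 1L) {
  loci <- dataset$loci
  out <- vector("list", length(unique(loci$chromosome)))
  n_skip <- 0L
  ci <- 0L
  for (chr in unique(loci$chromosome)) {
    ci <- ci + 1L
    idx <- which(loci$chromosome == chr)
    if (length(idx) < 2) next
    pos <- loci$position_bp[idx]
    if (is.unsorted(pos)) stop("loci not sorted by position on chromosome ", chr)
    d <- dataset$dosages[, idx, drop = FALSE]
    cc <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    dist_bp <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- dist_bp <= max_distance_bp
    pr <- pr[keep, , drop = FALSE]
    dist_bp <- dist_bp[keep]
    r2 <- cc[pr]^2
    bad <- is.na(r2)
    n_skip <- n_skip + sum(bad)
    out[[ci]] <- data.frame(
      locus_i = loci$locus_id[idx[pr[!bad, 1]]],
      locus_j = loci$locus_id[idx[pr[!bad, 2]]],
      chromosome = rep(chr, sum(!bad)),
      dist_bp = dist_bp[!bad],
      r_squared = r2[!bad],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(locus_i = character(0), locus_j = character(0),
                      chromosome = character(0), dist_bp = integer(0),
                      r_squared = numeric(0))
  }
  res$dist_morgans <- (res$dist_bp / 1e6) * cm_per_mb / 100
  res <- res[, c("locus_i", "locus_j", "chromosome", "dist_bp",
                 "dist_morgans", "r_squared")]
  if (thin < 1 && nrow(res) > 0) {
    keep_n <- max(1L, floor(thin * nrow(res)))
    res <- local_seed(thin_seed, res[sort(sample.int(nrow(res), keep_n)), ,
                                     drop = FALSE])
    rownames(res) <- NULL
  }
  attr(res, "n_skipped_zero_variance") <- n_skip
  res
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Effective population size from binned LD (Sved's relation)
#'
#' Pairs are binned by map distance; for each bin with midpoint c (Morgans),
#' Ne = (1 / (4c)) * (1 / r2_adj - 1), where r2_adj is the bin's mean
#' r-squared optionally reduced by a sample-size correction. Each bin maps
#' to roughly t = 1/(2c) generations ago. The summary Ne is the harmonic
#' mean over bins with a defined estimate.
#'
#' @param records data.frame from [pairwise_r2()].
#' @param bins numeric vector of bin breakpoints in Morgans (length >= 2).
#' @param n_samples number of genotyped individuals, used by the correction.
#' @param correction `"none"`, `"1/n"` or `"1/2n"`: amount subtracted from
#'   the mean r-squared to offset finite-sample inflation.
#' @param unit `"morgan"` (default, Sved's derivation) or `"centimorgan"`:
#'   unit in which c enters the formula.
#' @return a list with `table` (per-bin data.frame: `c_morgans`,
#'   `mean_r2`, `r2_adj`, `n_pairs`, `generations_ago`, `ne`) and
#'   `summary_ne`.
#' @export
estimate_ne <- function(records, bins, n_samples,
                        correction = c("none", "1/n", "1/2n"),
                        unit = c("morgan", "centimorgan")) {
  correction <- match.arg(correction)
  unit <- match.arg(unit)
  if (length(bins) < 2) stop("need at least two bin breakpoints")
  bins <- sort(bins)
  corr <- switch(correction, none = 0, `1/n` = 1 / n_samples,
                 `1/2n` = 1 / (2 * n_samples))
  bin_idx <- cut(records$dist_morgans, bins, include.lowest = TRUE)
  tab <- lapply(seq_len(length(bins) - 1L), function(b) {
    sel <- which(as.integer(bin_idx) == b)
    mid <- (bins[b] + bins[b + 1]) / 2
    mr2 <- if (length(sel)) mean(records$r_squared[sel]) else NA_real_
    r2a <- mr2 - corr
    c_eff <- if (unit == "morgan") mid else mid * 100
    ne <- if (!is.na(r2a) && r2a > 0) {
      max(0, (1 / (4 * c_eff)) * (1 / r2a - 1))
    } else NA_real_
    data.frame(c_morgans = mid, mean_r2 = mr2, r2_adj = r2a,
               n_pairs = length(sel), generations_ago = 1 / (2 * mid),
               ne = ne)
  })
  tab <- do.call(rbind, tab)
  ok <- !is.na(tab$ne) & tab$ne > 0
  summary_ne <- if (any(ok)) length(tab$ne[ok]) / sum(1 / tab$ne[ok]) else NA_real_
  list(table = tab, summary_ne = summary_ne)
}
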