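#' Sib-pair genomic-kinship recovery experiment
#'
#' Gene-drops unlinked biallelic SNPs through many independent two-parent
#' families and measures the mean VanRaden-normalized kinship (KS) of the
#' resulting sib pairs. With non-inbred unrelated founders the reference
#' values are 0.5 for full sibs and 0.25 for paternal half sibs; this
#' experiment checks that the whole chain (founder simulation, gene drop,
#' G matrix, KS normalization) reproduces them.
#'
#' @param type `"full"` (two shared parents) or `"half"` (shared sire,
#'   distinct unrelated dams).
#' @param n_pairs number of independent sib pairs (default 200).
#' @param n_loci number of unlinked SNPs (default 20,000), founder
#'   frequencies uniform on 0.05-0.95.
#' @param seed RNG seed.
#' @return a list: `mean_ks` (mean within-pair kinship), `pair_ks`
#'   (vector, one per pair), `type`, `n_pairs`, `n_loci`.
#' @export
sibpair_ks_experiment <- function(type = c("full", "half"), n_pairs = 200,
                                  n_loci = 20000, seed = 1L) {
  type <- match.arg(type)
  cfg <- sim_config(n_loci = n_loci, n_chromosomes = 18, seed = seed)
  i <- seq_len(n_pairs)
  off_a <- sprintf("O%04da", i)
  off_b <- sprintf("O%04db", i)
  if (type == "full") {
    sires <- sprintf("P%04ds", i); dams <- sprintf("P%04dd", i)
    ped <- data.frame(
      id = c(sires, dams, off_a, off_b),
      sire = c(rep(NA, 2 * n_pairs), sires, sires),
      dam = c(rep(NA, 2 * n_pairs), dams, dams),
      sex = rep(c("male", "female", "unknown", "unknown"),
                each = n_pairs), stringsAsFactors = FALSE)
    founder_ids <- c(sires, dams)
  } else {
    sires <- sprintf("S%04d", i)
    dam_a <- sprintf("D%04da", i); dam_b <- sprintf("D%04db", i)
    ped <- data.frame(
      id = c(sires, dam_a, dam_b, off_a, off_b),
      sire = c(rep(NA, 3 * n_pairs), sires, sires),
      dam = c(rep(NA, 3 * n_pairs), dam_a, dam_b),
      sex = rep(c("male", "female", "female", "unknown", "unknown"),
                each = n_pairs), stringsAsFactors = FALSE)
    founder_ids <- c(sires, dam_a, dam_b)
  }
  founders <- simulate_founders(cfg, length(founder_ids), ids = founder_ids)
  cohort <- gene_drop(pedigree(ped), founders, cfg, linkage = "unlinked",
                      seed = seed + 1L)
  ks <- kinship_from_g(vanraden_g(cohort))$values
  pair_ks <- ks[cbind(off_a, off_b)]
  list(mean_ks = mean(pair_ks), pair_ks = pair_ks, type = type,
       n_pairs = n_pairs, n_loci = n_loci)
}
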