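#' Simulation configuration
#'
#' @param n_loci total number of SNP loci, distributed as evenly as
#'   possible across chromosomes.
#' @param n_chromosomes number of autosomes (default 18, a porcine
#'   autosome count).
#' @param chrom_length_bp physical length per chromosome (default 136 Mb,
#'   giving an about 2.45 Gb autosomal genome at 18 autosomes).
#' @param founder_freq_range interval for the uniform draw of founder
#'   allele-b frequencies (default 0.05-0.95).
#' @param missing_rate genotype missingness fraction (default 0).
#' @param recombination_rate_cm_per_mb genetic map scaling (default 1).
#' @param seed RNG seed; every stochastic generator in this module derives
#'   its stream from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_loci = 10000, n_chromosomes = 18,
                       chrom_length_bp = 136e6,
                       founder_freq_range = c(0.05, 0.95),
                       missing_rate = 0,
                       recombination_rate_cm_per_mb = 1.0, seed = 1L) {
  if (n_loci < 1 || n_chromosomes < 1 || chrom_length_bp < 1) {
    stop("n_loci, n_chromosomes and chrom_length_bp must be positive")
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  if (length(founder_freq_range) != 2 ||
      any(founder_freq_range < 0 | founder_freq_range > 1)) {
    stop("founder_freq_range must be two values in [0,1]")
  }
  structure(list(n_loci = as.integer(n_loci),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 founder_freq_range = founder_freq_range,
                 missing_rate = missing_rate,
                 recombination_rate_cm_per_mb = recombination_rate_cm_per_mb,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# evenly spaced locus map for a config
sim_locus_map <- function(config) {
  per <- diff(round(seq(0, config$n_loci, length.out = config$n_chromosomes + 1)))
  chrom <- rep(as.character(seq_len(config$n_chromosomes)), per)
  pos <- unlist(lapply(per, function(m) {
    if (m == 0) return(integer(0))
    as.integer(round(seq(1, config$chrom_length_bp, length.out = m)))
  }))
  data.frame(locus_id = sprintf("snp%06d", seq_len(config$n_loci)),
             chromosome = chrom, position_bp = pos,
             allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
}

#' Simulate founder genotypes in linkage equilibrium
#'
#' Loci are placed evenly along the configured chromosomes; each founder's
#' dosage at locus k is Binomial(2, p_k) with p_k drawn uniformly from
#' `founder_freq_range`, independently across loci (no LD). Missingness is
#' applied at `missing_rate`. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param n_founders number of founder individuals.
#' @param ids optional sample ids (default F001...).
#' @param sex optional sex vector (default `"unknown"`).
#' @return a `genotype_dataset`; the founder frequencies used are attached
#'   as attribute `"founder_freqs"`.
#' @export
simulate_founders <- function(config, n_founders, ids = NULL, sex = NULL) {
  if (!inherits(config, "sim_config")) stop("config must be sim_config()")
  loci <- sim_locus_map(config)
  if (is.null(ids)) ids <- sprintf("F%03d", seq_len(n_founders))
  if (is.null(sex)) sex <- rep("unknown", n_founders)
  ds <- local_seed(config$seed, {
    p <- stats::runif(config$n_loci, config$founder_freq_range[1],
                      config$founder_freq_range[2])
    dos <- matrix(stats::rbinom(n_founders * config$n_loci, 2L,
                                rep(p, each = n_founders)),
                  nrow = n_founders)
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(dos)) < config$missing_rate,
                     nrow = n_founders)
      dos[mask] <- NA_integer_
    }
    out <- genotype_dataset(dos, loci,
                            data.frame(sample_id = ids, sex = sex,
                                       stringsAsFactors = FALSE))
    attr(out, "founder_freqs") <- p
    out
  })
  ds
}

#' Apply random missingness to a dataset
#'
#' @param dataset a `genotype_dataset`.
#' @param rate missingness fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return the dataset with dosages masked to `NA` at the given rate.
#' @export
add_missingness <- function(dataset, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0,1]")
  local_seed(seed, {
    d <- dataset$dosages
    d[matrix(stats::runif(length(d)) < rate, nrow = nrow(d))] <- NA_integer_
    genotype_dataset(d, dataset$loci, dataset$samples)
  })
}

#' Pedigree constructor
#'
#' @param df data.frame with columns `id`, `sire`, `dam`, `sex`; founders
#'   have `NA` for both parents. Parents must appear before their
#'   offspring.
#' @return a validated `pedigree` data.frame.
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam", "sex")
  if (!all(need %in% names(df))) {
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("duplicate pedigree ids")
  half <- xor(is.na(df$sire), is.na(df$dam))
  if (any(half)) stop("individuals must have either two parents or none")
  for (r in seq_len(nrow(df))) {
    for (par in c(df$sire[r], df$dam[r])) {
      if (!is.na(par) && !(par %in% df$id[seq_len(r - 1L)])) {
        stop("parent ", par, " of ", df$id[r],
             " does not precede it in the pedigree")
      }
    }
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder genotypes are phased into two haplotypes (heterozygous sites
#' assigned at random) and each non-founder inherits one recombinant
#' haplotype per parent. With `linkage = "map"` crossovers fall as a
#' Poisson process along each chromosome at
#' `config$recombination_rate_cm_per_mb`; with `linkage = "unlinked"`
#' every locus segregates independently (free recombination), the
#' idealized mode used for relatedness-expectation checks. Deterministic
#' given `seed`.
#'
#' @param ped a [pedigree()]; its founders must all be samples of
#'   `founders`.
#' @param founders a `genotype_dataset` with no missing calls for the
#'   founder individuals.
#' @param config a [sim_config()] (supplies chromosome length and
#'   recombination rate).
#' @param linkage `"map"` or `"unlinked"`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a `genotype_dataset` containing every pedigree member, in
#'   pedigree order.
#' @export
gene_drop <- function(ped, founders, config, linkage = c("map", "unlinked"),
                      seed = NULL) {
  linkage <- match.arg(linkage)
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  if (is.null(seed)) seed <- config$seed
  f_ids <- ped$id[is.na(ped$sire)]
  miss <- setdiff(f_ids, founders$samples$sample_id)
  if (length(miss)) stop("founders not in genotype data: ",
                         paste(miss, collapse = ", "))
  fidx <- match(f_ids, founders$samples$sample_id)
  fd <- founders$dosages[fidx, , drop = FALSE]
  if (anyNA(fd)) stop("founder genotypes must have no missing calls")
  loci <- founders$loci
  nl <- nrow(loci)
  chroms <- unique(loci$chromosome)
  chr_idx <- lapply(chroms, function(ch) which(loci$chromosome == ch))
  pos_m <- loci$position_bp / 1e6 * config$recombination_rate_cm_per_mb / 100
  chrom_len_m <- config$chrom_length_bp / 1e6 *
    config$recombination_rate_cm_per_mb / 100

  local_seed(seed, {
    nid <- nrow(ped)
    h1 <- matrix(0L, nid, nl)
    h2 <- matrix(0L, nid, nl)
    rownames(h1) <- rownames(h2) <- ped$id
    # phase founders: het sites split at random
    for (i in seq_along(f_ids)) {
      row <- match(f_ids[i], ped$id)
      g <- fd[i, ]
      a1 <- integer(nl); a2 <- integer(nl)
      a1[g == 2L] <- 1L; a2[g == 2L] <- 1L
      hh <- which(g == 1L)
      coin <- stats::runif(length(hh)) < 0.5
      a1[hh[coin]] <- 1L
      a2[hh[!coin]] <- 1L
      h1[row, ] <- a1; h2[row, ] <- a2
    }
    meiosis <- function(ha, hb) {
      if (linkage == "unlinked") {
        pick <- stats::runif(nl) < 0.5
        return(ifelse(pick, ha, hb))
      }
      gam <- integer(nl)
      for (ci in seq_along(chroms)) {
        ix <- chr_idx[[ci]]
        nxo <- stats::rpois(1, chrom_len_m)
        xo <- sort(stats::runif(nxo, 0, chrom_len_m))
        start <- stats::rbinom(1, 1, 0.5)
        src <- (findInterval(pos_m[ix], xo) + start) %% 2L
        gam[ix] <- ifelse(src == 0L, ha[ix], hb[ix])
      }
      gam
    }
    for (r in which(!is.na(ped$sire))) {
      si <- match(ped$sire[r], ped$id)
      di <- match(ped$dam[r], ped$id)
      h1[r, ] <- meiosis(h1[si, ], h2[si, ])
      h2[r, ] <- meiosis(h1[di, ], h2[di, ])
    }
    genotype_dataset(h1 + h2, loci,
                     data.frame(sample_id = ped$id, sex = ped$sex,
                                stringsAsFactors = FALSE))
  })
}

#' Simulate an LD panel with a known effective population size
#'
#' Builds loci in independent pairs. Each pair sits at a chosen map
#' distance c; its two haplotype alleles are drawn so that the dosage
#' correlation is exactly rho = sqrt(1 / (1 + 4 * ne_true * c)) (the
#' second allele copies the first with probability rho, else is drawn
#' fresh from the same frequency), so the expected squared correlation
#' matches Sved's relation at `ne_true`. Pairs are placed on separate
#' chromosome labels so only within-pair LD exists.
#'
#' @param ne_true true effective population size (> 0).
#' @param n_samples number of diploid individuals.
#' @param distances_morgans map distance for each pair (vector; one locus
#'   pair is created per element).
#' @param config a [sim_config()]; supplies the founder frequency range,
#'   map scaling and seed.
#' @return a `genotype_dataset` with `2 * length(distances_morgans)` loci.
#' @export
simulate_ld_panel <- function(ne_true, n_samples, distances_morgans,
                              config = sim_config()) {
  if (ne_true <= 0) stop("ne_true must be > 0")
  np <- length(distances_morgans)
  local_seed(config$seed, {
    p <- stats::runif(np, config$founder_freq_range[1],
                      config$founder_freq_range[2])
    rho <- sqrt(1 / (1 + 4 * ne_true * distances_morgans))
    nh <- 2L * n_samples
    a1 <- matrix(stats::rbinom(nh * np, 1L, rep(p, each = nh)), nrow = nh)
    copy <- matrix(stats::runif(nh * np) < rep(rho, each = nh), nrow = nh)
    fresh <- matrix(stats::rbinom(nh * np, 1L, rep(p, each = nh)), nrow = nh)
    a2 <- ifelse(copy, a1, fresh)
    odd <- seq(1, nh, by = 2)
    d1 <- a1[odd, , drop = FALSE] + a1[odd + 1, , drop = FALSE]
    d2 <- a2[odd, , drop = FALSE] + a2[odd + 1, , drop = FALSE]
    dos <- matrix(0L, n_samples, 2L * np)
    dos[, seq(1, 2 * np, by = 2)] <- d1
    dos[, seq(2, 2 * np, by = 2)] <- d2
    bp <- pmax(2L, as.integer(round(
      distances_morgans * 100 / config$recombination_rate_cm_per_mb * 1e6)))
    loci <- data.frame(
      locus_id = sprintf("p%05d_%d", rep(seq_len(np), each = 2), 1:2),
      chromosome = sprintf("c%05d", rep(seq_len(np), each = 2)),
      position_bp = as.integer(rbind(rep(1L, np), bp)),
      allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
    samples <- data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
                          sex = "unknown", stringsAsFactors = FALSE)
    genotype_dataset(dos, loci, samples)
  })
}

#' Implant autozygous tracts into a dataset
#'
#' Within each planned span the sample's genotype is set homozygous, the
#' allele chosen by an independent coin flip per locus; everything outside
#' the spans is untouched. Spans for one sample must not overlap.
#'
#' @param dataset a `genotype_dataset`.
#' @param plan data.frame with columns `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`.
#' @param seed RNG seed for the allele coin flips.
#' @return a list: `dataset` (modified) and `truth` (the plan with an
#'   `n_snps` column counting loci inside each span).
#' @export
implant_roh <- function(dataset, plan, seed = 1L) {
  plan <- as.data.frame(plan, stringsAsFactors = FALSE)
  if (nrow(plan) == 0) {
    return(list(dataset = dataset,
                truth = cbind(plan, n_snps = integer(0))))
  }
  if (any(plan$end_bp < plan$start_bp)) stop("span end before start")
  for (key in unique(paste(plan$sample_id, plan$chromosome))) {
    s <- plan[paste(plan$sample_id, plan$chromosome) == key, , drop = FALSE]
    s <- s[order(s$start_bp), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start_bp[-1] <= s$end_bp[-nrow(s)])) {
      stop("overlapping spans for ", key)
    }
  }
  maxpos <- tapply(dataset$loci$position_bp, dataset$loci$chromosome, max)
  if (any(plan$end_bp > maxpos[as.character(plan$chromosome)] |
          plan$start_bp < 1)) {
    stop("span outside chromosome bounds")
  }
  local_seed(seed, {
    d <- dataset$dosages
    n_snps <- integer(nrow(plan))
    for (r in seq_len(nrow(plan))) {
      si <- match(plan$sample_id[r], dataset$samples$sample_id)
      if (is.na(si)) stop("unknown sample in plan: ", plan$sample_id[r])
      li <- which(dataset$loci$chromosome == plan$chromosome[r] &
                  dataset$loci$position_bp >= plan$start_bp[r] &
                  dataset$loci$position_bp <= plan$end_bp[r])
      n_snps[r] <- length(li)
      d[si, li] <- 2L * stats::rbinom(length(li), 1L, 0.5)
    }
    list(dataset = genotype_dataset(d, dataset$loci, dataset$samples),
         truth = cbind(plan, n_snps = n_snps))
  })
}
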