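#' Parameters for sliding-window ROH detection
#'
#' Defaults follow the published PLINK-style settings for a medium-density
#' porcine array: 50-SNP sliding windows tolerating at most one
#' heterozygous and one missing call, SNP eligibility at a 5% hit
#' proportion, and final segments required to carry more than 30 SNPs,
#' span more than 1,000 kb, bridge no gap above 1,000 kb and keep a
#' density of at least 1 SNP per 1,000 kb.
#'
#' @param min_snps_per_segment segments must contain strictly more SNPs
#'   than this (default 30).
#' @param min_length_kb segments must be strictly longer than this
#'   (default 1000).
#' @param max_gap_kb maximum allowed gap between two consecutive segment
#'   SNPs (default 1000).
#' @param min_density_kb_per_snp maximum kb per SNP inside a segment
#'   (default 1000, i.e. at least 1 SNP per 1000 kb).
#' @param window_snps sliding-window size in SNPs (default 50).
#' @param window_max_het maximum heterozygous calls per homozygous window
#'   (default 1).
#' @param window_max_missing maximum missing calls per homozygous window
#'   (default 1).
#' @param min_hit_proportion minimum fraction of covering windows that are
#'   homozygous for a SNP to be eligible (default 0.05).
#' @return a `roh_params` list.
#' @export
roh_params <- function(min_snps_per_segment = 30, min_length_kb = 1000,
                       max_gap_kb = 1000, min_density_kb_per_snp = 1000,
                       window_snps = 50, window_max_het = 1,
                       window_max_missing = 1, min_hit_proportion = 0.05) {
  if (any(c(min_snps_per_segment, min_length_kb, max_gap_kb,
            min_density_kb_per_snp, window_snps) <= 0)) {
    stop("ROH parameters must be positive")
  }
  if (min_hit_proportion <= 0 || min_hit_proportion > 1) {
    stop("min_hit_proportion must be in (0, 1]")
  }
  structure(list(min_snps_per_segment = min_snps_per_segment,
                 min_length_kb = min_length_kb, max_gap_kb = max_gap_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 window_snps = window_snps, window_max_het = window_max_het,
                 window_max_missing = window_max_missing,
                 min_hit_proportion = min_hit_proportion),
            class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' PLINK-compatible two-stage scan, per sample and chromosome:
#' (1) full windows of `window_snps` consecutive SNPs are scored
#' homozygous when they contain at most `window_max_het` heterozygous and
#' `window_max_missing` missing calls (truncated windows at chromosome
#' ends are not evaluated); (2) each SNP's hit proportion is the fraction
#' of the windows covering it that are homozygous, and SNPs at or above
#' `min_hit_proportion` are eligible; (3) maximal runs of consecutive
#' eligible SNPs are split where the gap between adjacent SNPs exceeds
#' `max_gap_kb`; (4) runs survive only with more than
#' `min_snps_per_segment` SNPs, length above `min_length_kb`, and density
#' at or below `min_density_kb_per_snp` kb per SNP.
#'
#' @param dataset a `genotype_dataset` (loci sorted by chromosome and
#'   position, which the container enforces).
#' @param params a [roh_params()].
#' @return data.frame of segments: `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_kb`.
#' @export
detect_roh <- function(dataset, params = roh_params()) {
  if (!inherits(params, "roh_params")) stop("params must be roh_params()")
  loci <- dataset$loci
  segs <- list()
  for (chr in unique(loci$chromosome)) {
    idx <- which(loci$chromosome == chr)
    pos <- loci$position_bp[idx]
    if (is.unsorted(pos, strictly = FALSE)) {
      stop("loci unsorted on chromosome ", chr)
    }
    dmat <- dataset$dosages[, idx, drop = FALSE]
    for (s in seq_len(n_samples(dataset))) {
      runs <- roh_scan_one(dmat[s, ], pos, params)
      if (!is.null(runs) && nrow(runs)) {
        runs$sample_id <- dataset$samples$sample_id[s]
        runs$chromosome <- chr
        segs[[length(segs) + 1L]] <- runs
      }
    }
  }
  if (!length(segs)) {
    return(data.frame(sample_id = character(0), chromosome = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_kb = numeric(0)))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out[, c("sample_id", "chromosome", "start_bp", "end_bp", "n_snps",
          "length_kb")]
}

# one sample x one chromosome scan; d is a dosage vector, pos sorted bp
roh_scan_one <- function(d, pos, params) {
  m <- length(d)
  w <- params$window_snps
  if (m < w) return(NULL)
  het <- as.integer(!is.na(d) & d == 1L)
  mis <- as.integer(is.na(d))
  cs_het <- cumsum(het); cs_mis <- cumsum(mis)
  nw <- m - w + 1L
  i <- seq_len(nw)
  win_het <- cs_het[i + w - 1L] - c(0L, cs_het)[i]
  win_mis <- cs_mis[i + w - 1L] - c(0L, cs_mis)[i]
  hom_win <- as.integer(win_het <= params$window_max_het &
                        win_mis <= params$window_max_missing)
  k <- seq_len(m)
  lo <- pmax(1L, k - w + 1L)
  hi <- pmin(nw, k)
  cover <- hi - lo + 1L
  cs_hom <- cumsum(hom_win)
  hits <- cs_hom[hi] - c(0L, cs_hom)[lo]
  eligible <- (hits / cover) >= params$min_hit_proportion
  # break runs at ineligible SNPs and at over-long gaps
  gap_kb <- c(Inf, diff(pos) / 1000)
  brk <- !eligible | gap_kb > params$max_gap_kb
  # a gap break starts a new run at this SNP; ineligible SNPs are dropped
  run_id <- cumsum(brk)
  keep <- which(eligible)
  if (!length(keep)) return(NULL)
  out <- lapply(split(keep, run_id[keep]), function(ks) {
    # ks are consecutive eligible indices within one run
    data.frame(start_bp = pos[ks[1]], end_bp = pos[ks[length(ks)]],
               n_snps = length(ks),
               length_kb = (pos[ks[length(ks)]] - pos[ks[1]] + 1) / 1000)
  })
  out <- do.call(rbind, out)
  len_ok <- out$length_kb > params$min_length_kb
  cnt_ok <- out$n_snps > params$min_snps_per_segment
  den_ok <- out$length_kb / out$n_snps <= params$min_density_kb_per_snp
  out <- out[len_ok & cnt_ok & den_ok, , drop = FALSE]
  if (!nrow(out)) NULL else out
}

#' ROH-based inbreeding coefficient of one individual
#'
#' F_ROH = (total merged ROH length in kb) / (autosome length in kb).
#' Overlapping or adjacent segments are merged per chromosome first.
#'
#' @param segments data.frame of ROH segments for one sample (columns as
#'   returned by [detect_roh()]).
#' @param autosome_length_kb total autosomal genome length L in kb. The
#'   published porcine-array constant is 2,450,462.292 kb; for simulated
#'   genomes pass the simulated length.
#' @return a list: `sample_id`, `total_roh_kb`, `f_roh`,
#'   `autosome_length_kb`.
#' @export
froh <- function(segments, autosome_length_kb = 2450462.292) {
  if (autosome_length_kb <= 0) stop("autosome_length_kb must be > 0")
  if (nrow(segments) == 0) {
    return(list(sample_id = NA_character_, total_roh_kb = 0, f_roh = 0,
                autosome_length_kb = autosome_length_kb))
  }
  if (length(unique(segments$sample_id)) > 1) {
    stop("froh() expects segments of a single sample")
  }
  total <- 0
  for (chr in unique(segments$chromosome)) {
    s <- segments[segments$chromosome == chr, , drop = FALSE]
    s <- s[order(s$start_bp), , drop = FALSE]
    cur_s <- s$start_bp[1]; cur_e <- s$end_bp[1]
    for (r in seq_len(nrow(s))[-1]) {
      if (s$start_bp[r] <= cur_e + 1) {
        cur_e <- max(cur_e, s$end_bp[r])
      } else {
        total <- total + (cur_e - cur_s + 1) / 1000
        cur_s <- s$start_bp[r]; cur_e <- s$end_bp[r]
      }
    }
    total <- total + (cur_e - cur_s + 1) / 1000
  }
  list(sample_id = segments$sample_id[1], total_roh_kb = total,
       f_roh = total / autosome_length_kb,
       autosome_length_kb = autosome_length_kb)
}

#' Per-individual F_ROH table for a cohort
#'
#' @param segments data.frame from [detect_roh()] (any number of samples).
#' @param sample_ids ids to report (samples without segments get F_ROH 0).
#' @param autosome_length_kb as in [froh()].
#' @return data.frame: `sample_id`, `total_roh_kb`, `f_roh`.
#' @export
froh_table <- function(segments, sample_ids,
                       autosome_length_kb = 2450462.292) {
  rows <- lapply(sample_ids, function(id) {
    r <- froh(segments[segments$sample_id == id, , drop = FALSE],
              autosome_length_kb)
    data.frame(sample_id = id, total_roh_kb = r$total_roh_kb,
               f_roh = r$f_roh, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Population mean inbreeding coefficient
#'
#' Arithmetic mean of per-individual F_ROH values.
#'
#' @param f_roh numeric vector (or the data.frame from [froh_table()]).
#' @return the mean F_ROH.
#' @export
population_mean_froh <- function(f_roh) {
  if (is.data.frame(f_roh)) f_roh <- f_roh$f_roh
  if (length(f_roh) == 0) stop("no individual F_ROH values supplied")
  mean(f_roh)
}

#' Summarize detected ROH segments
#'
#' @param segments data.frame from [detect_roh()].
#' @param long_threshold_mb boundary between the short and long length
#'   classes (default 6 Mb).
#' @return a list with `per_individual` (count and min/median/max segment
#'   length in Mb per sample) and `length_classes` (counts below/at-or-above
#'   the threshold).
#' @export
roh_summary <- function(segments, long_threshold_mb = 6) {
  if (nrow(segments) == 0) {
    return(list(per_individual = data.frame(sample_id = character(0),
                                            n_segments = integer(0),
                                            min_mb = numeric(0),
                                            median_mb = numeric(0),
                                            max_mb = numeric(0)),
                length_classes = c(short = 0L, long = 0L),
                long_threshold_mb = long_threshold_mb))
  }
  mb <- segments$length_kb / 1000
  per <- do.call(rbind, lapply(split(mb, segments$sample_id), function(v) {
    data.frame(n_segments = length(v), min_mb = min(v),
               median_mb = stats::median(v), max_mb = max(v))
  }))
  per <- data.frame(sample_id = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(per_individual = per,
       length_classes = c(short = sum(mb < long_threshold_mb),
                          long = sum(mb >= long_threshold_mb)),
       long_threshold_mb = long_threshold_mb)
}
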