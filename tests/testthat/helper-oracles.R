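# Brute-force oracles and small random fixtures. Everything here is written
# as plain double loops over the definitions, independent of the package's
# vectorized implementations.

random_dataset <- function(n, N, miss = 0.1, n_chrom = 2, maf_lo = 0.05,
                           maf_hi = 0.95) {
  dos <- matrix(stats::rbinom(n * N, 2L, rep(runif(N, maf_lo, maf_hi),
                                             each = n)), n, N)
  if (miss > 0) dos[matrix(runif(n * N) < miss, n, N)] <- NA_integer_
  chrom <- sort(rep_len(as.character(seq_len(n_chrom)), N))
  pos <- unlist(lapply(split(seq_len(N), chrom), function(ix)
    sort(sample.int(1e6, length(ix)))), use.names = FALSE)
  loci <- data.frame(locus_id = sprintf("L%03d", seq_len(N)),
                     chromosome = chrom, position_bp = pos,
                     allele_a = "A", allele_b = "B",
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                        sex = sample(c("male", "female"), n, replace = TRUE),
                        stringsAsFactors = FALSE)
  genotype_dataset(dos, loci, samples)
}

o_locus_call_rate <- function(ds) {
  apply(ds$dosages, 2, function(v) sum(!is.na(v)) / length(v))
}

o_sample_call_rate <- function(ds) {
  apply(ds$dosages, 1, function(v) sum(!is.na(v)) / length(v))
}

o_maf <- function(ds) {
  apply(ds$dosages, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    p <- sum(v) / (2 * length(v))
    min(p, 1 - p)
  })
}

o_ho <- function(ds) {
  per <- apply(ds$dosages, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    sum(v == 1) / length(v)
  })
  mean(per, na.rm = TRUE)
}

o_he <- function(ds) {
  per <- apply(ds$dosages, 2, function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (!n) return(NA_real_)
    p <- sum(v) / (2 * n)
    (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
  })
  mean(per, na.rm = TRUE)
}

# exact HWE p by direct log-factorial enumeration of all het counts
o_hwe <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  rare <- 2 * min(naa, nbb) + nab
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- sapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    lgamma(n + 1) - lgamma(homr + 1) - lgamma(h + 1) - lgamma(homc + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  })
  p <- exp(lp)
  p <- p / sum(p)
  sum(p[p <= p[hets == nab] * (1 + 1e-12)])
}

# textbook pairwise r^2 between two dosage vectors
o_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || var(x) == 0 || var(y) == 0) return(NA_real_)
  (sum((x - mean(x)) * (y - mean(y))) /
     sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
}

o_ibs <- function(ds) {
  n <- nrow(ds$dosages)
  out <- matrix(0, n, n, dimnames = list(ds$samples$sample_id,
                                         ds$samples$sample_id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- 0; joint <- 0
    for (k in seq_len(ncol(ds$dosages))) {
      a <- ds$dosages[i, k]; b <- ds$dosages[j, k]
      if (is.na(a) || is.na(b)) next
      joint <- joint + 1
      shared <- shared + (2 - abs(a - b))
    }
    out[i, j] <- 1 - shared / (2 * joint)
  }
  out
}

o_vanraden <- function(ds) {
  d <- ds$dosages
  # loci with no typed calls have undefined frequency and are excluded
  d <- d[, colSums(!is.na(d)) > 0, drop = FALSE]
  n <- nrow(d); N <- ncol(d)
  p <- numeric(N)
  for (k in seq_len(N)) {
    v <- d[, k][!is.na(d[, k])]
    p[k] <- sum(v) / (2 * length(v))
  }
  z <- matrix(0, n, N)
  for (i in seq_len(n)) for (k in seq_len(N)) {
    z[i, k] <- if (is.na(d[i, k])) 0 else d[i, k] - 2 * p[k]
  }
  g <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    g[i, j] <- sum(z[i, ] * z[j, ])
  }
  g / (2 * sum(p * (1 - p)))
}

# naive ROH scan following the written algorithm with explicit loops
o_roh <- function(d, pos, params) {
  m <- length(d)
  w <- params$window_snps
  if (m < w) return(NULL)
  nw <- m - w + 1
  hom_win <- logical(nw)
  for (i in seq_len(nw)) {
    win <- d[i:(i + w - 1)]
    hom_win[i] <- sum(win == 1, na.rm = TRUE) <= params$window_max_het &&
      sum(is.na(win)) <= params$window_max_missing
  }
  eligible <- logical(m)
  for (k in seq_len(m)) {
    wins <- intersect(seq_len(nw), (k - w + 1):k)
    eligible[k] <- mean(hom_win[wins]) >= params$min_hit_proportion
  }
  segs <- list()
  start <- NA
  for (k in seq_len(m + 1)) {
    gap_break <- k > 1 && k <= m && (pos[k] - pos[k - 1]) / 1000 > params$max_gap_kb
    if (k <= m && eligible[k] && !is.na(start) && gap_break) {
      segs[[length(segs) + 1]] <- c(start, k - 1)
      start <- k
    } else if (k <= m && eligible[k] && is.na(start)) {
      start <- k
    } else if ((k > m || !eligible[k]) && !is.na(start)) {
      segs[[length(segs) + 1]] <- c(start, k - 1)
      start <- NA
    }
  }
  out <- NULL
  for (s in segs) {
    nsnp <- s[2] - s[1] + 1
    len_kb <- (pos[s[2]] - pos[s[1]] + 1) / 1000
    if (nsnp > params$min_snps_per_segment &&
        len_kb > params$min_length_kb &&
        len_kb / nsnp <= params$min_density_kb_per_snp) {
      out <- rbind(out, data.frame(start_bp = pos[s[1]], end_bp = pos[s[2]],
                                   n_snps = nsnp, length_kb = len_kb))
    }
  }
  out
}

# dosages equal up to a consistent per-locus allele-label flip
expect_dosages_equivalent <- function(a, b) {
  expect_equal(dim(a), dim(b))
  for (k in seq_len(ncol(a))) {
    same <- isTRUE(all.equal(a[, k], b[, k]))
    flip <- isTRUE(all.equal(a[, k], 2L - b[, k]))
    expect_true(same || flip,
                label = paste("column", k, "equal up to allele flip"))
  }
}

withr_tempdir <- function() withr::local_tempdir(.local_envir = parent.frame())
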