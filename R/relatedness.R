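#' VanRaden genomic relationship matrix (method 1)
#'
#' G = Z Z' / (2 * sum_k p_k (1 - p_k)), where Z holds dosages centered by
#' twice the allele-b frequency and p_k is that frequency. Missing dosages
#' are mean-imputed (centered value 0). Loci with undefined frequency
#' (no calls) are excluded; monomorphic loci contribute nothing to the
#' denominator.
#'
#' @param dataset a `genotype_dataset` with at least two samples.
#' @param freqs optional vector of allele-b frequencies to center with
#'   (e.g. base-population frequencies); defaults to frequencies observed
#'   in the dataset.
#' @return a `g_matrix` list: `values` (n x n symmetric matrix),
#'   `allele_freqs_used`, `n_loci_used`.
#' @export
vanraden_g <- function(dataset, freqs = NULL) {
  if (n_samples(dataset) < 2) stop("need at least two samples")
  p <- if (is.null(freqs)) alt_allele_freq(dataset) else freqs
  if (length(p) != n_loci(dataset)) stop("freqs length must match locus count")
  use <- !is.na(p)
  p <- p[use]
  d <- dataset$dosages[, use, drop = FALSE]
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all usable loci are monomorphic: G denominator is 0")
  z <- sweep(d, 2, 2 * p, `-`)
  z[is.na(z)] <- 0
  g <- tcrossprod(z) / denom
  ids <- dataset$samples$sample_id
  dimnames(g) <- list(ids, ids)
  structure(list(values = g, allele_freqs_used = p, n_loci_used = sum(use)),
            class = "g_matrix")
}

#' Kinship normalization of G
#'
#' KS_jk = G_jk / sqrt(G_jj * G_kk); the diagonal is exactly 1 wherever
#' defined. Pairs whose diagonal product is not positive are listed in
#' `undefined_pairs` and set `NA`.
#'
#' @param g a `g_matrix` from [vanraden_g()], or a plain symmetric matrix.
#' @return a `kinship_matrix` list: `values` (n x n), `undefined_pairs`
#'   (two-column character matrix, possibly empty).
#' @export
kinship_from_g <- function(g) {
  gm <- if (inherits(g, "g_matrix")) g$values else as.matrix(g)
  dg <- diag(gm)
  sc <- sqrt(outer(dg, dg))
  ks <- gm / sc
  bad_i <- which(dg <= 0)
  undef <- NULL
  if (length(bad_i)) {
    ids <- rownames(gm)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(gm)))
    ks[bad_i, ] <- NA_real_
    ks[, bad_i] <- NA_real_
    pairs <- expand.grid(i = bad_i, j = seq_len(nrow(gm)))
    pairs <- pairs[pairs$i != pairs$j, ]
    undef <- unique(t(apply(cbind(ids[pairs$i], ids[pairs$j]), 1, sort)))
  }
  dv <- diag(ks)
  dv[dg > 0] <- 1
  diag(ks) <- dv
  structure(list(values = ks,
                 undefined_pairs = if (is.null(undef))
                   matrix(character(0), 0, 2) else undef),
            class = "kinship_matrix")
}

#' Identity-by-state allele-sharing distance
#'
#' For each sample pair, similarity = (sum over jointly typed loci of
#' 2 - |dosage_i - dosage_j|) / (2 * number of jointly typed loci);
#' distance = 1 - similarity. A pair with no jointly typed locus is an
#' error.
#'
#' @param dataset a `genotype_dataset` with at least two samples.
#' @return an `ibs_distance` list: `values` (n x n symmetric matrix in
#'   `[0, 1]` with zero diagonal), `labels`.
#' @export
ibs_distance <- function(dataset) {
  n <- n_samples(dataset)
  if (n < 2) stop("need at least two samples")
  d <- dataset$dosages
  obs <- !is.na(d)
  d0 <- d; d0[!obs] <- 0L
  storage.mode(d0) <- "double"
  storage.mode(obs) <- "double"
  joint <- obs %*% t(obs)                       # jointly typed locus counts
  if (any(joint[upper.tri(joint)] == 0)) {
    pr <- which(joint == 0 & upper.tri(joint), arr.ind = TRUE)[1, ]
    stop("no jointly typed loci for pair ",
         dataset$samples$sample_id[pr[1]], " / ",
         dataset$samples$sample_id[pr[2]])
  }
  # sum |di - dj| over joint loci, via counts of each dosage class
  is0 <- (d0 == 0) * obs; is1 <- (d0 == 1) * obs; is2 <- (d0 == 2) * obs
  # |di-dj|: 0 vs 2 differs by 2; 1 vs {0,2} differs by 1
  absdiff <- 2 * (is0 %*% t(is2) + is2 %*% t(is0)) +
    (is1 %*% t(is0 + is2) + (is0 + is2) %*% t(is1))
  sim <- (2 * joint - absdiff) / (2 * joint)
  dist <- 1 - sim
  diag(dist) <- 0
  ids <- dataset$samples$sample_id
  dimnames(dist) <- list(ids, ids)
  structure(list(values = dist, labels = ids), class = "ibs_distance")
}

#' Relationship-coefficient distribution summary
#'
#' Summarizes the off-diagonal upper triangle of a kinship matrix: the mean
#' coefficient and the fraction of pairs in each interval defined by
#' `breaks` (intervals closed on the right: (-Inf, b1], (b1, b2], ...,
#' (bk, Inf)).
#'
#' @param ks a `kinship_matrix` or plain symmetric matrix.
#' @param breaks increasing numeric thresholds (default 0.125, 0.25, 0.5).
#' @return a list with `mean_ks`, `table` (data.frame: `interval`,
#'   `n_pairs`, `fraction`), and `n_pairs` total.
#' @export
relationship_distribution <- function(ks, breaks = c(0.125, 0.25, 0.5)) {
  km <- if (inherits(ks, "kinship_matrix")) ks$values else as.matrix(ks)
  if (nrow(km) < 2) stop("need at least two samples")
  vals <- km[upper.tri(km)]
  vals <- vals[!is.na(vals)]
  edges <- c(-Inf, sort(breaks), Inf)
  cutf <- cut(vals, edges, right = TRUE, include.lowest = FALSE)
  counts <- as.integer(table(cutf))
  data_tab <- data.frame(interval = levels(cutf), n_pairs = counts,
                         fraction = counts / length(vals),
                         stringsAsFactors = FALSE)
  list(mean_ks = mean(vals), table = data_tab, n_pairs = length(vals))
}

#' Write a square labelled matrix as TSV
#'
#' @param m matrix (or `g_matrix` / `kinship_matrix` / `ibs_distance`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, c("g_matrix", "kinship_matrix", "ibs_distance"))) m <- m$values
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
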