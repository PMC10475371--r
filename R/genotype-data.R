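#' Genotype dataset container
#'
#' Bundles a diploid dosage matrix with its locus map and sample metadata.
#' Dosages count copies of `allele_b` at each locus: 0, 1, 2 or `NA`
#' (missing). Loci are stored sorted by chromosome then physical position;
#' the dosage matrix columns follow the locus order, rows the sample order.
#'
#' @param dosages integer matrix, samples in rows, loci in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param loci data.frame with columns `locus_id`, `chromosome`,
#'   `position_bp` (1-based), `allele_a`, `allele_b`.
#' @param samples data.frame with columns `sample_id` and `sex`
#'   (`"male"`, `"female"` or `"unknown"`).
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, loci, samples) {
  dosages <- as.matrix(dosages)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_l <- c("locus_id", "chromosome", "position_bp", "allele_a", "allele_b")
  if (!all(need_l %in% names(loci))) {
    stop("loci must have columns: ", paste(need_l, collapse = ", "))
  }
  if (!all(c("sample_id", "sex") %in% names(samples))) {
    stop("samples must have columns sample_id, sex")
  }
  if (nrow(dosages) != nrow(samples)) {
    stop("dosage rows (", nrow(dosages), ") != number of samples (",
         nrow(samples), ")")
  }
  if (ncol(dosages) != nrow(loci)) {
    stop("dosage columns (", ncol(dosages), ") != number of loci (",
         nrow(loci), ")")
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (any(loci$position_bp < 0)) stop("position_bp must be >= 0")

  ord <- order(chrom_order_key(loci$chromosome), loci$position_bp)
  loci <- loci[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  rownames(loci) <- NULL
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(samples$sample_id, loci$locus_id)
  structure(list(dosages = dosages, loci = loci, samples = samples),
            class = "genotype_dataset")
}

# numeric-aware chromosome sort key ("2" before "10", non-numeric labels last)
chrom_order_key <- function(chrom) {
  chrom <- as.character(chrom)
  u <- unique(chrom)
  unum <- suppressWarnings(as.numeric(u))
  u_sorted <- u[order(ifelse(is.na(unum), Inf, unum), u)]
  match(chrom, u_sorted)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", n_samples(x), "samples x", n_loci(x), "loci on",
      length(unique(x$loci$chromosome)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  invisible(x)
}

#' Number of samples / loci in a dataset
#' @param dataset a `genotype_dataset`.
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$dosages)

#' @rdname n_samples
#' @export
n_loci <- function(dataset) ncol(dataset$dosages)

#' Subset a genotype dataset
#'
#' @param dataset a `genotype_dataset`.
#' @param samples logical/integer/character index over samples (optional).
#' @param loci logical/integer/character index over loci (optional).
#' @return the subset `genotype_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, loci = NULL) {
  si <- seq_len(n_samples(dataset))
  li <- seq_len(n_loci(dataset))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) {
      match(samples, dataset$samples$sample_id)
    } else si[samples]
    if (anyNA(si)) stop("unknown sample id in subset")
  }
  if (!is.null(loci)) {
    li <- if (is.character(loci)) match(loci, dataset$loci$locus_id) else li[loci]
    if (anyNA(li)) stop("unknown locus id in subset")
  }
  genotype_dataset(dataset$dosages[si, li, drop = FALSE],
                   dataset$loci[li, , drop = FALSE],
                   dataset$samples[si, , drop = FALSE])
}

# orient so that allele_b is the minor allele (PLINK A1-minor convention);
# ties at MAF 0.5 broken by lexicographic order, allele_b = smaller symbol's
# partner so that allele_a < allele_b lexicographically.
orient_minor_b <- function(dataset) {
  d <- dataset$dosages
  loci <- dataset$loci
  nm <- colSums(!is.na(d))
  p_b <- colSums(d, na.rm = TRUE) / (2 * pmax(nm, 1L))
  flip <- p_b > 0.5 | (p_b == 0.5 & loci$allele_b < loci$allele_a)
  flip[nm == 0] <- FALSE
  if (any(flip)) {
    d[, flip] <- 2L - d[, flip]
    tmp <- loci$allele_a[flip]
    loci$allele_a[flip] <- loci$allele_b[flip]
    loci$allele_b[flip] <- tmp
  }
  genotype_dataset(d, loci, dataset$samples)
}

#' Read genotypes from PLINK text files (.ped/.map)
#'
#' The .map file has 4 whitespace-separated columns (chromosome, locus id,
#' genetic position, bp position); the .ped file has 6 metadata columns
#' followed by two allele columns per locus, with "0" coding a missing
#' allele. After loading, each locus is oriented so that `allele_b` is the
#' minor allele in the data (ties at 0.5 broken lexicographically), so
#' dosage = minor-allele count. Monomorphic loci are retained; their
#' `allele_b` is a placeholder symbol distinct from the observed allele.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file.
#' @param autosomes optional character vector of chromosome labels to keep
#'   (e.g. `as.character(1:18)`); `NULL` keeps everything.
#' @return a `genotype_dataset`.
#' @export
read_plink_text <- function(ped_path, map_path, autosomes = NULL) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"))
  names(map) <- c("chromosome", "locus_id", "cm", "position_bp")
  nl <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * nl
  lens <- lengths(toks)
  if (length(lens) > 1 && length(unique(lens)) > 1) {
    bad <- which(lens != lens[1])[1]
    stop("ragged .ped line ", bad, ": ", lens[bad], " fields where line 1 has ",
         lens[1])
  }
  if (length(lens) > 0 && lens[1] != want) {
    stop("locus count mismatch: .ped implies ", (lens[1] - 6) / 2,
         " loci but .map has ", nl)
  }
  ns <- length(toks)
  tok <- matrix(unlist(toks), nrow = ns, byrow = TRUE)
  sex_code <- tok[, 5]
  samples <- data.frame(
    sample_id = tok[, 2],
    sex = c("male", "female")[match(sex_code, c("1", "2"))],
    stringsAsFactors = FALSE)
  samples$sex[is.na(samples$sex)] <- "unknown"

  a1 <- tok[, 6L + 2L * seq_len(nl) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(nl), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  dos <- matrix(NA_integer_, ns, nl)
  allele_a <- allele_b <- character(nl)
  for (k in seq_len(nl)) {
    obs <- sort(unique(stats::na.omit(c(a1[, k], a2[, k]))))
    if (length(obs) > 2) {
      stop("locus ", map$locus_id[k], " has >2 alleles in .ped")
    }
    if (length(obs) == 0) {
      allele_a[k] <- "A"; allele_b[k] <- "B"
      next
    }
    if (length(obs) == 1) {
      allele_a[k] <- obs[1]
      allele_b[k] <- placeholder_allele(obs[1])
    } else {
      allele_a[k] <- obs[1]; allele_b[k] <- obs[2]
    }
    dos[, k] <- (a1[, k] == allele_b[k]) + (a2[, k] == allele_b[k])
    dos[is.na(a1[, k]) | is.na(a2[, k]), k] <- NA_integer_
  }
  loci <- data.frame(locus_id = map$locus_id, chromosome = map$chromosome,
                     position_bp = map$position_bp,
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  ds <- genotype_dataset(dos, loci, samples)
  if (!is.null(autosomes)) {
    ds <- subset_dataset(ds, loci = ds$loci$chromosome %in% autosomes)
  }
  orient_minor_b(ds)
}

# lexicographic successor used to label the unobserved allele of a
# monomorphic locus
placeholder_allele <- function(a) {
  bases <- c("A", "C", "G", "T")
  i <- match(a, bases)
  if (!is.na(i)) bases[(i %% 4) + 1] else paste0(a, "x")
}

#' Write a genotype dataset as PLINK text files
#'
#' Emits `<prefix>.ped` and `<prefix>.map`. Missing dosages become "0 0".
#'
#' @param dataset a `genotype_dataset`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_plink_text <- function(dataset, prefix) {
  map <- data.frame(dataset$loci$chromosome, dataset$loci$locus_id, 0,
                    dataset$loci$position_bp)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  ns <- n_samples(dataset); nl <- n_loci(dataset)
  sexcode <- match(dataset$samples$sex, c("male", "female"))
  sexcode[is.na(sexcode)] <- 0L
  geno <- matrix("", ns, nl)
  for (k in seq_len(nl)) {
    a <- dataset$loci$allele_a[k]; b <- dataset$loci$allele_b[k]
    g <- dataset$dosages[, k]
    geno[, k] <- c(paste(a, a), paste(a, b), paste(b, b))[g + 1L]
    geno[is.na(g), k] <- "0 0"
  }
  body <- if (ns == 0) {
    character(0)
  } else {
    meta <- paste(dataset$samples$sample_id, dataset$samples$sample_id,
                  0, 0, sexcode, -9)
    if (nl > 0) paste(meta, apply(geno, 1, paste, collapse = " ")) else meta
  }
  writeLines(body, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read genotypes from a VCF file
#'
#' Biallelic SNP records are converted to dosages of the ALT allele
#' (REF -> `allele_a`, ALT -> `allele_b`); `./.` becomes missing.
#' Multiallelic records are skipped; the number skipped is attached as
#' attribute `"n_skipped_multiallelic"`. After loading, loci are oriented
#' so `allele_b` is the minor allele, as in [read_plink_text()].
#'
#' @param path path to a VCF (plain or gzip).
#' @param autosomes optional chromosome whitelist, as in [read_plink_text()].
#' @return a `genotype_dataset`.
#' @export
read_vcf <- function(path, autosomes = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2 || !any(grepl("GT", v@gt[, 1]))) {
    stop("VCF has no GT format field")
  }
  multi <- grepl(",", fix$ALT)
  n_skip <- sum(multi)
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  alt1 <- substr(gt, 1, 1); alt2 <- substr(gt, 3, 3)
  dos <- (alt1 == "1") + (alt2 == "1")
  dos[alt1 == "." | alt2 == "."] <- NA_integer_
  dos <- t(dos)  # samples x loci
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  loci <- data.frame(locus_id = ids, chromosome = fix$CHROM,
                     position_bp = as.integer(fix$POS),
                     allele_a = fix$REF, allele_b = fix$ALT,
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt), sex = "unknown",
                        stringsAsFactors = FALSE)
  ds <- genotype_dataset(dos, loci, samples)
  if (!is.null(autosomes)) {
    ds <- subset_dataset(ds, loci = ds$loci$chromosome %in% autosomes)
  }
  ds <- orient_minor_b(ds)
  attr(ds, "n_skipped_multiallelic") <- n_skip
  ds
}
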