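#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration on a symmetric distance matrix with
#' zero diagonal (computation delegated to \code{ape::nj}). On distances
#' that are exactly additive on a binary tree, the tree (topology and
#' branch lengths) is recovered.
#'
#' @param distances an `ibs_distance` object or a symmetric numeric matrix
#'   with zero diagonal and row/column labels; at least 3 taxa.
#' @return an \code{ape} `phylo` tree with the input labels as tips.
#' @export
neighbor_joining <- function(distances) {
  dm <- if (inherits(distances, "ibs_distance")) distances$values
        else as.matrix(distances)
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  }
  ape::nj(stats::as.dist(dm))
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` tree.
#' @param path output file path.
#' @param clamp_negative replace negative branch lengths by 0 in the output
#'   (default TRUE; they can arise from non-additive distances).
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path, clamp_negative = TRUE) {
  if (clamp_negative && !is.null(tree$edge.length)) {
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Build boar families from a kinship matrix
#'
#' Boars are grouped by single linkage: families are the connected
#' components of the graph whose edges join boar pairs with kinship at or
#' above `threshold`. Families are labelled A, B, C, ... by decreasing
#' size, ties broken by the lexicographically smallest member id.
#'
#' @param ks a `kinship_matrix` (or plain labelled matrix).
#' @param boar_ids character vector of boar sample ids (non-empty, subset
#'   of the matrix labels).
#' @param threshold kinship threshold in (0, 1), default 0.1.
#' @return a `family_assignment` list: `families` (named list mapping
#'   family label to boar ids), `sow_assignments` (empty named character
#'   vector until [assign_sows()] runs), `threshold`.
#' @export
build_boar_families <- function(ks, boar_ids, threshold = 0.1) {
  km <- if (inherits(ks, "kinship_matrix")) ks$values else as.matrix(ks)
  if (length(boar_ids) == 0) stop("boar id list is empty")
  if (!all(boar_ids %in% rownames(km))) stop("boar id missing from kinship matrix")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  sub <- km[boar_ids, boar_ids, drop = FALSE]
  nb <- length(boar_ids)
  comp <- seq_len(nb)                     # union-find over boars
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (i < j && !is.na(sub[i, j]) && sub[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(nb), find, integer(1))
  groups <- split(boar_ids, roots)
  sizes <- lengths(groups)
  first <- vapply(groups, function(g) sort(g)[1], character(1))
  ord <- order(-sizes, first)
  groups <- lapply(groups[ord], sort)
  names(groups) <- LETTERS[seq_along(groups)]
  structure(list(families = groups,
                 sow_assignments = stats::setNames(character(0), character(0)),
                 threshold = threshold),
            class = "family_assignment")
}

#' Assign sows to boar families by kinship
#'
#' Each sow is assigned to the family whose boars have the highest mean
#' kinship with her, provided her kinship with at least one boar reaches
#' `threshold`; otherwise she is `"unassigned"` (the separate family of
#' sows unrelated to all boars). Ties go to the earlier family label.
#'
#' @param ks a `kinship_matrix` (or plain labelled matrix).
#' @param families a `family_assignment` from [build_boar_families()].
#' @param sow_ids character vector of sow sample ids.
#' @param threshold qualifying single-boar kinship, default 0.1.
#' @return the `family_assignment` with `sow_assignments` filled: a named
#'   character vector mapping sow id to family label or `"unassigned"`.
#' @export
assign_sows <- function(ks, families, sow_ids, threshold = 0.1) {
  km <- if (inherits(ks, "kinship_matrix")) ks$values else as.matrix(ks)
  if (!inherits(families, "family_assignment")) {
    stop("families must come from build_boar_families()")
  }
  if (!all(sow_ids %in% rownames(km))) stop("sow id missing from kinship matrix")
  labs <- names(families$families)
  assign <- stats::setNames(rep("unassigned", length(sow_ids)), sow_ids)
  for (s in sow_ids) {
    mean_ks <- vapply(families$families,
                      function(b) mean(km[s, b], na.rm = TRUE), numeric(1))
    max_single <- vapply(families$families,
                         function(b) max(km[s, b], na.rm = TRUE), numeric(1))
    if (any(max_single >= threshold, na.rm = TRUE)) {
      assign[s] <- labs[which.max(mean_ks)]
    }
  }
  families$sow_assignments <- assign
  families
}

#' Family table as a data.frame
#'
#' @param families a `family_assignment` with sows assigned.
#' @param ks optional kinship matrix to add each animal's mean kinship to
#'   its family's boars.
#' @return data.frame with columns `sample_id`, `role`, `family`,
#'   `mean_ks_to_family`.
#' @export
family_table <- function(families, ks = NULL) {
  km <- if (inherits(ks, "kinship_matrix")) ks$values else ks
  rows <- list()
  for (lab in names(families$families)) {
    for (b in families$families[[lab]]) {
      mk <- if (!is.null(km)) {
        others <- setdiff(families$families[[lab]], b)
        if (length(others)) mean(km[b, others]) else NA_real_
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = b, role = "boar", family = lab,
        mean_ks_to_family = mk, stringsAsFactors = FALSE)
    }
  }
  for (s in names(families$sow_assignments)) {
    lab <- families$sow_assignments[[s]]
    mk <- if (!is.null(km) && lab != "unassigned") {
      mean(km[s, families$families[[lab]]])
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s, role = "sow", family = lab,
      mean_ks_to_family = mk, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
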