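ks_matrix <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  m
}

test_that("three-taxon neighbor joining gives the closed-form limb lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  co <- ape::cophenetic.phylo(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(co, d, tolerance = 1e-12)
  # limb of A = (d_AB + d_AC - d_BC) / 2 = 1
  a_edge <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(a_edge, 1)
})

test_that("neighbor joining recovers an additive four-taxon tree exactly", {
  # tree: (A:1, B:2) -- internal 5 -- (C:3, D:4)
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["C", "D"] <- d["D", "C"] <- 7
  d["A", "C"] <- d["C", "A"] <- 1 + 5 + 3
  d["A", "D"] <- d["D", "A"] <- 1 + 5 + 4
  d["B", "C"] <- d["C", "B"] <- 2 + 5 + 3
  d["B", "D"] <- d["D", "B"] <- 2 + 5 + 4
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-12)
  expect_true(setequal(sort(tr$edge.length),
                       sort(c(1, 2, 3, 4, 5))))
})

test_that("neighbor joining validates its input", {
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
  bad <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3)
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("newick output round-trips and clamps negative branches", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  tmp <- withr_tempdir()
  write_newick(tr, file.path(tmp, "t.nwk"))
  txt <- readLines(file.path(tmp, "t.nwk"))
  expect_match(txt, "^\\(.*\\);$")
  back <- ape::read.tree(file.path(tmp, "t.nwk"))
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[c("A", "B", "C"), c("A", "B", "C")],
               ape::cophenetic.phylo(tr)[c("A", "B", "C"), c("A", "B", "C")])
  tr$edge.length[1] <- -0.5
  write_newick(tr, file.path(tmp, "neg.nwk"))
  expect_false(grepl("-", readLines(file.path(tmp, "neg.nwk"))))
})

test_that("boar families are single-linkage components at the 0.1 threshold", {
  ids <- paste0("b", 1:6)
  m <- diag(6) * 0 + 0.02
  diag(m) <- 1
  m[1, 2] <- m[2, 1] <- 0.3
  m[2, 3] <- m[3, 2] <- 0.15
  m[1, 3] <- m[3, 1] <- 0.25
  fam <- build_boar_families(ks_matrix(m, ids), ids)
  expect_equal(lengths(fam$families), c(A = 3L, B = 1L, C = 1L, D = 1L))
  expect_equal(fam$families$A, c("b1", "b2", "b3"))

  # all isolated
  iso <- build_boar_families(ks_matrix(diag(6), ids), ids)
  expect_equal(length(iso$families), 6L)
  expect_true(all(lengths(iso$families) == 1))

  # chain a-b, b-c joined although a-c below threshold
  m2 <- diag(3)
  m2[1, 2] <- m2[2, 1] <- 0.12
  m2[2, 3] <- m2[3, 2] <- 0.12
  m2[1, 3] <- m2[3, 1] <- 0.01
  chain <- build_boar_families(ks_matrix(m2, c("a", "b", "c")), c("a", "b", "c"))
  expect_equal(chain$families$A, c("a", "b", "c"))
  expect_error(build_boar_families(ks_matrix(m2, c("a", "b", "c")),
                                   character(0)), "empty")
})

test_that("families form a partition and only refine as the threshold rises", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    m <- matrix(runif(n * n, 0, 0.4), n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    ids <- paste0("b", seq_len(n))
    lo <- build_boar_families(ks_matrix(m, ids), ids, threshold = 0.1)
    hi <- build_boar_families(ks_matrix(m, ids), ids, threshold = 0.25)
    expect_setequal(unlist(lo$families), ids)
    expect_equal(anyDuplicated(unlist(lo$families)), 0L)
    # every high-threshold family sits inside one low-threshold family
    for (f in hi$families) {
      holders <- sapply(lo$families, function(g) all(f %in% g))
      expect_equal(sum(holders), 1L)
    }
  }
})

test_that("sows attach to the closest qualifying family or stay unassigned", {
  ids <- c("b1", "b2", "sow1", "sow2")
  m <- diag(4)
  m[3, 1] <- m[1, 3] <- 0.05
  m[3, 2] <- m[2, 3] <- 0.3
  m[4, 1] <- m[1, 4] <- 0.05
  m[4, 2] <- m[2, 4] <- 0.04
  km <- ks_matrix(m, ids)
  fam <- build_boar_families(km, c("b1", "b2"))
  fam <- assign_sows(km, fam, c("sow1", "sow2"))
  boar_of <- function(lab) fam$families[[lab]]
  expect_equal(boar_of(unname(fam$sow_assignments["sow1"])), "b2")
  expect_equal(unname(fam$sow_assignments["sow2"]), "unassigned")
})

test_that("planted paternal half-sib families are recovered from gene-dropped data", {
  # 4 sire lines x 3 boars + sows sired inside/outside the lines
  n_lines <- 4
  cfg <- sim_config(n_loci = 8000, n_chromosomes = 8, seed = 52)
  sires <- paste0("S", seq_len(n_lines))
  boars <- paste0(rep(sires, each = 3), "_b", 1:3)
  dams <- paste0("D", seq_len(3 * n_lines))
  rsows <- paste0(rep(sires, each = 2), "_s", 1:2)
  rdams <- paste0("E", seq_len(2 * n_lines))
  usows <- paste0("U", 1:6)
  ped <- pedigree(data.frame(
    id = c(sires, dams, rdams, usows, boars, rsows),
    sire = c(rep(NA, n_lines + length(dams) + length(rdams) + 6),
             rep(sires, each = 3), rep(sires, each = 2)),
    dam = c(rep(NA, n_lines + length(dams) + length(rdams) + 6), dams, rdams),
    sex = "unknown"))
  founders <- simulate_founders(cfg, n_lines + length(dams) + length(rdams) + 6,
                                ids = c(sires, dams, rdams, usows))
  cohort <- gene_drop(ped, founders, cfg, linkage = "unlinked", seed = 53)
  obs <- subset_dataset(cohort, samples = c(boars, rsows, usows))
  ks <- kinship_from_g(vanraden_g(obs))
  fam <- build_boar_families(ks, boars)
  expect_equal(length(fam$families), n_lines)
  expect_true(all(lengths(fam$families) == 3))
  # each family is exactly one sire line
  for (f in fam$families) {
    expect_equal(length(unique(sub("_b.*", "", f))), 1L)
  }
  fam <- assign_sows(ks, fam, c(rsows, usows))
  for (s in rsows) {
    lab <- fam$sow_assignments[[s]]
    expect_equal(unique(sub("_b.*", "", fam$families[[lab]])),
                 sub("_s.*", "", s))
  }
  expect_true(all(fam$sow_assignments[usows] == "unassigned"))
})
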