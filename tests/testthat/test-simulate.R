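test_that("generators are reproducible given the seed", {
  cfg <- sim_config(n_loci = 500, n_chromosomes = 3, seed = 71)
  a <- simulate_founders(cfg, 10)
  b <- simulate_founders(cfg, 10)
  expect_identical(a$dosages, b$dosages)
  pan1 <- simulate_ld_panel(50, 30, rep(0.01, 20), sim_config(seed = 72))
  pan2 <- simulate_ld_panel(50, 30, rep(0.01, 20), sim_config(seed = 72))
  expect_identical(pan1$dosages, pan2$dosages)
  expect_false(identical(a$dosages,
                         simulate_founders(sim_config(n_loci = 500,
                                                      n_chromosomes = 3,
                                                      seed = 99), 10)$dosages))
})

test_that("founder frequencies and missingness match their configuration", {
  cfg <- sim_config(n_loci = 4000, n_chromosomes = 4,
                    founder_freq_range = c(0.5, 0.5), missing_rate = 0.1,
                    seed = 73)
  ds <- simulate_founders(cfg, 50)
  expect_lt(abs(mean(is.na(ds$dosages)) - 0.1), 0.01)
  # unfolded frequency: every locus simulated at p = 0.5
  p_hat <- colMeans(ds$dosages, na.rm = TRUE) / 2
  expect_lt(abs(mean(p_hat) - 0.5), 0.01)
  expect_lt(max(abs(p_hat - 0.5)), 0.25)
})

test_that("zero-recombination gene drop passes intact parental haplotypes", {
  cfg <- sim_config(n_loci = 300, n_chromosomes = 1,
                    recombination_rate_cm_per_mb = 0, seed = 74)
  # homozygous founders make haplotypes observable
  loci <- sim_locus_map(cfg)
  dosA <- matrix(rep(c(0L, 2L), length.out = 300), 1)
  dosB <- matrix(rep(c(2L, 0L), length.out = 300), 1)
  founders <- genotype_dataset(rbind(dosA, dosB), loci,
                               data.frame(sample_id = c("p1", "p2"),
                                          sex = c("male", "female")))
  ped <- pedigree(data.frame(id = c("p1", "p2", "o1"),
                             sire = c(NA, NA, "p1"), dam = c(NA, NA, "p2"),
                             sex = c("male", "female", "unknown")))
  dd <- gene_drop(ped, founders, cfg, linkage = "map", seed = 75)
  o <- dd$dosages["o1", ]
  # offspring = one intact haplotype from each homozygous parent: all hets
  expect_equal(unname(o), (dosA[1, ] + dosB[1, ]) / 2)
})

test_that("gene drop conserves allele frequencies in expectation", {
  cfg <- sim_config(n_loci = 3000, n_chromosomes = 3, seed = 76)
  n_fam <- 40
  sires <- sprintf("s%02d", 1:n_fam); dams <- sprintf("d%02d", 1:n_fam)
  offs <- sprintf("o%02d", 1:n_fam)
  ped <- pedigree(data.frame(id = c(sires, dams, offs),
                             sire = c(rep(NA, 2 * n_fam), sires),
                             dam = c(rep(NA, 2 * n_fam), dams),
                             sex = "unknown"))
  founders <- simulate_founders(cfg, 2 * n_fam, ids = c(sires, dams))
  dd <- gene_drop(ped, founders, cfg, seed = 77)
  off_ds <- subset_dataset(dd, samples = offs)
  pf <- colMeans(founders$dosages) / 2
  po <- colMeans(off_ds$dosages) / 2
  expect_lt(mean(abs(pf - po)), 0.06)
  expect_lt(abs(mean(pf) - mean(po)), 0.01)
})

test_that("selfing accumulates autozygosity across generations", {
  cfg <- sim_config(n_loci = 4000, n_chromosomes = 4,
                    founder_freq_range = c(0.5, 0.5), seed = 78)
  gens <- paste0("g", 0:4)
  ped <- pedigree(data.frame(id = gens,
                             sire = c(NA, gens[-5]), dam = c(NA, gens[-5]),
                             sex = "unknown"))
  founders <- simulate_founders(cfg, 1, ids = "g0")
  dd <- gene_drop(ped, founders, cfg, seed = 79)
  het <- sapply(gens, function(g)
    mean(dd$dosages[g, ] == 1L))
  expect_true(all(diff(het) < 0))
})

test_that("the LD panel realizes Sved's r2 and the independence limit", {
  cfg <- sim_config(seed = 80)
  pan <- simulate_ld_panel(50, 300, rep(0.005, 400), cfg)
  ld <- pairwise_r2(pan, max_distance_bp = 1e9)
  target <- 1 / (1 + 4 * 50 * 0.005)
  expect_lt(abs(mean(ld$r_squared) - target), 0.03)
  far <- simulate_ld_panel(50, 300, rep(5, 300), sim_config(seed = 81))
  ldf <- pairwise_r2(far, max_distance_bp = 1e12)
  expect_lt(mean(ldf$r_squared), 3 / 300)
})

test_that("implant_roh edits exactly the planned spans", {
  cfg <- sim_config(n_loci = 1000, n_chromosomes = 2, chrom_length_bp = 10e6,
                    founder_freq_range = c(0.45, 0.55), seed = 82)
  ds <- simulate_founders(cfg, 3)
  out <- implant_roh(ds, data.frame(sample_id = character(0),
                                    chromosome = character(0),
                                    start_bp = integer(0),
                                    end_bp = integer(0)))
  expect_identical(out$dataset$dosages, ds$dosages)
  plan <- data.frame(sample_id = "F001", chromosome = "1",
                     start_bp = 2e6, end_bp = 4e6)
  out <- implant_roh(ds, plan, seed = 83)
  inside <- ds$loci$chromosome == "1" & ds$loci$position_bp >= 2e6 &
    ds$loci$position_bp <= 4e6
  expect_true(all(out$dataset$dosages[1, inside] %in% c(0L, 2L)))
  expect_identical(out$dataset$dosages[1, !inside], ds$dosages[1, !inside])
  expect_identical(out$dataset$dosages[-1, ], ds$dosages[-1, ])
  expect_equal(out$truth$n_snps, sum(inside))
  bad <- rbind(plan, data.frame(sample_id = "F001", chromosome = "1",
                                start_bp = 3e6, end_bp = 5e6))
  expect_error(implant_roh(ds, bad), "overlapping")
  expect_error(implant_roh(ds, data.frame(sample_id = "F001",
                                          chromosome = "1", start_bp = 9e6,
                                          end_bp = 11e6)), "bounds")
})

test_that("pedigree validation rejects broken structures", {
  expect_error(pedigree(data.frame(id = c("a", "b"), sire = c(NA, "c"),
                                   dam = c(NA, "a"), sex = "unknown")),
               "does not precede")
  expect_error(pedigree(data.frame(id = c("a", "a"), sire = NA, dam = NA,
                                   sex = "unknown")), "duplicate")
  expect_error(pedigree(data.frame(id = "a", sire = "x", dam = NA,
                                   sex = "unknown")), "two parents or none")
  cfg <- sim_config(n_loci = 100, seed = 84)
  f <- simulate_founders(cfg, 1, ids = "zz")
  ped <- pedigree(data.frame(id = c("q", "r", "o"), sire = c(NA, NA, "q"),
                             dam = c(NA, NA, "r"), sex = "unknown"))
  expect_error(gene_drop(ped, f, cfg), "founders not in genotype data")
})
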