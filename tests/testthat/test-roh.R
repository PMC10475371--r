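single_chrom_ds <- function(dosage_vec, pos) {
  genotype_dataset(matrix(dosage_vec, 1),
    data.frame(locus_id = sprintf("L%04d", seq_along(pos)),
               chromosome = "1", position_bp = pos,
               allele_a = "A", allele_b = "B"),
    data.frame(sample_id = "x", sex = "unknown"))
}

# heterozygosity-rich background with a planted homozygous stretch
planted_run <- function(m, run, het_prob = 0.5, seed = 1) {
  set.seed(seed)
  d <- ifelse(runif(m) < het_prob, 1L, sample(c(0L, 2L), m, replace = TRUE))
  d[run] <- sample(c(0L, 2L), length(run), replace = TRUE)
  d
}

test_that("a planted homozygous stretch yields one segment matching the checker", {
  pos <- seq(25e3, by = 25e3, length.out = 200)
  d <- planted_run(200, 50:120, seed = 61)
  ds <- single_chrom_ds(d, pos)
  segs <- detect_roh(ds)
  expect_equal(nrow(segs), 1L)
  oracle <- o_roh(d, pos, roh_params())
  expect_equal(segs$start_bp, oracle$start_bp)
  expect_equal(segs$end_bp, oracle$end_bp)
  expect_equal(segs$n_snps, oracle$n_snps)
  # the planted run is covered
  expect_lte(segs$start_bp, pos[50] + 5e5)
  expect_gte(segs$end_bp, pos[120] - 5e5)
})

test_that("heterozygous samples and short runs produce no segments", {
  pos <- seq(10e3, by = 10e3, length.out = 200)
  allhet <- single_chrom_ds(rep(1L, 200), pos)
  expect_equal(nrow(detect_roh(allhet)), 0L)
  # 25 homozygous SNPs spread over > 2 Mb: fails the > 30 SNP filter
  pos2 <- seq(100e3, by = 100e3, length.out = 80)
  d <- planted_run(80, 30:54, seed = 62)
  expect_equal(nrow(detect_roh(single_chrom_ds(d, pos2))), 0L)
})

test_that("detection matches the exhaustive checker on random chromosomes", {
  set.seed(63)
  for (rep in 1:20) {
    m <- sample(60:200, 1)
    pos <- sort(sample.int(30e6, m))
    d <- ifelse(runif(m) < 0.12, 1L, sample(c(0L, 2L), m, replace = TRUE))
    d[runif(m) < 0.03] <- NA_integer_
    p <- roh_params(min_snps_per_segment = 10, min_length_kb = 100,
                    window_snps = 20)
    got <- detect_roh(single_chrom_ds(d, pos), p)
    want <- o_roh(d, pos, p)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("segments never overlap and always satisfy the filters", {
  set.seed(64)
  cfg <- sim_config(n_loci = 4000, n_chromosomes = 4, chrom_length_bp = 40e6,
                    founder_freq_range = c(0.4, 0.6), seed = 65)
  ds <- simulate_founders(cfg, 5)
  plan <- data.frame(sample_id = rep(ds$samples$sample_id, each = 2),
                     chromosome = rep(c("1", "3"), 5),
                     start_bp = 10e6, end_bp = 16e6)
  ds <- implant_roh(ds, plan, seed = 66)$dataset
  prm <- roh_params()
  segs <- detect_roh(ds, prm)
  expect_gt(nrow(segs), 0)
  expect_true(all(segs$n_snps > prm$min_snps_per_segment))
  expect_true(all(segs$length_kb > prm$min_length_kb))
  expect_true(all(segs$length_kb / segs$n_snps <= prm$min_density_kb_per_snp))
  for (key in unique(paste(segs$sample_id, segs$chromosome))) {
    s <- segs[paste(segs$sample_id, segs$chromosome) == key, ]
    s <- s[order(s$start_bp), ]
    if (nrow(s) > 1) expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
  }
})

test_that("F_ROH is total merged length over genome length", {
  expect_equal(froh(data.frame(sample_id = character(0),
                               chromosome = character(0), start_bp = integer(0),
                               end_bp = integer(0), n_snps = integer(0),
                               length_kb = numeric(0)))$f_roh, 0)
  segs <- data.frame(sample_id = "x", chromosome = c("1", "2"),
                     start_bp = c(1, 1), end_bp = c(60e6, 40e6 + 1) - 1,
                     n_snps = 100, length_kb = c(60e3, 40e3))
  r <- froh(segs, autosome_length_kb = 2450462.292)
  expect_equal(r$total_roh_kb, 100e3)
  expect_equal(r$f_roh, 100e3 / 2450462.292)
  # overlapping segments are merged before summing
  ov <- data.frame(sample_id = "x", chromosome = "1",
                   start_bp = c(1e6, 2e6), end_bp = c(3e6, 4e6),
                   n_snps = 10, length_kb = 0)
  expect_equal(froh(ov, autosome_length_kb = 1e4)$total_roh_kb, 3000 + 1 / 1000)
  # full coverage gives 1
  full <- data.frame(sample_id = "x", chromosome = "1", start_bp = 1,
                     end_bp = 1e7, n_snps = 10, length_kb = 1e4)
  expect_equal(froh(full, autosome_length_kb = 1e4)$f_roh, 1, tolerance = 1e-3)
  expect_error(froh(full, autosome_length_kb = 0), "> 0")
})

test_that("population mean F_ROH is the arithmetic mean", {
  expect_equal(population_mean_froh(c(0.10, 0.08)), 0.09)
  expect_equal(population_mean_froh(rep(0.2, 54)), 0.2)
  expect_error(population_mean_froh(numeric(0)), "no individual")
})

test_that("roh_summary reports per-individual counts and length classes", {
  segs <- data.frame(sample_id = "x", chromosome = "1",
                     start_bp = c(1, 2, 3), end_bp = c(4, 5, 6),
                     n_snps = 40, length_kb = c(3e3, 5e3, 8e3))
  s <- roh_summary(segs)
  expect_equal(s$per_individual$n_segments, 3L)
  expect_equal(s$per_individual$min_mb, 3)
  expect_equal(s$per_individual$max_mb, 8)
  expect_equal(unname(s$length_classes), c(2L, 1L))
  empty <- roh_summary(segs[0, ])
  expect_equal(nrow(empty$per_individual), 0L)
})

test_that("weakening a detection threshold never shrinks total ROH length", {
  set.seed(67)
  pos <- seq(5e3, by = 25e3, length.out = 500)
  d <- ifelse(runif(500) < 0.25, 1L, sample(c(0L, 2L), 500, replace = TRUE))
  d[120:220] <- sample(c(0L, 2L), 101, replace = TRUE)
  d[300:420] <- sample(c(0L, 2L), 121, replace = TRUE)
  ds <- single_chrom_ds(d, pos)
  base <- roh_params(min_snps_per_segment = 40, min_length_kb = 1500,
                     window_snps = 50, window_max_het = 0,
                     min_hit_proportion = 0.1)
  total <- function(p) {
    s <- detect_roh(ds, p)
    if (nrow(s) == 0) 0 else sum(s$length_kb)
  }
  t0 <- total(base)
  weaker <- list(
    roh_params(min_snps_per_segment = 20, min_length_kb = 1500,
               window_snps = 50, window_max_het = 0, min_hit_proportion = 0.1),
    roh_params(min_snps_per_segment = 40, min_length_kb = 800,
               window_snps = 50, window_max_het = 0, min_hit_proportion = 0.1),
    roh_params(min_snps_per_segment = 40, min_length_kb = 1500,
               window_snps = 50, window_max_het = 1, min_hit_proportion = 0.1),
    roh_params(min_snps_per_segment = 40, min_length_kb = 1500,
               window_snps = 50, window_max_het = 0, min_hit_proportion = 0.05))
  for (p in weaker) expect_gte(total(p), t0)
})
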