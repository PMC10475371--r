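#' Herd-shaped simulation preset
#'
#' Generates a cohort shaped like a small SPF conservation herd: 54
#' genotyped animals (6 boars in 4 sire lines - one line of three paternal
#' half-sib boars plus three singleton boars - 23 sows sharing one of the
#' four sires, and 25 unrelated founder sows) on a chip-like panel of
#' about 50k evenly spaced SNPs across 18 autosomes of 136 Mb. Autozygous
#' tracts are implanted per animal (segment counts uniform on 35-60,
#' lengths uniform on 3-8 Mb, mirroring the reported per-individual ROH
#' ranges) and 2% missingness is applied last.
#'
#' @param seed integer seed driving every stochastic step.
#' @param n_loci panel size (default 49,500; divisible across 18
#'   autosomes).
#' @param missing_rate final genotype missingness (default 0.02).
#' @return a list: `dataset` (the 54 observed animals), `pedigree` (full,
#'   including unobserved parents), `truth` (list with `boar_families`,
#'   `sow_family`, `roh_plan`, `autosome_length_kb`, `boar_ids`,
#'   `sow_ids`).
#' @export
simulate_herd <- function(seed = 1L, n_loci = 49500L, missing_rate = 0.02) {
  cfg <- sim_config(n_loci = n_loci, n_chromosomes = 18,
                    chrom_length_bp = 136e6, missing_rate = 0,
                    seed = seed)
  boars <- c("A1", "A2", "A3", "B1", "C1", "D1")
  boar_sire <- c("S1", "S1", "S1", "S2", "S3", "S4")
  rsows <- sprintf("R%02d", 1:23)
  rsow_sire <- rep(c("S1", "S2", "S3", "S4"), c(8, 5, 5, 5))
  fsows <- sprintf("F%02d", 1:25)
  boar_dams <- sprintf("DB%02d", seq_along(boars))
  rsow_dams <- sprintf("DR%02d", seq_along(rsows))
  founder_ids <- c(paste0("S", 1:4), boar_dams, rsow_dams, fsows)
  ped <- pedigree(data.frame(
    id = c(founder_ids, boars, rsows),
    sire = c(rep(NA, length(founder_ids)), boar_sire, rsow_sire),
    dam = c(rep(NA, length(founder_ids)), boar_dams, rsow_dams),
    sex = c(rep("male", 4), rep("female", length(boar_dams) +
              length(rsow_dams) + length(fsows)),
            rep("male", length(boars)), rep("female", length(rsows))),
    stringsAsFactors = FALSE))

  founders <- simulate_founders(cfg, length(founder_ids), ids = founder_ids,
                                sex = ped$sex[match(founder_ids, ped$id)])
  full <- gene_drop(ped, founders, cfg, linkage = "map", seed = seed + 1L)
  observed <- c(boars, rsows, fsows)
  ds <- subset_dataset(full, samples = observed)

  plan <- herd_roh_plan(observed, cfg, seed = seed + 2L)
  imp <- implant_roh(ds, plan, seed = seed + 3L)
  ds <- add_missingness(imp$dataset, missing_rate, seed = seed + 4L)

  sow_family <- stats::setNames(rep("unassigned", 48), c(rsows, fsows))
  sow_family[rsows] <- c(A = "A", B = "B", C = "C", D = "D")[
    c(rep("A", 8), rep("B", 5), rep("C", 5), rep("D", 5))]
  truth <- list(
    boar_families = list(A = c("A1", "A2", "A3"), B = "B1", C = "C1",
                         D = "D1"),
    sow_family = sow_family,
    roh_plan = imp$truth,
    autosome_length_kb = cfg$n_chromosomes * (cfg$chrom_length_bp / 1000),
    boar_ids = boars, sow_ids = c(rsows, fsows))
  list(dataset = ds, pedigree = ped, truth = truth)
}

# random non-overlapping autozygous-tract plan, one draw per animal
herd_roh_plan <- function(ids, cfg, seed) {
  local_seed(seed, {
    rows <- list()
    for (id in ids) {
      n_seg <- sample(35:60, 1)
      lens <- stats::runif(n_seg, 3e6, 8e6)
      placed <- lapply(as.character(seq_len(cfg$n_chromosomes)),
                       function(ch) cbind(numeric(0), numeric(0)))
      names(placed) <- as.character(seq_len(cfg$n_chromosomes))
      for (L in lens) {
        for (try in 1:200) {
          ch <- as.character(sample.int(cfg$n_chromosomes, 1))
          st <- floor(stats::runif(1, 1, cfg$chrom_length_bp - L))
          en <- st + L - 1
          have <- placed[[ch]]
          if (nrow(have) == 0 ||
              all(en < have[, 1] - 1 | st > have[, 2] + 1)) {
            placed[[ch]] <- rbind(have, c(st, en))
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = id, chromosome = ch, start_bp = st, end_bp = en,
              stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a herd preset and write it to disk
#'
#' Writes the genotypes as PLINK text files plus pedigree and truth tables.
#'
#' @param outdir output directory (created if needed).
#' @param seed simulation seed.
#' @param ... passed to [simulate_herd()].
#' @return invisibly, the [simulate_herd()] result.
#' @export
run_simulate <- function(outdir, seed = 1L, ...) {
  sim <- simulate_herd(seed = seed, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_plink_text(sim$dataset, file.path(outdir, "herd"))
  utils::write.table(as.data.frame(sim$pedigree), file.path(outdir, "pedigree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$roh_plan, file.path(outdir, "roh_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fam_truth <- data.frame(
    sample_id = c(unlist(sim$truth$boar_families, use.names = FALSE),
                  names(sim$truth$sow_family)),
    family = c(rep(names(sim$truth$boar_families),
                   lengths(sim$truth$boar_families)),
               unname(sim$truth$sow_family)), stringsAsFactors = FALSE)
  utils::write.table(fam_truth, file.path(outdir, "family_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sim)
}

#' Run the full population characterization
#'
#' Orchestrates the whole analysis on one dataset: three QC tracks
#' (polymorphism track: call rates + HWE; core track: call rates + HWE +
#' MAF; ROH track: call rates only), diversity parameters, LD-based
#' effective population size, VanRaden G and kinship, IBS distances, a
#' neighbor-joining tree, boar-family construction with sow assignment,
#' and ROH-based inbreeding. All outputs are written under `outdir`;
#' `summary.json` carries the headline parameters.
#'
#' @param dataset a `genotype_dataset`.
#' @param outdir output directory.
#' @param boar_ids,sow_ids sample ids of boars and sows; defaults taken
#'   from the dataset's `sex` metadata.
#' @param autosome_length_kb total autosome length L for F_ROH.
#' @param ne_bins distance-bin breakpoints in Morgans for the Ne estimate.
#' @param max_distance_bp,cm_per_mb,r2_thin passed to [pairwise_r2()].
#' @param ne_correction sample-size correction for [estimate_ne()].
#' @param family_threshold kinship threshold for family construction.
#' @param seed seed for the (only) stochastic step, r-squared pair
#'   thinning.
#' @param qc a [qc_config()] whose call-rate thresholds apply to all three
#'   tracks.
#' @return invisibly, a list with the summary, the per-stage objects and
#'   the output paths.
#' @export
run_characterize <- function(dataset, outdir,
                             boar_ids = NULL, sow_ids = NULL,
                             autosome_length_kb = 2450462.292,
                             ne_bins = seq(0.005, 0.05, by = 0.005),
                             max_distance_bp = 5e6, cm_per_mb = 1.0,
                             r2_thin = 0.1, ne_correction = "1/n",
                             family_threshold = 0.1, seed = 1L,
                             qc = qc_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(tool = "herdchar",
               version = as.character(utils::packageVersion("herdchar")),
               seed = seed,
               config_hash = cheap_hash(paste(autosome_length_kb,
                 paste(ne_bins, collapse = ","), max_distance_bp, cm_per_mb,
                 r2_thin, ne_correction, family_threshold)))

  if (is.null(boar_ids)) {
    boar_ids <- dataset$samples$sample_id[dataset$samples$sex == "male"]
  }
  if (is.null(sow_ids)) {
    sow_ids <- dataset$samples$sample_id[dataset$samples$sex == "female"]
  }

  # QC tracks share the call-rate thresholds; HWE/MAF tiers differ
  mk <- function(hwe, maf) qc_config(qc$min_locus_call_rate,
                                     qc$min_sample_call_rate,
                                     qc$hwe_p_threshold, qc$min_maf,
                                     enable_hwe = hwe, enable_maf = maf)
  qc_pn <- apply_qc(dataset, mk(TRUE, FALSE))
  qc_core <- apply_qc(dataset, mk(TRUE, TRUE))
  qc_roh <- apply_qc(dataset, mk(FALSE, FALSE))
  qc_json <- list(provenance = prov,
                  pn_track = qc_counts(qc_pn$report),
                  core_track = qc_counts(qc_core$report),
                  roh_track = qc_counts(qc_roh$report))
  jsonlite::write_json(qc_json, file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # diversity: P_N on its own track, the rest on the core track
  div_pn <- diversity_summary(qc_pn$dataset)
  div_core <- diversity_summary(qc_core$dataset)
  ld <- pairwise_r2(qc_core$dataset, max_distance_bp = max_distance_bp,
                    cm_per_mb = cm_per_mb, thin = r2_thin, thin_seed = seed)
  ne <- estimate_ne(ld, ne_bins, n_samples = n_samples(qc_core$dataset),
                    correction = ne_correction)
  write_tsv_prov(ne$table, file.path(outdir, "ne_bins.tsv"), prov)
  diversity <- list(provenance = prov, p_n = div_pn$p_n,
                    h_o = div_core$h_o, h_e = div_core$h_e,
                    m_polymorphic = div_pn$m_polymorphic,
                    n_loci_pn_track = div_pn$n_total_loci,
                    n_loci_core_track = div_core$n_total_loci,
                    ne_summary = ne$summary_ne)
  jsonlite::write_json(diversity, file.path(outdir, "diversity.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # relatedness and families
  g <- vanraden_g(qc_core$dataset)
  ks <- kinship_from_g(g)
  ibs <- ibs_distance(qc_core$dataset)
  write_matrix_tsv(g, file.path(outdir, "g_matrix.tsv"))
  write_matrix_tsv(ks, file.path(outdir, "ks_matrix.tsv"))
  write_matrix_tsv(ibs, file.path(outdir, "ibs_matrix.tsv"))
  tree <- neighbor_joining(ibs)
  write_newick(tree, file.path(outdir, "tree.nwk"))
  rel <- relationship_distribution(ks)
  fam <- build_boar_families(ks, boar_ids, threshold = family_threshold)
  fam <- assign_sows(ks, fam, sow_ids, threshold = family_threshold)
  write_tsv_prov(family_table(fam, ks), file.path(outdir, "families.tsv"),
                 prov)

  # ROH-based inbreeding on the lenient track
  segs <- detect_roh(qc_roh$dataset, roh_params())
  write_tsv_prov(segs, file.path(outdir, "roh.tsv"), prov)
  ft <- froh_table(segs, qc_roh$dataset$samples$sample_id,
                   autosome_length_kb = autosome_length_kb)
  write_tsv_prov(ft, file.path(outdir, "froh.tsv"), prov)

  summary <- list(provenance = prov,
                  ne = ne$summary_ne,
                  pn = div_pn$p_n,
                  ho = div_core$h_o,
                  he = div_core$h_e,
                  mean_ks = rel$mean_ks,
                  mean_froh = population_mean_froh(ft),
                  n_families = length(fam$families))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, qc = qc_json, diversity = diversity,
                 ne = ne, g = g, ks = ks, ibs = ibs, tree = tree,
                 relationship = rel, families = fam, roh = segs,
                 froh = ft, outdir = outdir))
}

qc_counts <- function(rep) {
  list(n_loci_input = rep$n_loci_input, n_loci_pass = rep$n_loci_pass,
       n_samples_removed = rep$n_samples_removed,
       removed_call_rate = rep$n_removed_call_rate,
       removed_hwe = rep$n_removed_hwe, removed_maf = rep$n_removed_maf)
}

# small stable content hash (djb2) for provenance stamps
cheap_hash <- function(x) {
  h <- 5381
  for (v in utf8ToInt(x)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

write_tsv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  writeLines(sprintf("# %s %s seed=%s config=%s", prov$tool, prov$version,
                     prov$seed, prov$config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
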