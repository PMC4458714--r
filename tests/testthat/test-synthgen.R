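test_that("generators are deterministic under a fixed seed and independent streams", {
  spec <- simulation_spec(seed = 33, n_proteins = 40L, n_contaminants = 5L,
                          n_true = 50L, n_false_per_class = 50L,
                          n_interactors = 5L, n_intervals = 30L,
                          bait_levels = c(bait = 4, bait_msl2kd = 3,
                                          bait_rnase = 2))
  d1 <- sim_database(spec)
  d2 <- sim_database(spec)
  expect_identical(d1$organism$sequence, d2$organism$sequence)
  db <- build_decoy_database(d1$organism, d1$contaminants)
  p1 <- sim_psms(spec, db)
  p2 <- sim_psms(spec, db)
  expect_identical(p1, p2)
  expect_identical(sim_counts(spec)$corrected, sim_counts(spec)$corrected)
  i1 <- sim_intervals(spec)
  i2 <- sim_intervals(spec)
  expect_identical(i1$query$intervals, i2$query$intervals)
  # a different seed changes output
  expect_false(identical(
    sim_database(simulation_spec(seed = 34, n_proteins = 40L,
                                 n_contaminants = 5L,
                                 n_interactors = 5L))$organism$sequence,
    d1$organism$sequence))
})

test_that("database generator plants shared tryptic peptides and honors sizes", {
  spec <- simulation_spec(seed = 12, n_proteins = 100L, n_contaminants = 7L,
                          shared_block_fraction = 0.1)
  dbs <- sim_database(spec)
  expect_equal(nrow(dbs$organism), 100L)
  expect_equal(nrow(dbs$contaminants), 7L)
  expect_true(all(dbs$contaminants$origin == "contaminant"))
  # at least one tryptic peptide owned by >= 2 proteins
  peps <- lapply(dbs$organism$sequence[1:15],
                 function(s) digest_tryptic(s, 0)$peptide)
  counts <- table(unlist(peps))
  expect_gte(max(counts), 2)
  # empty database
  expect_equal(nrow(sim_database(simulation_spec(seed = 1, n_proteins = 0L,
                                                 n_contaminants = 0L,
                                                 n_interactors = 0L))$organism),
               0L)
})

test_that("decoy and false-target scores come from one law; no true matches leaves ~nothing", {
  spec <- simulation_spec(seed = 44)
  dbs <- sim_database(spec)
  db <- build_decoy_database(dbs$organism, dbs$contaminants)
  psms <- compute_discriminant(sim_psms(spec, db), filter_config())
  truth <- setNames(attr(psms, "truth")$is_true, attr(psms, "truth")$spectrum_id)
  false_targets <- psms$discriminant[!psms$is_decoy & !truth[psms$spectrum_id]]
  decoys <- psms$discriminant[psms$is_decoy]
  ks <- suppressWarnings(ks.test(false_targets, decoys))
  expect_gt(ks$p.value, 0.05)
  # degenerate: no true matches -> the 1% filter keeps almost nothing
  spec0 <- simulation_spec(seed = 44, n_true = 0L, n_false_per_class = 800L)
  psms0 <- sim_psms(spec0, db)
  res0 <- filter_psms(psms0, filter_config(target_fdr = 0.01))
  expect_lte(nrow(res0$confident[!res0$confident$is_decoy, ]),
             0.05 * sum(!psms0$is_decoy))
})

test_that("count generator delivers exact totals, planted structure and labels", {
  spec <- simulation_spec(seed = 9, n_proteins = 120L, n_interactors = 12L,
                          totals = 900L)
  ce <- sim_counts(spec)
  expect_equal(unname(colSums(ce$unique)), rep(900, 15))
  truth <- attr(ce, "truth")
  expect_length(truth$interactors, 12L)
  expect_length(intersect(truth$msl2kd_sensitive, truth$rnase_sensitive), 0L)
  # planted interactors have visibly higher bait-side means
  bait_cols <- ce$samples$sample_id[ce$samples$condition == "bait"]
  ctrl_cols <- ce$samples$sample_id[ce$samples$condition %in%
                                      c("control_empty", "control_gfp")]
  lift <- rowMeans(ce$corrected[truth$interactors, bait_cols]) /
    pmax(rowMeans(ce$corrected[truth$interactors, ctrl_cols]), 0.5)
  expect_gt(median(lift), 2)
  # null world: with fold 1 and no treatment effects, FDR 0.2 calls stay rare
  spec_null <- simulation_spec(seed = 10, n_proteins = 150L,
                               n_interactors = 0L, enrichment_fold = 1,
                               n_treatment_sensitive = 0L, totals = 800L)
  calls <- call_interactors(sim_counts(spec_null), seed = 3)
  expect_lte(sum(calls$confident), 0.05 * nrow(calls))
})

test_that("interval generator plants jittered copies", {
  spec <- simulation_spec(seed = 15, n_intervals = 80L,
                          planted_fraction = 0.5, jitter_sd = 50)
  iv <- sim_intervals(spec)
  expect_equal(nrow(iv$query$intervals), 80L)
  expect_length(iv$truth, 40L)
  # planted fraction 0: no more correlation than chance (checked loosely)
  iv0 <- sim_intervals(simulation_spec(seed = 15, n_intervals = 200L,
                                       planted_fraction = 0))
  dc <- distance_correlation(iv0$query, iv0$reference, n_perm = 19, seed = 2)
  expect_lt(abs(dc$relative_ecdf_area_correlation), 0.15)
})

test_that("synthgen_all writes the full fixture directory with truth sidecar", {
  outdir <- withr::local_tempdir()
  spec <- simulation_spec(seed = 6, n_proteins = 25L, n_contaminants = 3L,
                          n_true = 40L, n_false_per_class = 40L,
                          n_interactors = 4L, n_intervals = 20L,
                          totals = 400L, enrichment_fold = 3,
                          bait_levels = c(bait = 3, bait_msl2kd = 2,
                                          bait_rnase = 2))
  paths <- synthgen_all(spec, outdir)
  expect_true(all(file.exists(paths)))
  db <- read_fasta(file.path(outdir, "db.fasta"))
  expect_equal(nrow(db), 2 * (25 + 3))
  psms <- read_psm_table(file.path(outdir, "psms.tsv"))
  expect_true(all(c("spectrum_id", "peptide", "is_decoy") %in% names(psms)))
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 6)
  expect_length(truth$count_truth$interactors, 4L)
  sizes <- read_chrom_sizes(file.path(outdir, "sizes.tsv"))
  expect_equal(sizes, spec$genome)
})
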