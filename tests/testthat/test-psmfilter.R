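scored_psms <- function(target_scores, decoy_scores, charge = 2L) {
  rbind(
    make_psms(sprintf("T%04d", seq_along(target_scores)), charge = charge,
              discriminant = target_scores),
    make_psms(sprintf("D%04d", seq_along(decoy_scores)), charge = charge,
              accessions = "REV_P1", is_decoy = TRUE,
              discriminant = decoy_scores)
  )
}

test_that("spectrum prefilter applies ion, intensity and inclusive MH+ gates", {
  psms <- make_psms(rep("PEPK", 10))
  psms$n_ions <- c(25, 24, 40, 40, 40, 40, 40, 40, 40, 40)
  psms$intensity <- c(1000, 1000, 500, 501, 1000, 1000, 1000, 1000, 1000, 1000)
  psms$mhplus <- c(550, 600, 600, 550, 500, 4000, 4001, 549.9, 2000, 3000)
  out <- prefilter_spectra(psms, filter_config())
  # hand application of the predicates: rows 1, 4, 6, 9, 10 survive
  expect_equal(out$spectrum_id, psms$spectrum_id[c(1, 4, 6, 9, 10)])
  # boundary cases are inclusive for ions and MH+, exclusive for intensity
  expect_true("sp0001" %in% out$spectrum_id)   # 25 ions, MH+ 550
  expect_false("sp0003" %in% out$spectrum_id)  # intensity exactly 500
  expect_error(prefilter_spectra(psms[, setdiff(names(psms), "mhplus")]),
               "mhplus")
})

test_that("discriminant is the weighted inner product of transformed features", {
  expect_equal(discriminant_combine(c(a = 0, b = 0), c(a = 1, b = 2)), 0)
  expect_equal(discriminant_combine(c(a = 0.5, b = 0.25), c(a = 1, b = 2)), 1.0)
  f <- c(a = 0.3, b = -0.2)
  expect_equal(discriminant_combine(2 * f, c(a = 1.5, b = 4)),
               2 * discriminant_combine(f, c(a = 1.5, b = 4)))
  expect_error(discriminant_combine(c(a = 1), c(a = 1, b = 2)), "b")

  psms <- make_psms("PEPTIDEK")
  psms$primary_score <- 3
  psms$delta_score <- 0.2
  psms$rank_score <- 2
  out <- compute_discriminant(psms, filter_config())
  expect_equal(out$discriminant,
               1.0 * (log(3) - log(8)) + 8.0 * 0.2 + 0.2 * (-log(2)))
})

test_that("class histograms partition records and conserve mass", {
  grid <- expand.grid(charge = 1:3, ntt = 0:2, mod = c("unmod", "M+16"),
                      stringsAsFactors = FALSE)
  psms <- make_psms(rep("PEPK", nrow(grid)), charge = grid$charge,
                    mod_state = grid$mod, discriminant = rnorm(nrow(grid)))
  psms$ntt <- grid$ntt
  h <- class_histograms(psms)
  expect_length(h, 18L)
  expect_equal(sum(vapply(h, function(x) sum(x$target$counts), numeric(1))),
               nrow(grid))
  one <- class_histograms(make_psms("PEPK", discriminant = 1.23))
  expect_length(one, 1L)
  expect_equal(sum(one[[1]]$target$counts), 1L)
  expect_equal(sum(one[[1]]$decoy$counts), 0L)
  both <- class_histograms(scored_psms(rnorm(100), rnorm(100)))
  expect_equal(sum(both[[1]]$target$counts), 100L)
  expect_equal(sum(both[[1]]$decoy$counts), 100L)
})

test_that("fdr_threshold matches a brute-force scan over bin edges", {
  # worked example: targets {5,4,3,2,1}, decoys {2.5,1.5}
  breaks <- seq(0, 6, by = 0.1)
  th <- fdr_threshold(score_histogram(c(5, 4, 3, 2, 1), breaks),
                      score_histogram(c(2.5, 1.5), breaks), 0.01)
  expect_equal(th$threshold, 3)
  expect_equal(th$kept_targets, 3L)
  expect_equal(th$est_fdr, 0)
  # no decoys: lowest target bin edge, all kept
  th2 <- fdr_threshold(score_histogram(c(1.25, 2, 3), breaks),
                       score_histogram(numeric(), breaks), 0.01)
  expect_equal(th2$kept_targets, 3L)
  expect_lte(th2$threshold, 1.25)
  # all decoys above all targets: class rejects everything
  th3 <- fdr_threshold(score_histogram(c(1, 1.5), breaks),
                       score_histogram(c(5, 5.5), breaks), 0.01)
  expect_equal(th3$kept_targets, 0L)
  expect_equal(th3$threshold, Inf)
  # random histograms against the oracle
  set.seed(11)
  for (i in 1:25) {
    ts <- rnorm(200, 1); ds <- rnorm(50)
    br <- seq(floor(min(ts, ds)), ceiling(max(ts, ds)) + 0.1, by = 0.1)
    fdr <- sample(c(0.01, 0.05, 0.2), 1)
    got <- fdr_threshold(score_histogram(ts, br), score_histogram(ds, br), fdr)
    want <- oracle_fdr_threshold(ts, ds, br, fdr)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$kept_targets, want$kept)
  }
})

test_that("filter_psms keeps a monotone, idempotent confident set", {
  set.seed(5)
  psms <- rbind(scored_psms(c(rnorm(500, 4), rnorm(500)), rnorm(500)),
                scored_psms(c(rnorm(500, 4), rnorm(500)), rnorm(500),
                            charge = 3L))
  res01 <- filter_psms(psms, filter_config(target_fdr = 0.01))
  res05 <- filter_psms(psms, filter_config(target_fdr = 0.05))
  # monotone in the requested FDR
  expect_true(all(res01$confident$spectrum_id %in% res05$confident$spectrum_id))
  # idempotent under the same thresholds
  thr <- setNames(res01$report$threshold, res01$report$class)
  again <- res01$confident[res01$confident$discriminant >=
                             thr[psm_class(res01$confident)], ]
  expect_equal(nrow(again), nrow(res01$confident))
  # empty input
  empty <- filter_psms(psms[0, ], filter_config())
  expect_equal(nrow(empty$confident), 0L)
  expect_equal(nrow(empty$report), 0L)
  # report carries the weights used
  expect_equal(attr(res01$report, "weights"),
               filter_config()$discriminant_weights)
})

test_that("small-decoy classes fall back to the pooled histogram", {
  set.seed(6)
  big <- scored_psms(c(rnorm(800, 4), rnorm(800)), rnorm(800))
  tiny <- scored_psms(rnorm(30, 4), rnorm(10), charge = 3L)
  res <- filter_psms(rbind(big, tiny), filter_config())
  expect_true(res$report$pooled[res$report$class == "3+/ntt2/unmod"])
  expect_false(res$report$pooled[res$report$class == "2+/ntt2/unmod"])
})

test_that("decoy status resolves ambiguous accession lists to target", {
  expect_equal(psm_is_decoy(c("REV_P1;REV_P2", "REV_P1;P2", "P1")),
               c(TRUE, FALSE, FALSE))
})

test_that("realized FDP on labeled synthetic PSMs stays within twice the request", {
  spec <- simulation_spec(seed = 41)
  db <- build_decoy_database(sim_database(spec)$organism,
                             sim_database(spec)$contaminants)
  psms <- sim_psms(spec, db)
  truth <- setNames(attr(psms, "truth")$is_true, attr(psms, "truth")$spectrum_id)
  res <- filter_psms(psms, filter_config(target_fdr = 0.01))
  kept <- res$confident[!res$confident$is_decoy, ]
  expect_gt(nrow(kept), 1000)
  expect_lte(mean(!truth[kept$spectrum_id]), 0.02)
})
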