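#' Simulation specification
#'
#' Collects every tunable of the synthetic-data generators in one validated
#' list.  Defaults describe the "desk-scale" stated world used throughout
#' the test suite: 500 organism proteins (a full-scale run of 19577 is just
#' a parameter change) plus 179 random stand-ins for the common-contaminant
#' list; peptide-spectrum matches whose true matches score high and whose
#' false target matches and decoy matches are drawn i.i.d. from one shared
#' low-scoring law; an overdispersed count experiment (Dirichlet-multinomial
#' sampling, so per-sample totals are exact and per-protein marginals are
#' beta-binomial) with 500 background proteins, 50 planted interactors at
#' 5-fold enrichment, 3 replicates per condition, per-sample totals of 2000
#' and overdispersion 0.001 (replicate variance about three times Poisson at
#' these totals, matching typical AP-MS replicate scatter); and a
#' 3-chromosome toy genome of 1 Mb
#' chromosomes with 300 intervals per set, half of the query intervals
#' planted as jittered copies of reference intervals.
#'
#' Every generator derives its RNG stream from `seed` by a fixed documented
#' offset (database +1, PSMs +2, counts +3, intervals +4), so regenerating
#' one input does not perturb the others.
#'
#' @param seed master integer seed.
#' @param n_proteins,n_contaminants organism / contaminant database sizes.
#' @param peptide_blocks range of tryptic blocks per protein.
#' @param block_length range of residues per tryptic block.
#' @param shared_block_fraction fraction of proteins sharing one identical
#'   tryptic peptide block (exercises grouping and count splitting).
#' @param n_true,n_false_per_class true PSMs and false target matches (and
#'   equally many decoy matches) per peptide class.
#' @param psm_classes charge states used for synthetic PSM classes.
#' @param true_score_mean,true_score_sd,null_score_sd discriminant score
#'   law: true matches `N(true_score_mean, true_score_sd)`, false and decoy
#'   matches `N(0, null_score_sd)`.
#' @param n_reps replicates per condition.
#' @param totals per-sample total spectral counts.
#' @param theta count overdispersion.
#' @param n_interactors planted bait-specific interactors.
#' @param enrichment_fold interactor enrichment in bait-side samples.
#' @param n_treatment_sensitive planted treatment-sensitive interactors per
#'   treatment (disjoint subsets of the planted interactors).
#' @param treatment_folds named attenuation factors applied to sensitive
#'   interactors in the corresponding treatment condition.
#' @param bait_levels relative bait-protein abundance (in background-protein
#'   units) per bait-side condition; differs across conditions to exercise
#'   bait normalization.
#' @param genome named chromosome-length vector of the toy genome.
#' @param n_intervals intervals per interval set.
#' @param interval_width width range of generated intervals.
#' @param planted_fraction fraction of query intervals that are jittered
#'   copies of reference intervals.
#' @param jitter_sd standard deviation (bases) of the planted jitter.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_proteins = 500L,
                            n_contaminants = 179L,
                            peptide_blocks = c(5L, 12L),
                            block_length = c(6L, 14L),
                            shared_block_fraction = 0.1,
                            n_true = 1200L,
                            n_false_per_class = 1200L,
                            psm_classes = c(2L, 3L),
                            true_score_mean = 3.5,
                            true_score_sd = 0.8,
                            null_score_sd = 1,
                            n_reps = 3L,
                            totals = 2000L,
                            theta = 0.001,
                            n_interactors = 50L,
                            enrichment_fold = 5,
                            n_treatment_sensitive = 15L,
                            treatment_folds = c(msl2kd = 0.25, rnase = 0.25),
                            bait_levels = c(bait = 25, bait_msl2kd = 15,
                                            bait_rnase = 10),
                            genome = c(chr2L = 1e6, chr2R = 1e6, chr3L = 1e6),
                            n_intervals = 300L,
                            interval_width = c(500, 2000),
                            planted_fraction = 0.5,
                            jitter_sd = 200) {
  stopifnot(theta >= 0, theta < 1, planted_fraction >= 0,
            planted_fraction <= 1, enrichment_fold > 0,
            n_interactors <= n_proteins)
  structure(as.list(environment()), class = "simulation_spec")
}

aa_pool <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]  # no K/R/P: cut sites are explicit

random_block <- function(len) {
  paste0(paste(sample(aa_pool, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

#' Generate forward-only organism and contaminant databases
#'
#' Proteins are concatenations of random tryptic blocks (each ending in K or
#' R, with no internal K/R/P), so the in-silico digest is exact.  A
#' configurable fraction of organism proteins share one identical block,
#' guaranteeing shared tryptic peptides that exercise protein grouping and
#' shared-count splitting.  Deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec].
#' @return list with `organism` and `contaminants`, both forward-only
#'   [sequence_db] objects.
#' @export
sim_database <- function(spec) {
  with_seed(spec$seed + 1L, {
    shared_block <- random_block(10L)
    make_db <- function(n, prefix, origin, share = 0) {
      if (n == 0L) return(empty_sequence_db(origin))
      seqs <- vapply(seq_len(n), function(i) {
        k <- sample(seq(spec$peptide_blocks[1], spec$peptide_blocks[2]), 1L)
        blocks <- vapply(sample(seq(spec$block_length[1], spec$block_length[2]),
                                k, replace = TRUE),
                         random_block, character(1))
        if (share > 0 && i <= ceiling(share * n))
          blocks[sample(k, 1L)] <- shared_block
        paste(blocks, collapse = "")
      }, character(1))
      sequence_db(sprintf("%s%04d", prefix, seq_len(n)), seqs, origin = origin)
    }
    list(organism = make_db(spec$n_proteins, "G", "organism",
                            spec$shared_block_fraction),
         contaminants = make_db(spec$n_contaminants, "CONT", "contaminant"))
  })
}

#' Generate a synthetic PSM table with hidden truth labels
#'
#' True matches are real tryptic peptides of organism proteins with
#' discriminant-driving scores drawn from a high-scoring law; false target
#' matches and decoy matches are random peptides scored i.i.d. from one
#' shared low-scoring law (so decoy counts estimate false target counts).
#' Raw scores are generated such that the default discriminant of
#' [filter_config()] reproduces the intended score exactly.  Classes are
#' assigned over `spec$psm_classes` charge states (ntt 2, unmodified).  The
#' hidden truth labels are attached as attribute `"truth"` (a data frame
#' `spectrum_id`, `is_true`); pipeline code must not read them.
#'
#' @param spec a [simulation_spec].
#' @param database the concatenated target+decoy [sequence_db] from
#'   [build_decoy_database()].
#' @return a PSM data frame ready for [filter_psms()].
#' @export
sim_psms <- function(spec, database) {
  fwd <- database[!database$is_decoy & database$origin == "organism", ]
  dec <- database[database$is_decoy, ]
  with_seed(spec$seed + 2L, {
    # index of true tryptic peptides (no missed cleavage), length >= 6
    idx <- lapply(fwd$sequence, function(s) {
      p <- digest_tryptic(s, missed_cleavages = 0L)$peptide
      p[nchar(p) >= 6L]
    })
    pep2acc <- split(rep(fwd$accession, lengths(idx)),
                     unlist(idx, use.names = FALSE))
    all_true_peps <- names(pep2acc)
    n_cls <- length(spec$psm_classes)
    n_true <- spec$n_true * n_cls
    n_false <- spec$n_false_per_class * n_cls
    make_rows <- function(n, peptide, accessions, score, is_decoy) {
      cls <- rep_len(spec$psm_classes, n)
      rank_score <- sample(1:10, n, replace = TRUE)
      primary <- exp(rnorm(n, log(3), 0.3))
      f1 <- log(primary) - log(nchar(peptide))
      f3 <- -log(rank_score)
      cfg <- filter_config()
      w <- cfg$discriminant_weights
      delta <- (score - w[["lenlog_primary"]] * f1 -
                  w[["neglog_rank"]] * f3) / w[["delta"]]
      data.frame(peptide = peptide, charge = cls, ntt = rep(2L, n),
                 mod_state = rep("unmod", n), primary_score = primary,
                 delta_score = delta, rank_score = rank_score,
                 n_ions = 25L + rpois(n, 30),
                 intensity = runif(n, 600, 5000),
                 mhplus = runif(n, 600, 3900),
                 accessions = accessions, is_decoy = rep_len(is_decoy, n),
                 stringsAsFactors = FALSE)
    }
    true_peps <- sample(all_true_peps, n_true, replace = TRUE)
    true_rows <- make_rows(n_true, true_peps,
                           vapply(pep2acc[true_peps], paste, character(1),
                                  collapse = ";"),
                           rnorm(n_true, spec$true_score_mean,
                                 spec$true_score_sd),
                           FALSE)
    rand_pep <- function(n) vapply(sample(8:15, n, replace = TRUE),
                                   random_block, character(1))
    false_rows <- make_rows(n_false, rand_pep(n_false),
                            sample(fwd$accession, n_false, replace = TRUE),
                            rnorm(n_false, 0, spec$null_score_sd), FALSE)
    decoy_rows <- make_rows(n_false, rand_pep(n_false),
                            sample(dec$accession, n_false, replace = TRUE),
                            rnorm(n_false, 0, spec$null_score_sd), TRUE)
    psms <- rbind(true_rows, false_rows, decoy_rows)
    is_true <- rep(c(TRUE, FALSE, FALSE),
                   c(nrow(true_rows), nrow(false_rows), nrow(decoy_rows)))
    ord <- sample(nrow(psms))
    psms <- psms[ord, , drop = FALSE]
    is_true <- is_true[ord]
    psms <- data.frame(spectrum_id = sprintf("sp%06d", seq_len(nrow(psms))),
                       sample_id = "S1", psms, stringsAsFactors = FALSE)
    rownames(psms) <- NULL
    attr(psms, "truth") <- data.frame(spectrum_id = psms$spectrum_id,
                                      is_true = is_true,
                                      stringsAsFactors = FALSE)
    psms
  })
}

#' Generate an overdispersed count experiment with planted interactors
#'
#' Emulates the bait / empty-vector / GFP / MSL2-knockdown / RNase design:
#' background proteins at a common expected fraction in every sample,
#' planted interactors enriched `enrichment_fold`-fold in all bait-side
#' samples, disjoint subsets of them attenuated by `treatment_folds` in the
#' MSL2kd and RNase conditions, and a bait protein whose abundance differs
#' across bait-side conditions so that bait normalization matters.  Counts
#' are drawn per sample as Dirichlet-multinomial with concentration
#' `pi * (1 - theta) / theta`, giving exactly `spec$totals` counts per
#' column and beta-binomial(`pi_i`, `theta`) marginals.
#'
#' @param spec a [simulation_spec].
#' @return a [count_experiment] (corrected counts filled, bait id `"BAIT"`)
#'   with hidden truth attached as attribute `"truth"`: a list with
#'   `interactors`, `msl2kd_sensitive`, `rnase_sensitive`.
#' @export
sim_counts <- function(spec) {
  ids <- c("BAIT", sprintf("G%04d", seq_len(spec$n_proteins)))
  planted <- sprintf("G%04d", seq_len(spec$n_interactors))
  ms_sens <- planted[seq_len(min(spec$n_treatment_sensitive, length(planted)))]
  rn_sens <- setdiff(planted, ms_sens)
  rn_sens <- rn_sens[seq_len(min(spec$n_treatment_sensitive, length(rn_sens)))]
  conditions <- c("bait", "control_empty", "control_gfp",
                  "bait_msl2kd", "bait_rnase")
  samples <- data.frame(
    sample_id = unlist(lapply(conditions, function(cd)
      sprintf("%s_%d", cd, seq_len(spec$n_reps)))),
    condition = rep(conditions, each = spec$n_reps),
    stringsAsFactors = FALSE)
  # expected count fractions: controls are uniform; on the bait side the
  # bait protein and the planted interactors hold fold-multiples of their
  # control fraction and the background absorbs the compensation, so the
  # planted enrichment is exactly `enrichment_fold` on the fraction scale
  rel_mass <- function(cond) {
    base <- setNames(rep(1 / length(ids), length(ids)), ids)
    bait_side <- cond %in% c("bait", "bait_msl2kd", "bait_rnase")
    if (!bait_side) return(base)
    pi <- base
    pi["BAIT"] <- base[["BAIT"]] * spec$bait_levels[[cond]]
    pi[planted] <- base[planted] * spec$enrichment_fold
    if (cond == "bait_msl2kd")
      pi[ms_sens] <- pi[ms_sens] * spec$treatment_folds[["msl2kd"]]
    if (cond == "bait_rnase")
      pi[rn_sens] <- pi[rn_sens] * spec$treatment_folds[["rnase"]]
    special <- c("BAIT", planted)
    bg <- setdiff(ids, special)
    spare <- 1 - sum(pi[special])
    if (spare <= 0) stop("planted mass exceeds 1; reduce folds or counts")
    pi[bg] <- spare / length(bg)
    pi
  }
  cnt <- with_seed(spec$seed + 3L, {
    sapply(seq_len(nrow(samples)), function(j) {
      pi <- rel_mass(samples$condition[j])
      p <- if (spec$theta < 1e-12) pi else {
        g <- rgamma(length(pi), shape = pi * (1 - spec$theta) / spec$theta)
        g / sum(g)
      }
      rmultinom(1, spec$totals, p)[, 1]
    })
  })
  dimnames(cnt) <- list(ids, samples$sample_id)
  ce <- count_experiment(cnt, samples = samples, bait_id = "BAIT",
                         corrected = cnt + 0.0)
  attr(ce, "truth") <- list(interactors = planted,
                            msl2kd_sensitive = ms_sens,
                            rnase_sensitive = rn_sens)
  ce
}

#' Generate query and reference interval sets on a toy genome
#'
#' Reference intervals are placed uniformly per chromosome (widths uniform
#' in `spec$interval_width`).  A planted fraction of query intervals are
#' copies of randomly chosen reference intervals jittered by a centred
#' normal of standard deviation `spec$jitter_sd`; the rest are uniform.
#'
#' @param spec a [simulation_spec].
#' @return list with `query` and `reference` `interval_set`s and `truth`
#'   (indices of planted query intervals).
#' @export
sim_intervals <- function(spec) {
  with_seed(spec$seed + 4L, {
    g <- spec$genome
    draw_uniform <- function(n) {
      chrom <- sample(names(g), n, replace = TRUE, prob = g / sum(g))
      w <- round(runif(n, spec$interval_width[1], spec$interval_width[2]))
      s <- floor(runif(n) * pmax(g[chrom] - w, 1))
      list(chrom = chrom, start = s, end = pmin(s + w, g[chrom]))
    }
    r <- draw_uniform(spec$n_intervals)
    reference <- interval_set(r$chrom, r$start, r$end, seqlengths = g)
    n_pl <- round(spec$planted_fraction * spec$n_intervals)
    q <- draw_uniform(spec$n_intervals - n_pl)
    if (n_pl > 0) {
      # without replacement: planted fraction 1 with zero jitter reproduces
      # the reference set exactly
      src <- sample(nrow(reference$intervals), n_pl)
      d <- reference$intervals[src, ]
      off <- round(rnorm(n_pl, 0, spec$jitter_sd))
      w <- d$end - d$start
      s <- pmin(pmax(d$start + off, 0), g[d$chrom] - w)
      q <- list(chrom = c(q$chrom, d$chrom), start = c(q$start, s),
                end = c(q$end, s + w))
    }
    query <- interval_set(q$chrom, q$start, q$end, seqlengths = g)
    list(query = query, reference = reference,
         truth = if (n_pl > 0) seq(spec$n_intervals - n_pl + 1,
                                   spec$n_intervals) else integer())
  })
}

#' Write every synthetic input to a directory
#'
#' Produces the standard-format files consumed by the pipeline (organism,
#' contaminant and concatenated FASTA; PSM TSV; corrected-count TSV with its
#' condition sidecar; query/reference BED; chromosome sizes TSV) plus a
#' hidden-truth sidecar `truth.json` that acceptance tests may read but
#' pipeline code must not.
#'
#' @param spec a [simulation_spec].
#' @param outdir output directory (created if needed).
#' @return the paths written, invisibly.
#' @export
synthgen_all <- function(spec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  dbs <- sim_database(spec)
  write_fasta(dbs$organism, p("organism.fasta"))
  write_fasta(dbs$contaminants, p("contaminants.fasta"))
  db <- build_decoy_database(dbs$organism, dbs$contaminants)
  write_fasta(db, p("db.fasta"))
  psms <- sim_psms(spec, db)
  write_psm_table(psms, p("psms.tsv"))
  counts <- sim_counts(spec)
  write_count_experiment(counts, p("counts.tsv"))
  iv <- sim_intervals(spec)
  write_bed(iv$query, p("query.bed"))
  write_bed(iv$reference, p("reference.bed"))
  write_chrom_sizes(spec$genome, p("sizes.tsv"))
  jsonlite::write_json(
    list(seed = spec$seed,
         psm_truth = attr(psms, "truth"),
         count_truth = attr(counts, "truth"),
         planted_query_rows = iv$truth),
    p("truth.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(vapply(c("organism.fasta", "contaminants.fasta", "db.fasta",
                     "psms.tsv", "counts.tsv", "query.bed", "reference.bed",
                     "sizes.tsv", "truth.json"), p, character(1)))
}
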