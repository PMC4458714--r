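round_half_up <- function(x) floor(x + 0.5)

#' Call confident bait interactors
#'
#' Per protein group, the corrected spectral counts of the bait
#' immunoprecipitation samples are compared with the pooled control samples
#' (empty-vector and GFP pull-downs treated as control replicates) by the
#' beta-binomial likelihood-ratio test, with per-sample trial totals taken as
#' the column sums of the (half-up rounded) corrected-count matrix.  Raw
#' p-values are Benjamini-Hochberg adjusted across all tested proteins; a
#' protein is a confident interactor when its q-value is below `fdr_cut`
#' and its enrichment direction is bait over control (documented flag for
#' the purely two-sided variant).
#'
#' @param experiment a [count_experiment] with corrected counts.
#' @param fdr_cut BH FDR cutoff (default 0.2).
#' @param bait_conditions condition label(s) of the test samples.
#' @param control_conditions condition label(s) pooled as controls.
#' @param two_sided_only if `TRUE`, drop the bait-over-control direction
#'   requirement.
#' @param seed RNG seed for the bootstrap reference of [bb_test()].
#' @param ... passed to [bb_test()] (e.g. `p_method`, `n_boot`).
#' @return data frame (one row per tested protein): `group_id`, `p_value`,
#'   `q_value`, `direction`, `confident`; proteins absent from every used
#'   sample are skipped and listed in the `"skipped"` attribute.
#' @export
call_interactors <- function(experiment, fdr_cut = 0.2,
                             bait_conditions = "bait",
                             control_conditions = c("control_empty", "control_gfp"),
                             two_sided_only = FALSE, seed = 1L, ...) {
  stopifnot(inherits(experiment, "count_experiment"),
            !is.null(experiment$corrected))
  cond <- experiment$samples$condition
  a_cols <- experiment$samples$sample_id[cond %in% bait_conditions]
  b_cols <- experiment$samples$sample_id[cond %in% control_conditions]
  if (length(a_cols) < 1L) stop("no bait samples in experiment")
  if (length(b_cols) < 2L) stop("fewer than 2 control samples in experiment")
  m <- round_half_up(experiment$corrected[, c(a_cols, b_cols), drop = FALSE])
  totals <- colSums(m)
  # samples with no counts at all carry no evidence; drop them
  a_cols <- a_cols[totals[a_cols] > 0]
  b_cols <- b_cols[totals[b_cols] > 0]
  if (length(a_cols) == 0L || length(b_cols) < 2L) {
    out <- data.frame(group_id = rownames(m), p_value = 1, q_value = 1,
                      direction = 0, confident = FALSE,
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- character()
    return(out)
  }
  m <- m[, c(a_cols, b_cols), drop = FALSE]
  present <- rowSums(m) > 0
  skipped <- rownames(m)[!present]
  tested <- rownames(m)[present]
  res <- with_seed(seed, lapply(tested, function(g) {
    bb_test(m[g, a_cols], totals[a_cols], m[g, b_cols], totals[b_cols], ...)
  }))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  dir <- vapply(res, `[[`, numeric(1), "direction")
  q <- bh_adjust(p)
  out <- data.frame(group_id = tested, p_value = p, q_value = q,
                    direction = dir,
                    confident = q < fdr_cut & (two_sided_only | dir > 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Bait-normalize a treatment condition
#'
#' Rescales a treatment condition's counts so the bait protein's mean count
#' matches the reference condition:
#' `factor = mean bait count (reference) / mean bait count (treatment)`,
#' and every protein's treatment counts are multiplied by it, after which
#' the bait rows agree in the mean.
#'
#' @param experiment a [count_experiment] with corrected counts and
#'   `bait_id` set.
#' @param condition the treatment condition label (e.g. `"bait_msl2kd"`,
#'   `"bait_rnase"`).
#' @param reference the reference condition label (default `"bait"`).
#' @return list with `counts` (the scaled treatment-sample submatrix, real
#'   valued) and `factor`.
#' @export
normalize_by_bait <- function(experiment, condition, reference = "bait") {
  stopifnot(inherits(experiment, "count_experiment"),
            !is.null(experiment$corrected))
  bait <- experiment$bait_id
  if (is.na(bait) || !bait %in% rownames(experiment$corrected))
    stop("bait protein not present in the experiment")
  ref_cols  <- experiment$samples$sample_id[experiment$samples$condition == reference]
  cond_cols <- experiment$samples$sample_id[experiment$samples$condition == condition]
  if (!length(ref_cols)) stop("no samples with condition '", reference, "'")
  if (!length(cond_cols)) stop("no samples with condition '", condition, "'")
  bait_ref  <- mean(experiment$corrected[bait, ref_cols])
  bait_cond <- mean(experiment$corrected[bait, cond_cols])
  if (bait_cond == 0)
    stop("bait protein has zero counts in condition '", condition,
         "'; cannot normalize")
  if (bait_ref == 0)
    stop("bait protein has zero counts in reference condition '", reference, "'")
  factor <- bait_ref / bait_cond
  list(counts = experiment$corrected[, cond_cols, drop = FALSE] * factor,
       factor = factor)
}

#' Classify treatment effects on confident interactors
#'
#' For each confident interactor, compares the untreated bait samples with
#' the bait-normalized treatment samples by the beta-binomial test at level
#' `alpha` and labels the protein `"Increase"` or `"Decrease"` by the
#' direction of the change, or `"none"` when not significant.  When
#' expression fold-changes are supplied (named vector, treatment over
#' reference), the treatment counts are divided by the protein's fold-change
#' before testing, so an apparent change exactly matching a transcriptional
#' change cancels; proteins with no ratio available are left uncorrected and
#' listed in the `"uncorrected"` attribute.
#'
#' @param experiment a [count_experiment] with corrected counts.
#' @param treatment treatment condition label.
#' @param interactors result of [call_interactors()]; only rows with
#'   `confident = TRUE` are classified (pass a custom frame to test others).
#' @param alpha significance level (default 0.05).
#' @param expression_ratios optional named numeric vector of expression
#'   fold-changes (treatment / reference).
#' @param reference reference condition label (default `"bait"`).
#' @param seed RNG seed for the bootstrap reference of [bb_test()].
#' @param ... passed to [bb_test()].
#' @return data frame: `group_id`, `effect` (`"Increase"`, `"Decrease"`,
#'   `"none"`), `p_value`.
#' @export
classify_treatment <- function(experiment, treatment, interactors,
                               alpha = 0.05, expression_ratios = NULL,
                               reference = "bait", seed = 1L, ...) {
  stopifnot(inherits(experiment, "count_experiment"))
  ids <- interactors$group_id[interactors$confident]
  norm <- normalize_by_bait(experiment, treatment, reference)
  treat <- norm$counts
  uncorrected <- character()
  if (!is.null(expression_ratios)) {
    for (g in intersect(ids, rownames(treat))) {
      r <- unname(expression_ratios[g])
      if (length(r) != 1L || is.na(r)) {
        uncorrected <- c(uncorrected, g)
      } else {
        treat[g, ] <- treat[g, ] / r
      }
    }
    uncorrected <- union(uncorrected, setdiff(ids, names(expression_ratios)))
  }
  ref_cols <- experiment$samples$sample_id[experiment$samples$condition == reference]
  ref <- round_half_up(experiment$corrected[, ref_cols, drop = FALSE])
  treat <- round_half_up(treat)
  totals_ref <- colSums(ref)
  totals_trt <- colSums(treat)
  res <- with_seed(seed, lapply(ids, function(g) {
    t <- bb_test(treat[g, ], totals_trt, ref[g, ], totals_ref, ...)
    effect <- "none"
    if (t$p_value < alpha && t$direction > 0) effect <- "Increase"
    if (t$p_value < alpha && t$direction < 0) effect <- "Decrease"
    data.frame(group_id = g, effect = effect, p_value = t$p_value,
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, c(list(data.frame()), res))
  rownames(out) <- NULL
  attr(out, "uncorrected") <- intersect(unique(uncorrected), ids)
  out
}

#' Packaged annotation of bait interactors with nucleic-acid-metabolism roles
#'
#' Returns the packaged fixture table of the 51 mass-spectrometry-identified
#' MLE helicase interactors with a clear function in nucleic acid metabolism,
#' as curated in the source AP-MS study: protein description, biological
#' process, and the observed effect of MSL2 knockdown and of RNase treatment
#' on the interaction (`"Decrease"`, `"Increase"`, or blank for no
#' significant effect).
#'
#' @return data frame with 51 rows and columns `protein_description`,
#'   `biological_process`, `msl2kd_effect`, `rnase_effect`.
#' @export
interactor_annotations <- function() {
  path <- system.file("extdata", "mle_interactors_nucleic_acid.tsv",
                      package = "apmsflow", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                   check.names = FALSE)
  bad_m <- !df$msl2kd_effect %in% c("Decrease", "Increase", "")
  bad_r <- !df$rnase_effect %in% c("Decrease", "Increase", "")
  if (any(bad_m) || any(bad_r)) stop("fixture vocabulary violation")
  df
}

#' Read an expression-ratio table
#'
#' Two-column TSV (gene id, fold-change) used for optional expression
#' correction of treatment counts.
#'
#' @param path file path.
#' @return named numeric vector of fold-changes.
#' @export
read_expression_ratios <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), df[[1]])
}
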