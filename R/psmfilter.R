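#' Configuration for peptide-spectrum match filtering
#'
#' Collects the tunables of the target-decoy filter: the requested peptide
#' false discovery rate, spectrum-quality prefilter thresholds, the linear
#' discriminant weights, and histogram/threshold mechanics.
#'
#' The default discriminant combines three transformed SEQUEST-style scores:
#' the log of the primary match score normalized by peptide length
#' (`lenlog_primary`, weight 1.0), the delta score to the runner-up taken
#' as-is (`delta`, weight 8.0) and the negated log of the rank-based score
#' (`neglog_rank`, weight 0.2), with zero bias.  The published coefficients
#' of the original in-house pipeline are not available; these documented
#' defaults are recorded in every filter report so runs are reproducible, and
#' nothing downstream depends on their specific values.
#'
#' @param target_fdr requested peptide FDR in (0,1) (default 0.01).
#' @param histogram_bin_width discriminant-score bin width (default 0.1);
#'   thresholds snap to bin edges.
#' @param discriminant_weights named numeric vector of weights for the
#'   transformed features.
#' @param discriminant_bias additive bias (default 0).
#' @param min_ions minimum fragment-ion count (default 25, inclusive).
#' @param min_intensity minimum absolute precursor intensity (default 500,
#'   exclusive: intensity must exceed it).
#' @param mass_range inclusive MH+ window in Da (default `c(550, 4000)`).
#' @param min_class_decoys classes with fewer decoys fall back to the pooled
#'   all-class histogram (default 50).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(target_fdr = 0.01,
                          histogram_bin_width = 0.1,
                          discriminant_weights = c(lenlog_primary = 1.0,
                                                   delta = 8.0,
                                                   neglog_rank = 0.2),
                          discriminant_bias = 0,
                          min_ions = 25L,
                          min_intensity = 500,
                          mass_range = c(550, 4000),
                          min_class_decoys = 50L) {
  stopifnot(target_fdr > 0, target_fdr < 1,
            histogram_bin_width > 0,
            length(mass_range) == 2L, mass_range[1] < mass_range[2])
  structure(list(target_fdr = target_fdr,
                 histogram_bin_width = histogram_bin_width,
                 discriminant_weights = discriminant_weights,
                 discriminant_bias = discriminant_bias,
                 min_ions = min_ions,
                 min_intensity = min_intensity,
                 mass_range = mass_range,
                 min_class_decoys = min_class_decoys),
            class = "filter_config")
}

psm_required_cols <- c("spectrum_id", "peptide", "charge", "ntt", "mod_state")

check_psm_table <- function(psms, cols = psm_required_cols) {
  missing <- setdiff(cols, names(psms))
  if (length(missing))
    stop("PSM table is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(psms)
}

#' Class key of a peptide-spectrum match
#'
#' PSMs are partitioned by charge state (1+, 2+, 3+), number of tryptic
#' termini (0, 1, 2) and modification state (unmodified or M+16), giving at
#' most 18 classes; score thresholds are set per class.
#'
#' @param psms a PSM data frame.
#' @return character vector of class keys, e.g. `"2+/ntt2/unmod"`.
#' @export
psm_class <- function(psms) {
  check_psm_table(psms)
  sprintf("%d+/ntt%d/%s", as.integer(psms$charge), as.integer(psms$ntt),
          as.character(psms$mod_state))
}

#' Spectrum-quality prefilter
#'
#' Removes PSMs whose spectra fail the acquisition-quality gates: a minimum
#' fragment-ion count (inclusive), a minimum absolute intensity (exclusive)
#' and an inclusive MH+ mass window.  Relative record order is preserved.
#'
#' @param psms PSM data frame with numeric columns `n_ions`, `intensity`,
#'   `mhplus`.
#' @param cfg a [filter_config].
#' @return the surviving rows of `psms`.
#' @export
prefilter_spectra <- function(psms, cfg = filter_config()) {
  check_psm_table(psms, c(psm_required_cols, "n_ions", "intensity", "mhplus"))
  keep <- psms$n_ions >= cfg$min_ions &
    psms$intensity > cfg$min_intensity &
    psms$mhplus >= cfg$mass_range[1] & psms$mhplus <= cfg$mass_range[2]
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Linear discriminant score
#'
#' `discriminant_combine()` is the bare linear form: the inner product of a
#' feature matrix with a weight vector plus a bias.  `compute_discriminant()`
#' derives the transformed features from a PSM table's raw search scores --
#' `lenlog_primary = log(primary_score / nchar(peptide))`, `delta =
#' delta_score`, `neglog_rank = -log(rank_score)` -- and fills the
#' `discriminant` column.
#'
#' @param features numeric matrix (rows = records) or vector whose columns
#'   are named like `weights`.
#' @param weights named numeric weight vector.
#' @param bias additive constant (default 0).
#' @return `discriminant_combine()`: numeric vector of scores.
#' @export
discriminant_combine <- function(features, weights, bias = 0) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  missing <- setdiff(names(weights), colnames(features))
  if (length(missing))
    stop("missing discriminant feature(s): ", paste(missing, collapse = ", "))
  drop(features[, names(weights), drop = FALSE] %*% weights) + bias
}

#' @rdname discriminant_combine
#' @param psms PSM data frame with numeric columns `primary_score`,
#'   `delta_score`, `rank_score` (all positive where logged).
#' @param cfg a [filter_config] supplying weights and bias.
#' @return `compute_discriminant()`: `psms` with a filled `discriminant`
#'   column.
#' @export
compute_discriminant <- function(psms, cfg = filter_config()) {
  need <- c("primary_score", "delta_score", "rank_score")
  check_psm_table(psms, c(psm_required_cols, need))
  features <- cbind(
    lenlog_primary = log(psms$primary_score) - log(nchar(psms$peptide)),
    delta = psms$delta_score,
    neglog_rank = -log(psms$rank_score)
  )
  psms$discriminant <- discriminant_combine(features,
                                            cfg$discriminant_weights,
                                            cfg$discriminant_bias)
  psms
}

#' Score histogram on a fixed bin grid
#'
#' @param scores numeric vector.
#' @param breaks strictly increasing numeric vector of bin edges; scores fall
#'   in `[breaks[i], breaks[i+1])`.
#' @return list of class `score_histogram` with elements `breaks` and
#'   `counts` (length `length(breaks) - 1`).
#' @export
score_histogram <- function(scores, breaks) {
  stopifnot(length(breaks) >= 2L, !is.unsorted(breaks, strictly = TRUE))
  idx <- findInterval(scores, breaks, rightmost.closed = FALSE)
  idx <- idx[idx >= 1L & idx <= length(breaks) - 1L]
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, counts = counts), class = "score_histogram")
}

common_breaks <- function(scores, bin_width) {
  lo <- floor(min(scores) / bin_width) * bin_width
  hi <- ceiling(max(scores) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  seq(lo, hi + bin_width / 2, by = bin_width)
}

#' Per-class target and decoy score histograms
#'
#' Splits scored PSMs into their charge/ntt/modification classes and builds a
#' pair of discriminant-score histograms (matches to forward sequences,
#' matches to reversed sequences) per occupied class, all on one common bin
#' grid.
#'
#' @param psms scored PSM data frame (`discriminant` filled, `is_decoy`
#'   logical).
#' @param bin_width histogram bin width.
#' @return named list (one element per occupied class) of lists with
#'   `target` and `decoy` [score_histogram]s; the shared `breaks` are
#'   attached as an attribute.
#' @export
class_histograms <- function(psms, bin_width = 0.1) {
  check_psm_table(psms, c(psm_required_cols, "discriminant", "is_decoy"))
  if (nrow(psms) == 0L)
    return(structure(list(), breaks = numeric()))
  breaks <- common_breaks(psms$discriminant, bin_width)
  cls <- psm_class(psms)
  out <- lapply(split(seq_len(nrow(psms)), cls), function(i) {
    list(target = score_histogram(psms$discriminant[i][!psms$is_decoy[i]], breaks),
         decoy  = score_histogram(psms$discriminant[i][psms$is_decoy[i]], breaks))
  })
  attr(out, "breaks") <- breaks
  out
}

#' Target-decoy FDR threshold for one score-histogram pair
#'
#' Scans the bin edges of target-occupied bins from the bottom and returns
#' the smallest edge `t` at which the estimated FDR
#' `decoys >= t / targets >= t` drops to at or below `target_fdr` (candidate
#' cut points are the observed target scores, snapped to their bin edges).
#' When no candidate qualifies the class rejects all records
#' (`threshold = Inf`, `kept_targets = 0`).  When no targets remain at an
#' edge the FDR is taken as 0 if no decoys remain either, else 1.
#'
#' @param target_hist,decoy_hist [score_histogram]s on a common grid.
#' @param target_fdr requested FDR.
#' @return list with `threshold`, `kept_targets`, `est_fdr`.
#' @export
fdr_threshold <- function(target_hist, decoy_hist, target_fdr = 0.01) {
  stopifnot(identical(target_hist$breaks, decoy_hist$breaks))
  tc <- rev(cumsum(rev(target_hist$counts)))   # targets >= left edge of bin i
  dc <- rev(cumsum(rev(decoy_hist$counts)))
  fdr <- ifelse(tc == 0, ifelse(dc == 0, 0, 1), dc / tc)
  ok <- which(fdr <= target_fdr & target_hist$counts > 0)
  if (length(ok) == 0L)
    return(list(threshold = Inf, kept_targets = 0L, est_fdr = NA_real_))
  i <- ok[1]
  list(threshold = target_hist$breaks[i],
       kept_targets = as.integer(tc[i]),
       est_fdr = fdr[i])
}

#' Filter peptide-spectrum matches at a requested peptide FDR
#'
#' The full class-specific target-decoy filter: computes the discriminant
#' score if absent, histograms targets and decoys per charge/ntt/modification
#' class on a common grid, sets each class's score threshold at the requested
#' FDR from its decoy histogram, and removes all records (target and decoy)
#' below their class threshold.  Classes with fewer than
#' `cfg$min_class_decoys` decoy matches fall back to the pooled all-class
#' histogram pair.  Records in classes absent from the report (none, by
#' construction) or below threshold are dropped; survivors keep their input
#' order.  Filtering is idempotent.
#'
#' @param psms PSM data frame; `is_decoy` may be absent, in which case it is
#'   derived from `accessions` (a record is decoy iff every accession carries
#'   `decoy_prefix`; ambiguous records count as target).
#' @param cfg a [filter_config].
#' @param prefilter apply [prefilter_spectra()] first (`"auto"` applies it
#'   only when the quality columns are present).
#' @param decoy_prefix accession prefix identifying decoys.
#' @return list with `confident` (surviving PSMs) and `report` (one row per
#'   class: counts, pooled-fallback flag, threshold, kept targets, estimated
#'   FDR); the discriminant weights used are attached as attribute
#'   `"weights"` of the report.
#' @export
filter_psms <- function(psms, cfg = filter_config(),
                        prefilter = c("auto", "yes", "no"),
                        decoy_prefix = "REV_") {
  prefilter <- match.arg(prefilter)
  check_psm_table(psms)
  if (!"is_decoy" %in% names(psms))
    psms$is_decoy <- psm_is_decoy(psms$accessions, decoy_prefix)
  report0 <- data.frame(class = character(), n_targets = integer(),
                        n_decoys = integer(), pooled = logical(),
                        threshold = numeric(), kept_targets = integer(),
                        est_fdr = numeric(), stringsAsFactors = FALSE)
  if (nrow(psms) == 0L) {
    attr(report0, "weights") <- cfg$discriminant_weights
    return(list(confident = psms, report = report0))
  }
  if (prefilter == "yes" ||
      (prefilter == "auto" &&
       all(c("n_ions", "intensity", "mhplus") %in% names(psms))))
    psms <- prefilter_spectra(psms, cfg)
  if (!"discriminant" %in% names(psms) || anyNA(psms$discriminant))
    psms <- compute_discriminant(psms, cfg)
  hists <- class_histograms(psms, cfg$histogram_bin_width)
  breaks <- attr(hists, "breaks")
  pooled <- list(
    target = score_histogram(psms$discriminant[!psms$is_decoy], breaks),
    decoy  = score_histogram(psms$discriminant[psms$is_decoy], breaks)
  )
  pooled_thr <- fdr_threshold(pooled$target, pooled$decoy, cfg$target_fdr)
  rows <- lapply(names(hists), function(cl) {
    h <- hists[[cl]]
    nd <- sum(h$decoy$counts)
    use_pooled <- nd < cfg$min_class_decoys
    thr <- if (use_pooled) pooled_thr
           else fdr_threshold(h$target, h$decoy, cfg$target_fdr)
    data.frame(class = cl, n_targets = sum(h$target$counts),
               n_decoys = nd, pooled = use_pooled,
               threshold = thr$threshold,
               kept_targets = if (use_pooled)
                 sum(h$target$counts[h$target$breaks[-length(breaks)] >= thr$threshold])
               else thr$kept_targets,
               est_fdr = thr$est_fdr, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, c(list(report0), rows))
  thr_by_class <- setNames(report$threshold, report$class)
  keep <- psms$discriminant >= thr_by_class[psm_class(psms)]
  confident <- psms[keep, , drop = FALSE]
  rownames(confident) <- NULL
  attr(report, "weights") <- cfg$discriminant_weights
  list(confident = confident, report = report)
}

#' Decoy status from accession lists
#'
#' A PSM is a decoy match iff every accession it maps to carries the decoy
#' prefix; a record mapping to both target and decoy sequences resolves to
#' target (conservative).
#'
#' @param accessions character vector of semicolon-joined accession lists.
#' @param prefix decoy accession prefix.
#' @return logical vector.
#' @export
psm_is_decoy <- function(accessions, prefix = "REV_") {
  vapply(strsplit(as.character(accessions), ";", fixed = TRUE),
         function(a) length(a) > 0L && all(startsWith(a, prefix)),
         logical(1))
}

#' Read / write a PSM table
#'
#' Tab-separated with a header; one row per MS2 spectrum identification.
#' Required columns: `spectrum_id`, `peptide`, `charge`, `ntt`, `mod_state`;
#' score and quality columns as produced by the search; `accessions`
#' semicolon-joined; `is_decoy` optional (derived from the accession prefix
#' when absent).
#'
#' @param path file path.
#' @param psms PSM data frame.
#' @param decoy_prefix prefix used to derive `is_decoy` when absent.
#' @return `read_psm_table()`: a data frame.
#' @export
read_psm_table <- function(path, decoy_prefix = "REV_") {
  psms <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_psm_table(psms)
  if (!"is_decoy" %in% names(psms))
    psms$is_decoy <- psm_is_decoy(psms$accessions, decoy_prefix)
  psms
}

#' @rdname read_psm_table
#' @export
write_psm_table <- function(psms, path) {
  write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
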