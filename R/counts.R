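#' Spectral-count experiments
#'
#' A `count_experiment` bundles a protein-group by sample matrix of unique
#' spectral counts, a registry of shared-peptide counts awaiting proportional
#' splitting, the corrected-count matrix once split, sample condition labels
#' and the bait accession.
#'
#' @param unique_counts integer matrix (groups x samples).
#' @param shared named list: one entry per shared peptide, each a list with
#'   `owners` (group ids) and `counts` (named per-sample counts).
#' @param samples data frame with columns `sample_id` and `condition`
#'   (levels used downstream: `bait`, `control_empty`, `control_gfp`,
#'   `bait_msl2kd`, `bait_rnase`).
#' @param bait_id group id of the bait protein (or `NA`).
#' @param corrected optional corrected-count matrix.
#' @param distinct_unique optional matrix of per-sample distinct unique
#'   peptide counts (used by the `"distinct"` splitting variant).
#' @return an object of class `count_experiment`.
#' @export
count_experiment <- function(unique_counts, shared = list(),
                             samples = NULL, bait_id = NA_character_,
                             corrected = NULL, distinct_unique = NULL) {
  stopifnot(is.matrix(unique_counts))
  if (is.null(samples))
    samples <- data.frame(sample_id = colnames(unique_counts),
                          condition = "bait", stringsAsFactors = FALSE)
  stopifnot(identical(colnames(unique_counts), samples$sample_id))
  structure(list(unique = unique_counts, shared = shared,
                 corrected = corrected, distinct_unique = distinct_unique,
                 samples = samples, bait_id = bait_id),
            class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat(sprintf("<count_experiment> %d protein groups x %d samples (%d shared peptides%s)\n",
              nrow(x$unique), ncol(x$unique), length(x$shared),
              if (is.null(x$corrected)) ", not yet split" else ", split"))
  print(table(x$samples$condition))
  invisible(x)
}

#' Tally unique and shared spectral counts
#'
#' Assigns each confident spectrum to the surviving protein group(s) owning
#' its peptide.  Spectra whose peptide belongs to exactly one group increment
#' that group's unique count in the spectrum's sample; spectra of peptides
#' shared between groups are recorded in the shared registry for later
#' proportional splitting.  By the parsimony guarantee every confident
#' peptide of a removed subset group is still covered by a surviving
#' superset group, so nothing is lost.
#'
#' @param confident_psms filtered PSM data frame (columns `peptide`,
#'   `sample_id`; missing `sample_id` treated as `"S1"`).
#' @param groups surviving `protein_groups`.
#' @param samples optional data frame (`sample_id`, `condition`); defaults to
#'   the samples seen in the PSMs, condition `"bait"`.
#' @param bait_id optional bait group id.
#' @return a [count_experiment] with unique counts and the shared registry
#'   filled (corrected counts not yet computed).  Spectra whose peptide is
#'   owned by no surviving group are dropped with a warning.
#' @export
tally_counts <- function(confident_psms, groups, samples = NULL,
                         bait_id = NA_character_) {
  stopifnot(inherits(groups, "protein_groups"))
  check_psm_table(confident_psms, "peptide")
  if (!"sample_id" %in% names(confident_psms))
    confident_psms$sample_id <- "S1"
  gid <- vapply(groups, `[[`, character(1), "group_id")
  pep_owner <- split(
    rep(gid, vapply(groups, function(g) length(g$peptides), integer(1))),
    unlist(lapply(groups, `[[`, "peptides"), use.names = FALSE)
  )
  if (is.null(samples))
    samples <- data.frame(sample_id = sort(unique(confident_psms$sample_id)),
                          condition = "bait", stringsAsFactors = FALSE)
  sid <- samples$sample_id
  owned <- confident_psms$peptide %in% names(pep_owner)
  if (!all(owned)) {
    warning(sum(!owned), " spectra of peptides owned by no surviving group ",
            "were dropped")
    confident_psms <- confident_psms[owned, , drop = FALSE]
  }
  uc <- matrix(0L, nrow = length(gid), ncol = length(sid),
               dimnames = list(gid, sid))
  du <- uc
  shared <- list()
  tab <- table(confident_psms$peptide, factor(confident_psms$sample_id, levels = sid))
  for (p in rownames(tab)) {
    owners <- pep_owner[[p]]
    cnt <- as.integer(tab[p, ])
    names(cnt) <- sid
    if (length(owners) == 1L) {
      uc[owners, ] <- uc[owners, ] + cnt
      du[owners, ] <- du[owners, ] + as.integer(cnt > 0L)
    } else {
      shared[[p]] <- list(owners = owners, counts = cnt)
    }
  }
  count_experiment(uc, shared, samples, bait_id, distinct_unique = du)
}

#' Split shared-peptide counts proportionally to unique evidence
#'
#' For each shared peptide with per-sample count `c` owned by groups `S`,
#' group `g` receives `c * u_g / sum(u_h, h in S)` added to its corrected
#' count in that sample, where `u_g` is `g`'s unique evidence in that sample:
#' its unique spectral count (default) or its distinct unique-peptide count
#' (`method = "distinct"`, a sensitivity-analysis variant).  When every
#' owner's unique evidence is zero the count is split equally (logged in the
#' experiment's `equal_split` field).  Splitting is per sample, with that sample's
#' unique evidence.  Per sample, total corrected mass equals total unique
#' plus total shared mass (conservation); corrected counts are kept as reals.
#'
#' @param experiment a [count_experiment] from [tally_counts()].
#' @param method weight shared counts by unique spectral counts
#'   (`"spectral"`, default) or distinct unique-peptide counts
#'   (`"distinct"`).
#' @return the experiment with `corrected` filled.
#' @export
split_shared <- function(experiment, method = c("spectral", "distinct")) {
  method <- match.arg(method)
  stopifnot(inherits(experiment, "count_experiment"))
  w_mat <- if (method == "spectral") experiment$unique
           else experiment$distinct_unique
  corrected <- experiment$unique + 0.0
  equal_split <- character()
  for (p in names(experiment$shared)) {
    entry <- experiment$shared[[p]]
    for (s in colnames(corrected)) {
      c_ps <- entry$counts[[s]]
      if (c_ps == 0) next
      u <- w_mat[entry$owners, s]
      if (sum(u) == 0) {
        share <- rep(c_ps / length(u), length(u))
        equal_split <- c(equal_split, paste0(p, "@", s))
      } else {
        share <- c_ps * u / sum(u)
      }
      corrected[entry$owners, s] <- corrected[entry$owners, s] + share
    }
  }
  experiment$corrected <- corrected
  experiment$equal_split <- unique(equal_split)
  experiment
}

#' Read / write a corrected-count matrix with its condition sidecar
#'
#' The matrix is a TSV with protein-group rows and sample columns; sample
#' condition labels and the bait accession travel in a JSON sidecar.
#'
#' @param experiment a [count_experiment] with corrected counts.
#' @param path TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `read_count_experiment()`: a [count_experiment] (unique counts set
#'   to the rounded corrected counts when only corrected values were stored).
#' @export
write_count_experiment <- function(experiment, path) {
  m <- if (is.null(experiment$corrected)) experiment$unique else experiment$corrected
  df <- data.frame(group_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(samples = experiment$samples, bait_id = experiment$bait_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_count_experiment
#' @export
read_count_experiment <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$group_id
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  samples <- as.data.frame(side$samples, stringsAsFactors = FALSE)
  m <- m[, samples$sample_id, drop = FALSE]
  count_experiment(round(m), samples = samples,
                   bait_id = if (is.null(side$bait_id)) NA_character_ else side$bait_id,
                   corrected = m)
}
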