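#' Map confident peptides to proteins and group by identical peptide sets
#'
#' Every confident peptide is located (as an exact substring, I and L
#' distinct by default) in the search database; proteins identified by
#' identical sets of peptides are grouped together as redundant members of
#' one protein group.  A group is a decoy group iff all of its members are
#' decoy entries -- a group mixing target and decoy members resolves to
#' target (conservative).  Peptides matching no database sequence are
#' excluded with a warning and listed in the `"unmapped"` attribute.
#'
#' @param confident_psms filtered PSM data frame (columns `peptide`, `ntt`,
#'   and `sample_id`; a missing `sample_id` is treated as one sample `"S1"`).
#' @param database a [sequence_db] (typically the concatenated target+decoy
#'   database).
#' @param distinct_il treat I and L as distinct residues (default `TRUE`);
#'   when `FALSE` both sides are mapped through I -> L first.
#' @return an object of class `protein_groups`: a list of groups, each a
#'   list with `group_id`, `accessions`, `peptides`, `is_decoy` and
#'   `evidence` (data frame `sample_id`, `peptide`, `ntt` = max observed ntt).
#' @export
map_and_group <- function(confident_psms, database, distinct_il = TRUE) {
  check_psm_table(confident_psms, c("peptide", "ntt"))
  if (!"sample_id" %in% names(confident_psms))
    confident_psms$sample_id <- "S1"
  peptides <- unique(confident_psms$peptide)
  seqs <- database$sequence
  map_pep <- function(p) database$accession[grepl(p, seqs, fixed = TRUE)]
  if (!distinct_il) {
    seqs <- chartr("I", "L", seqs)
    map_pep <- function(p) database$accession[grepl(chartr("I", "L", p),
                                                    seqs, fixed = TRUE)]
  }
  hits <- lapply(peptides, map_pep)
  names(hits) <- peptides
  unmapped <- peptides[lengths(hits) == 0L]
  if (length(unmapped)) {
    warning(length(unmapped), " confident peptide(s) matched no database ",
            "sequence and were excluded")
    hits <- hits[lengths(hits) > 0L]
  }
  # invert: protein -> peptide set
  prot2pep <- split(rep(names(hits), lengths(hits)), unlist(hits, use.names = FALSE))
  prot2pep <- lapply(prot2pep, function(p) sort(unique(p)))
  keys <- vapply(prot2pep, paste, character(1), collapse = "\r")
  decoy_of <- setNames(database$is_decoy, database$accession)
  groups <- lapply(split(names(prot2pep), keys), function(acc) {
    acc <- sort(acc)
    peps <- prot2pep[[acc[1]]]
    ev <- confident_psms[confident_psms$peptide %in% peps, c("sample_id", "peptide", "ntt")]
    ev <- stats::aggregate(ntt ~ sample_id + peptide, data = ev, FUN = max)
    list(group_id = acc[1],
         accessions = acc,
         peptides = peps,
         is_decoy = all(decoy_of[acc]),
         evidence = ev[order(ev$sample_id, ev$peptide), , drop = FALSE])
  })
  groups <- unname(groups[order(vapply(groups, `[[`, character(1), "group_id"))])
  structure(groups, class = "protein_groups", unmapped = unmapped)
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("<protein_groups> %d groups (%d decoy)\n",
              length(x), sum(vapply(x, `[[`, logical(1), "is_decoy"))))
  invisible(x)
}

#' @export
as.data.frame.protein_groups <- function(x, ...) {
  data.frame(
    group_id = vapply(x, `[[`, character(1), "group_id"),
    accessions = vapply(x, function(g) paste(g$accessions, collapse = ";"),
                        character(1)),
    n_peptides = vapply(x, function(g) length(g$peptides), integer(1)),
    is_decoy = vapply(x, `[[`, logical(1), "is_decoy"),
    stringsAsFactors = FALSE
  )
}

#' Parsimonious removal of subset protein groups
#'
#' A group whose peptide set is a proper subset of another group's peptide
#' set is removed; its peptides remain covered by the superset group.  The
#' result does not depend on input order.
#'
#' @param groups a `protein_groups` object.
#' @return the surviving `protein_groups`.
#' @export
apply_parsimony <- function(groups) {
  stopifnot(inherits(groups, "protein_groups"))
  n <- length(groups)
  if (n <= 1L) return(groups)
  sets <- lapply(groups, `[[`, "peptides")
  sizes <- lengths(sets)
  remove <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      # proper subset: strictly smaller and contained (identical sets were
      # merged at grouping time, so equality cannot occur)
      if (sizes[i] < sizes[j] && all(sets[[i]] %in% sets[[j]])) {
        remove[i] <- TRUE
        break
      }
    }
  }
  out <- groups[!remove]
  structure(out, class = "protein_groups", unmapped = attr(groups, "unmapped"))
}

#' Two-peptide rule
#'
#' A group survives iff in at least one sample it is identified by at least
#' two distinct peptides each having at least one tryptic terminus.  (The
#' alternative reading -- requiring this in every sample -- would erase
#' proteins absent from a control lane and contradict the differential
#' design; the chosen reading is flagged in the attached report attribute.)
#'
#' @param groups a `protein_groups` object.
#' @return the surviving `protein_groups`; attribute `"rule"` documents the
#'   per-sample interpretation.
#' @export
two_peptide_filter <- function(groups) {
  stopifnot(inherits(groups, "protein_groups"))
  keep <- vapply(groups, function(g) {
    ev <- g$evidence[g$evidence$ntt >= 1L, , drop = FALSE]
    if (nrow(ev) == 0L) return(FALSE)
    any(vapply(split(ev$peptide, ev$sample_id),
               function(p) length(unique(p)) >= 2L, logical(1)))
  }, logical(1))
  structure(groups[keep], class = "protein_groups",
            unmapped = attr(groups, "unmapped"),
            rule = ">=2 distinct peptides with ntt>=1 in >=1 sample")
}

#' Protein-level FDR from decoy groups
#'
#' Estimated as the number of surviving decoy groups divided by the number of
#' surviving target groups.
#'
#' @param groups a `protein_groups` object (post-filtering).
#' @return a fraction; `NA` (with a warning) when no target group survives.
#' @export
protein_fdr <- function(groups) {
  stopifnot(inherits(groups, "protein_groups"))
  dec <- vapply(groups, `[[`, logical(1), "is_decoy")
  n_target <- sum(!dec)
  if (n_target == 0L) {
    warning("no target groups; protein FDR undefined")
    return(NA_real_)
  }
  sum(dec) / n_target
}

#' Protein-group report table
#'
#' @param groups a `protein_groups` object.
#' @return data frame: group id, member accessions, number of distinct
#'   peptides, per-sample distinct-peptide counts (one column per sample),
#'   decoy flag.
#' @export
protein_group_table <- function(groups) {
  df <- as.data.frame(groups)
  samples <- sort(unique(unlist(lapply(groups, function(g) g$evidence$sample_id))))
  for (s in samples)
    df[[paste0("n_peptides.", s)]] <- vapply(groups, function(g)
      length(unique(g$evidence$peptide[g$evidence$sample_id == s])), integer(1))
  df
}
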