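#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after lysine (K) or arginine (R), by default not
#' when the next residue is proline (the classic SEQUEST-era rule), and
#' returns all peptides with up to `missed_cleavages` internal missed
#' cleavage sites.  Protein termini count as tryptic, so every peptide
#' produced by a full digest is fully tryptic (ntt = 2); the per-terminus
#' flags are still reported because downstream peptide-spectrum matches may
#' carry semi-tryptic evidence.
#'
#' @param sequence a single amino-acid string.
#' @param missed_cleavages maximum number of internal missed cleavage sites
#'   (default 2).
#' @param proline_rule if `TRUE` (default), do not cleave K/R-P bonds.
#' @param on_nonstandard `"reject"` (default) errors on residues outside the
#'   IUPAC amino-acid alphabet; `"skip"` silently drops peptides containing
#'   them.
#' @return a data frame with columns `peptide`, `start`, `end` (1-based,
#'   inclusive), `n_missed`, `nterm_tryptic`, `cterm_tryptic`, `ntt`.
#' @examples
#' digest_tryptic("AKRB", missed_cleavages = 0)$peptide  # "AK" "R" "B"
#' digest_tryptic("AKPA", missed_cleavages = 0)$peptide  # "AKPA"
#' @export
digest_tryptic <- function(sequence, missed_cleavages = 2L,
                           proline_rule = TRUE,
                           on_nonstandard = c("reject", "skip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  valid <- ch %in% strsplit("ACDEFGHIKLMNPQRSTVWYBJZXUO", "")[[1]]
  if (!all(valid) && on_nonstandard == "reject")
    stop("non-standard residue(s) in sequence: ",
         paste(unique(ch[!valid]), collapse = ", "))
  n <- length(ch)
  # cleavage points: position i means a cut after residue i
  cut_after <- which(ch %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (proline_rule && length(cut_after))
    cut_after <- cut_after[ch[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)            # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  rows <- vector("list", 0L)
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + missed_cleavages)) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- c(s, e, j - i)
    }
  }
  m <- do.call(rbind, rows)
  pep <- substring(sequence, m[, 1], m[, 2])
  keep <- rep(TRUE, length(pep))
  if (!all(valid) && on_nonstandard == "skip") {
    badpos <- which(!valid)
    keep <- !vapply(seq_along(pep),
                    function(k) any(badpos >= m[k, 1] & badpos <= m[k, 2]),
                    logical(1))
  }
  out <- data.frame(
    peptide = pep, start = m[, 1], end = m[, 2], n_missed = m[, 3],
    nterm_tryptic = TRUE, cterm_tryptic = TRUE, ntt = 2L,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
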