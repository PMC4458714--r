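#' Protein sequence databases with target/decoy provenance
#'
#' A `sequence_db` is a data frame with one row per protein entry and columns
#' `accession` (unique identifier), `sequence` (amino-acid string),
#' `origin` (`"organism"` or `"contaminant"`) and `is_decoy` (logical).
#' Decoy entries carry a reserved accession prefix and hold the
#' character-reversal of a forward entry's sequence.
#'
#' @param accession character vector of unique accessions.
#' @param sequence character vector of amino-acid sequences (non-empty).
#' @param origin `"organism"` or `"contaminant"`, recycled.
#' @param is_decoy logical, recycled (default `FALSE`).
#' @param description optional character vector of FASTA descriptions.
#' @return an object of class `sequence_db` (a data frame).
#' @export
sequence_db <- function(accession, sequence, origin = "organism",
                        is_decoy = FALSE, description = NA_character_) {
  accession <- as.character(accession)
  sequence  <- toupper(as.character(sequence))
  n <- length(accession)
  stopifnot(length(sequence) == n)
  db <- data.frame(
    accession   = accession,
    sequence    = sequence,
    origin      = rep_len(as.character(origin), n),
    is_decoy    = rep_len(as.logical(is_decoy), n),
    description = rep_len(as.character(description), n),
    stringsAsFactors = FALSE
  )
  validate_sequence_db(db)
  class(db) <- c("sequence_db", "data.frame")
  db
}

validate_sequence_db <- function(db) {
  if (nrow(db) == 0L) return(invisible(db))
  dup <- db$accession[duplicated(db$accession)]
  if (length(dup))
    stop("duplicate accession(s): ", paste(unique(dup), collapse = ", "))
  empty <- db$accession[!nzchar(db$sequence) | is.na(db$sequence)]
  if (length(empty))
    stop("empty sequence for accession(s): ", paste(empty, collapse = ", "))
  bad <- !db$origin %in% c("organism", "contaminant")
  if (any(bad)) stop("origin must be 'organism' or 'contaminant'")
  invisible(db)
}

#' @export
print.sequence_db <- function(x, ...) {
  cat(sprintf("<sequence_db> %d entries (%d forward, %d decoy)\n",
              nrow(x), sum(!x$is_decoy), sum(x$is_decoy)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}

reverse_sequence <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Build a concatenated target + contaminant + reversed-decoy database
#'
#' Appends the contaminant entries to the organism entries and then appends a
#' whole-sequence reversed decoy for every forward entry, so the output holds
#' exactly twice as many entries as the combined forward input.  Decoy
#' accessions are the forward accession with `prefix` prepended.  Order is
#' forwards (organism, then contaminants) followed by decoys in the same
#' order, stable within each block.
#'
#' @param organism_db,contaminant_db forward-only [sequence_db] objects
#'   (no decoy entries).
#' @param prefix reserved decoy accession prefix (default `"REV_"`).
#' @return a [sequence_db] with `2 * (nrow(organism_db) + nrow(contaminant_db))`
#'   entries.
#' @examples
#' org <- sequence_db(c("P1", "P2"), c("MKLV", "AAKR"))
#' db  <- build_decoy_database(org, empty_sequence_db("contaminant"))
#' nrow(db)            # 4
#' db$sequence[3]      # "VLKM"
#' @export
build_decoy_database <- function(organism_db, contaminant_db = NULL,
                                 prefix = "REV_") {
  if (is.null(contaminant_db)) contaminant_db <- empty_sequence_db("contaminant")
  stopifnot(inherits(organism_db, "sequence_db"),
            inherits(contaminant_db, "sequence_db"))
  if (any(organism_db$is_decoy) || any(contaminant_db$is_decoy))
    stop("inputs must be forward-only databases")
  if (!nzchar(prefix)) stop("decoy prefix must be non-empty")
  org <- as.data.frame(organism_db)
  org$origin <- rep("organism", nrow(org))
  cont <- as.data.frame(contaminant_db)
  cont$origin <- rep("contaminant", nrow(cont))
  fwd <- rbind(org, cont)
  dup <- fwd$accession[duplicated(fwd$accession)]
  if (length(dup))
    stop("duplicate accession(s) across inputs: ",
         paste(unique(dup), collapse = ", "))
  if (nrow(fwd) == 0L) return(empty_sequence_db())
  empty <- fwd$accession[!nzchar(fwd$sequence)]
  if (length(empty))
    stop("empty sequence for accession(s): ", paste(empty, collapse = ", "))
  pre <- startsWith(fwd$accession, prefix)
  if (any(pre))
    stop("forward accession(s) already carry the decoy prefix: ",
         paste(fwd$accession[pre], collapse = ", "))
  dec <- fwd
  dec$accession <- paste0(prefix, fwd$accession)
  dec$sequence  <- reverse_sequence(fwd$sequence)
  dec$is_decoy  <- TRUE
  out <- rbind(fwd, dec)
  rownames(out) <- NULL
  class(out) <- c("sequence_db", "data.frame")
  attr(out, "decoy_prefix") <- prefix
  out
}

#' @rdname build_decoy_database
#' @param db a concatenated [sequence_db].
#' @return `strip_decoys()`: the forward block of `db`.
#' @export
strip_decoys <- function(db) {
  out <- db[!db$is_decoy, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname sequence_db
#' @export
empty_sequence_db <- function(origin = "organism") {
  db <- data.frame(accession = character(), sequence = character(),
                   origin = character(), is_decoy = logical(),
                   description = character(), stringsAsFactors = FALSE)
  class(db) <- c("sequence_db", "data.frame")
  db
}

#' Read / write a sequence database as FASTA
#'
#' Thin wrappers around [Biostrings::readAAStringSet()] and
#' [Biostrings::writeXStringSet()].  The FASTA header is the accession
#' followed, after a space, by the optional description; output is wrapped at
#' 60 columns.  On reading, decoy status is derived from the accession prefix.
#'
#' @param path file path.
#' @param db a [sequence_db].
#' @param origin origin flag assigned to all non-decoy entries read.
#' @param prefix decoy accession prefix used to flag decoys on read.
#' @return `read_fasta()` returns a [sequence_db]; `write_fasta()` returns
#'   `path` invisibly.
#' @export
read_fasta <- function(path, origin = "organism", prefix = "REV_") {
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) return(empty_sequence_db())
  nm <- names(aas)
  acc <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), NA_character_)
  db <- sequence_db(acc, as.character(aas), origin = origin,
                    is_decoy = startsWith(acc, prefix), description = desc)
  db
}

#' @rdname read_fasta
#' @export
write_fasta <- function(db, path) {
  hdr <- ifelse(is.na(db$description), db$accession,
                paste(db$accession, db$description))
  aas <- Biostrings::AAStringSet(setNames(db$sequence, hdr))
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}
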