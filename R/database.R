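# The short-peptide read database: reads, stable ids, offsets into the
# sentinel-separated concatenated text, and optional per-read provenance
# (source id + interval) for simulated data.

#' Construct a peptide read database
#'
#' @param reads character vector of amino-acid read sequences (length >= 1
#'   each; standard residues plus the wildcard `X`).
#' @param ids stable read identifiers (default `read_1..n`); must be unique.
#' @param provenance optional data.frame with one row per read and columns
#'   `source`, `start`, `end` (0-based, half-open interval in the source
#'   protein the read was sampled from).
#' @return an object of class `peptide_db` with fields `reads`, `ids`, `lens`,
#'   `offsets` (0-based start of each read in the concatenated text), `text`
#'   (reads joined by a sentinel character, with a trailing sentinel) and
#'   `provenance`.
#' @export
peptide_db <- function(reads, ids = NULL, provenance = NULL) {
  stopifnot(is.character(reads), length(reads) >= 1L)
  if (any(nchar(reads) < 1L)) stop("every read must have length >= 1")
  bad <- grepl(sprintf("[^%sX]", paste(AA_STANDARD, collapse = "")), reads)
  if (any(bad)) stop("read contains invalid residues: ", reads[bad][[1]])
  if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("read ids must be unique")
  if (!is.null(provenance)) {
    stopifnot(is.data.frame(provenance), nrow(provenance) == length(reads),
              all(c("source", "start", "end") %in% names(provenance)))
  }
  lens <- nchar(reads)
  offsets <- c(0L, cumsum(lens + 1L))[seq_along(reads)]
  structure(
    list(reads = unname(reads), ids = ids, lens = lens,
         offsets = as.integer(offsets),
         text = paste0(paste(reads, collapse = TEXT_SENTINEL), TEXT_SENTINEL),
         provenance = provenance),
    class = c("peptide_db", "pepgrasp_obj"))
}

#' @export
format.peptide_db <- function(x, ...) {
  sprintf("<peptide_db: %d reads, %d residues%s>",
          length(x$reads), sum(x$lens),
          if (is.null(x$provenance)) "" else ", with provenance")
}

#' @export
length.peptide_db <- function(x) length(x$reads)

#' Total residues in the database (the search-space size n)
#' @param db a [peptide_db()].
#' @export
db_residues <- function(db) sum(db$lens)

#' Read a peptide database from a FASTA file
#'
#' @param path amino-acid FASTA file.
#' @param provenance optional provenance TSV (columns `source`, `start`,
#'   `end`, same order as the FASTA records) as written by
#'   [write_peptide_db()].
#' @return a [peptide_db()].
#' @export
read_peptide_db <- function(path, provenance = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  prov <- NULL
  if (!is.null(provenance)) {
    prov <- utils::read.delim(provenance, stringsAsFactors = FALSE)
    prov <- prov[, c("source", "start", "end")]
  }
  peptide_db(as.character(ss), ids = sub("\\s.*$", "", names(ss)),
             provenance = prov)
}

#' Write a peptide database (FASTA plus optional provenance TSV)
#'
#' @param db a [peptide_db()].
#' @param path output FASTA path.
#' @param provenance optional path for a provenance TSV
#'   (`id`, `source`, `start`, `end`).
#' @return `path`, invisibly.
#' @export
write_peptide_db <- function(db, path, provenance = NULL) {
  ss <- Biostrings::AAStringSet(setNames(db$reads, db$ids))
  Biostrings::writeXStringSet(ss, path)
  if (!is.null(provenance)) {
    if (is.null(db$provenance)) stop("database has no provenance to write")
    utils::write.table(cbind(id = db$ids, db$provenance), provenance,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read query protein sequences from FASTA
#'
#' @param path amino-acid FASTA file.
#' @return named character vector of query sequences.
#' @export
read_queries <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}
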