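# Database indexing: suffix array + LCP, pre-built extension links (both
# directions), the reduced-alphabet k-mer seed index, and the versioned
# on-disk index bundle.

#' Build the suffix array and LCP array of a peptide database
#'
#' Suffixes of the sentinel-separated concatenated text are sorted
#' lexicographically (sentinels lowest); `lcp[i]` is the longest-common-prefix
#' length of the suffixes at ranks i-1 and i (`lcp[1] = 0`).
#'
#' @param db a [peptide_db()].
#' @return an object of class `suffix_index` with 0-based `sa`, `lcp`, and
#'   `text_len`.
#' @export
build_suffix_index <- function(db) {
  stopifnot(inherits(db, "peptide_db"))
  res <- cpp_suffix_index(db$text)
  structure(list(sa = res$sa, lcp = res$lcp, text_len = nchar(db$text)),
            class = c("suffix_index", "pepgrasp_obj"))
}

#' @export
format.suffix_index <- function(x, ...) {
  sprintf("<suffix_index: %d positions>", x$text_len)
}

# reads collapsed out of link construction: substrings of a longer read, or
# exact duplicates of a read with a smaller index (the representative stays)
contained_reads <- function(db, sidx) {
  cpp_contained_reads(db$text, sidx$sa, sidx$lcp, db$offsets, db$lens)
}

reverse_strings <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

# MES dominance filter on one source's candidates: drop a sink whose
# extension sequence is contained in another candidate's extension as a
# substring; ties between identical extensions are broken towards the longer
# overlap, then the smaller read index.
mes_filter <- function(sink, overlap, ext) {
  n <- length(ext)
  if (n <= 1L) return(rep(TRUE, n))
  keep <- logical(n)
  nc <- nchar(ext)
  for (i in seq_len(n)) {
    inside <- grepl(ext[[i]], ext, fixed = TRUE)
    inside[i] <- FALSE
    dom <- inside & (nc > nc[[i]] |
                       (ext == ext[[i]] &
                          (overlap > overlap[[i]] |
                             (overlap == overlap[[i]] & sink < sink[[i]]))))
    keep[[i]] <- !any(dom)
  }
  keep
}

#' Build the extension-link table of a peptide database
#'
#' A right link `source -> sink` records that the sink read is a maximal
#' extension sequence (MES) of the source: the last `overlap` residues of the
#' source equal the first `overlap` residues of the sink, `overlap >=
#' min_overlap`, the sink extends beyond the source, and the sink's extension
#' is not contained in any other candidate's extension as a substring.  The
#' left direction is the mirror image (derived from a second suffix array on
#' the residue-reversed reads).  Exact duplicates and fully contained reads
#' are collapsed out of link construction (post-mapping restores them), and a
#' read never links to itself.  Fan-out is capped at `max_links` per source,
#' keeping the longest overlaps first (ties broken by ascending read index).
#'
#' @param db a [peptide_db()].
#' @param index a [build_suffix_index()] result for `db` (forward text).
#' @param min_overlap minimum exact overlap in residues (default 10).
#' @param max_links fan-out cap per source read (default 20; `Inf` disables).
#' @param direction `"right"` or `"left"`.
#' @return an object of class `extension_links` with a `links` data.frame
#'   (`src`, `sink` read indices, `overlap`) and a per-source lookup.
#' @export
build_extension_links <- function(db, index = build_suffix_index(db),
                                  min_overlap = 10L, max_links = 20L,
                                  direction = c("right", "left")) {
  direction <- match.arg(direction)
  stopifnot(inherits(db, "peptide_db"), min_overlap >= 1L)
  contained <- contained_reads(db, index)
  if (direction == "right") {
    cand <- cpp_link_candidates(db$text, index$sa, index$lcp, db$offsets,
                                db$lens, contained, as.integer(min_overlap))
    reads_used <- db$reads
  } else {
    rev_reads <- reverse_strings(db$reads)
    rev_text <- paste0(paste(rev_reads, collapse = TEXT_SENTINEL), TEXT_SENTINEL)
    ridx <- cpp_suffix_index(rev_text)
    cand <- cpp_link_candidates(rev_text, ridx$sa, ridx$lcp, db$offsets,
                                db$lens, contained, as.integer(min_overlap))
    reads_used <- rev_reads
  }
  keep_rows <- list()
  if (nrow(cand) > 0) {
    ext <- substr(reads_used[cand$sink], cand$overlap + 1L,
                  nchar(reads_used[cand$sink]))
    for (s in unique(cand$src)) {
      rows <- which(cand$src == s)
      ok <- mes_filter(cand$sink[rows], cand$overlap[rows], ext[rows])
      rows <- rows[ok]
      o <- order(-cand$overlap[rows], cand$sink[rows])
      rows <- rows[o]
      if (is.finite(max_links) && length(rows) > max_links)
        rows <- rows[seq_len(max_links)]
      keep_rows[[as.character(s)]] <- rows
    }
  }
  rows <- unlist(keep_rows, use.names = FALSE)
  links <- cand[rows, , drop = FALSE]
  links <- links[order(links$src, -links$overlap, links$sink), , drop = FALSE]
  rownames(links) <- NULL
  structure(
    list(direction = direction, links = links,
         by_src = split(links[c("sink", "overlap")], links$src),
         min_overlap = as.integer(min_overlap), max_links = max_links),
    class = c("extension_links", "pepgrasp_obj"))
}

#' @export
format.extension_links <- function(x, ...) {
  sprintf("<extension_links %s: %d links, min_overlap=%d, max_links=%s>",
          x$direction, nrow(x$links), x$min_overlap,
          format(x$max_links))
}

# per-source lookup; src is a read index
links_for <- function(links, src) {
  links$by_src[[as.character(src)]]
}

#' Brute-force maximal extension sequences of one read (test oracle)
#'
#' Independent of the suffix-array route: enumerates all exact suffix/prefix
#' overlaps `>= min_overlap` between the source and every other read by
#' direct string comparison, then removes any sink whose extension sequence
#' is contained in another candidate's extension as a substring (same
#' deterministic tie rule as [build_extension_links()]).  Exact duplicates and
#' contained reads are collapsed with the same representative rule; a
#' contained source yields no links.
#'
#' @param source read index or read id in `db`.
#' @param db a [peptide_db()].
#' @param min_overlap minimum overlap (residues).
#' @param direction `"right"` or `"left"`.
#' @return data.frame (`sink`, `overlap`), sorted by descending overlap then
#'   ascending sink index.
#' @export
brute_force_mes <- function(source, db, min_overlap = 10L,
                            direction = c("right", "left")) {
  direction <- match.arg(direction)
  stopifnot(inherits(db, "peptide_db"))
  if (is.character(source)) source <- match(source, db$ids)
  stopifnot(!is.na(source), source >= 1L, source <= length(db$reads))
  reads <- db$reads
  lens <- db$lens
  n <- length(reads)
  # brute-force containment with the representative tie rule
  contained <- vapply(seq_len(n), function(t) {
    hit <- grepl(reads[[t]], reads, fixed = TRUE)
    hit[t] <- FALSE
    any(hit & (lens > lens[[t]] | (reads == reads[[t]] & seq_len(n) < t)))
  }, NA)
  empty <- data.frame(sink = integer(0), overlap = integer(0))
  if (contained[[s <- source]]) return(empty)
  sread <- reads[[s]]
  cand <- list()
  for (t in seq_len(n)) {
    if (t == s || contained[[t]]) next
    maxov <- 0L
    upper <- min(lens[[s]], lens[[t]]) - 1L
    for (ov in (if (upper >= min_overlap) seq.int(upper, min_overlap) else integer(0))) {
      hit <- if (direction == "right") {
        substr(sread, lens[[s]] - ov + 1L, lens[[s]]) ==
          substr(reads[[t]], 1L, ov)
      } else {
        substr(sread, 1L, ov) ==
          substr(reads[[t]], lens[[t]] - ov + 1L, lens[[t]])
      }
      if (hit) { maxov <- ov; break }
    }
    if (maxov > 0L) {
      ext <- if (direction == "right") substr(reads[[t]], maxov + 1L, lens[[t]])
             else substr(reads[[t]], 1L, lens[[t]] - maxov)
      cand[[length(cand) + 1L]] <- list(sink = t, overlap = maxov, ext = ext)
    }
  }
  if (length(cand) == 0L) return(empty)
  sink <- vapply(cand, `[[`, 0L, "sink")
  overlap <- vapply(cand, `[[`, 0L, "overlap")
  ext <- vapply(cand, `[[`, "", "ext")
  nc <- nchar(ext)
  keep <- vapply(seq_along(cand), function(i) {
    dom <- FALSE
    for (j in seq_along(cand)) {
      if (j == i) next
      if (!grepl(ext[[i]], ext[[j]], fixed = TRUE)) next
      if (nc[[j]] > nc[[i]] ||
          (ext[[j]] == ext[[i]] &&
             (overlap[[j]] > overlap[[i]] ||
                (overlap[[j]] == overlap[[i]] && sink[[j]] < sink[[i]])))) {
        dom <- TRUE
        break
      }
    }
    !dom
  }, NA)
  out <- data.frame(sink = sink[keep], overlap = overlap[keep])
  out <- out[order(-out$overlap, out$sink), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the reduced-alphabet k-mer seed index
#'
#' Every k-length window of every read (length >= k) is recorded exactly once
#' under its reduced-alphabet k-mer; windows touching the wildcard letter are
#' skipped.
#'
#' @param db a [peptide_db()].
#' @param alphabet a [reduced_alphabet()].
#' @param k seed length (default 6).
#' @return an object of class `seed_index` with `occ` (data.frame `read`,
#'   `pos`, 0-based window start) and a lookup table keyed by reduced k-mer.
#' @export
build_seed_index <- function(db, alphabet = reduced_alphabet(), k = 6L) {
  stopifnot(inherits(db, "peptide_db"), k >= 1L)
  red <- reduce_sequence(db$reads, alphabet)
  occ_read <- integer(0); occ_pos <- integer(0); occ_kmer <- character(0)
  nw <- pmax(0L, db$lens - k + 1L)
  idx <- which(nw > 0L)
  if (length(idx) > 0L) {
    occ_read <- rep(idx, nw[idx])
    occ_pos <- unlist(lapply(nw[idx], seq_len), use.names = FALSE) - 1L
    occ_kmer <- substring(red[occ_read], occ_pos + 1L, occ_pos + k)
    ok <- !grepl("#", occ_kmer, fixed = TRUE)
    occ_read <- occ_read[ok]; occ_pos <- occ_pos[ok]; occ_kmer <- occ_kmer[ok]
  }
  occ <- data.frame(read = occ_read, pos = occ_pos)
  structure(
    list(k = as.integer(k), alphabet = alphabet, occ = occ,
         table = split(seq_len(nrow(occ)), occ_kmer), reads = db$reads),
    class = c("seed_index", "pepgrasp_obj"))
}

#' @export
format.seed_index <- function(x, ...) {
  sprintf("<seed_index: k=%d, %d occurrences, %d distinct k-mers>",
          x$k, nrow(x$occ), length(x$table))
}

## ---- index bundle ----------------------------------------------------------

INDEX_FORMAT_VERSION <- "1"

index_fingerprint <- function(params, db) {
  paste0("pepgrasp/", INDEX_FORMAT_VERSION,
         ";k=", params$k, ";alphabet=", params$alphabet,
         ";min_overlap=", params$min_overlap,
         ";max_links=", params$max_links,
         ";matrix=", params$matrix,
         ";gap=", params$gap_open, "/", params$gap_extend,
         ";reads=", length(db$reads), ";residues=", db_residues(db))
}

#' Build the full searchable index of a peptide database
#'
#' Bundles the suffix/LCP arrays, both extension-link tables, and the seed
#' index, plus a parameter fingerprint used to refuse incompatible searches.
#'
#' @param db a [peptide_db()].
#' @param matrix a [scoring_matrix()] (named in the fingerprint).
#' @param alphabet a [reduced_alphabet()].
#' @param k seed length.
#' @param min_overlap minimum link overlap (residues).
#' @param max_links fan-out cap.
#' @return an object of class `grasp_index`.
#' @export
build_index <- function(db, matrix = blosum62(),
                        alphabet = reduced_alphabet(), k = 6L,
                        min_overlap = 10L, max_links = 20L) {
  sidx <- build_suffix_index(db)
  params <- list(k = as.integer(k), alphabet = alphabet$name,
                 min_overlap = as.integer(min_overlap),
                 max_links = max_links, matrix = matrix$name,
                 gap_open = matrix$gap_open, gap_extend = matrix$gap_extend)
  structure(
    list(db = db, suffix = sidx,
         links_right = build_extension_links(db, sidx, min_overlap, max_links,
                                             "right"),
         links_left = build_extension_links(db, sidx, min_overlap, max_links,
                                            "left"),
         seeds = build_seed_index(db, alphabet, k),
         alphabet = alphabet, params = params,
         fingerprint = index_fingerprint(params, db)),
    class = c("grasp_index", "pepgrasp_obj"))
}

#' @export
format.grasp_index <- function(x, ...) {
  c(format(x$db), format(x$suffix), format(x$links_right),
    format(x$links_left), format(x$seeds),
    sprintf("fingerprint: %s", x$fingerprint))
}

#' Save an index to a directory of versioned JSON artifacts
#'
#' Writes `meta.json` (format version, parameters, fingerprint, alphabet
#' groups), `db.json`, `suffix.json`, and the two link tables.  The seed
#' index is rebuilt deterministically on load and is not serialized.
#'
#' @param index a [build_index()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_index <- function(index, dir) {
  stopifnot(inherits(index, "grasp_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, f)
    jsonlite::write_json(x, file.path(dir, f), auto_unbox = TRUE, digits = NA,
                         null = "null")
  wj(list(format_version = INDEX_FORMAT_VERSION, params = index$params,
          fingerprint = index$fingerprint,
          alphabet_groups = as.list(index$alphabet$groups)), "meta.json")
  wj(list(ids = index$db$ids, reads = index$db$reads,
          provenance = index$db$provenance), "db.json")
  wj(list(sa = index$suffix$sa, lcp = index$suffix$lcp), "suffix.json")
  wj(index$links_right$links, "links_right.json")
  wj(index$links_left$links, "links_left.json")
  invisible(dir)
}

read_index_json <- function(dir, f) {
  path <- file.path(dir, f)
  if (!file.exists(path)) stop("missing index artifact: ", path)
  tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
           error = function(e) stop("corrupt index file '", path, "': ",
                                    conditionMessage(e)))
}

#' Load an index saved by [save_index()]
#'
#' @param dir index directory.
#' @return a `grasp_index`; errors on version mismatch or corrupt artifacts.
#' @export
load_index <- function(dir) {
  meta <- read_index_json(dir, "meta.json")
  if (!identical(as.character(meta$format_version), INDEX_FORMAT_VERSION))
    stop("index format version mismatch: found '", meta$format_version,
         "', expected '", INDEX_FORMAT_VERSION, "'")
  dbj <- read_index_json(dir, "db.json")
  prov <- dbj$provenance
  if (!is.null(prov) && !is.data.frame(prov)) prov <- as.data.frame(prov)
  if (!is.null(prov) && nrow(prov) == 0L) prov <- NULL
  db <- peptide_db(dbj$reads, ids = dbj$ids, provenance = prov)
  sj <- read_index_json(dir, "suffix.json")
  sidx <- structure(list(sa = as.integer(sj$sa), lcp = as.integer(sj$lcp),
                         text_len = nchar(db$text)),
                    class = c("suffix_index", "pepgrasp_obj"))
  if (length(sidx$sa) != sidx$text_len)
    stop("corrupt index file '", file.path(dir, "suffix.json"),
         "': suffix array length mismatch")
  params <- meta$params
  params$max_links <- as.numeric(params$max_links)  # "Inf" round-trips via JSON string
  groups <- unlist(meta$alphabet_groups)
  alphabet <- reduced_alphabet(groups)
  alphabet$name <- params$alphabet
  mk_links <- function(f, direction) {
    links <- read_index_json(dir, f)
    if (length(links) == 0L || nrow(links) == 0L)
      links <- data.frame(src = integer(0), sink = integer(0),
                          overlap = integer(0))
    links <- data.frame(src = as.integer(links$src),
                        sink = as.integer(links$sink),
                        overlap = as.integer(links$overlap))
    structure(
      list(direction = direction, links = links,
           by_src = split(links[c("sink", "overlap")], links$src),
           min_overlap = as.integer(params$min_overlap),
           max_links = params$max_links),
      class = c("extension_links", "pepgrasp_obj"))
  }
  idx <- structure(
    list(db = db, suffix = sidx,
         links_right = mk_links("links_right.json", "right"),
         links_left = mk_links("links_left.json", "left"),
         seeds = build_seed_index(db, alphabet, as.integer(params$k)),
         alphabet = alphabet, params = params,
         fingerprint = meta$fingerprint),
    class = c("grasp_index", "pepgrasp_obj"))
  if (!identical(index_fingerprint(idx$params, db), idx$fingerprint))
    stop("index fingerprint mismatch: artifacts do not match their metadata")
  idx
}
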