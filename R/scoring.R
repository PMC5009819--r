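# Amino-acid alphabets, substitution matrices and BLAST-style alignment
# statistics shared by the indexing, search and evaluation stages.

#' The 20 standard amino-acid one-letter codes
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# wildcard policy: 'X' scores 0 against everything and reduces to a dedicated
# letter that is excluded from seeding windows
AA_WILDCARD <- "X"

#' Construct a substitution scoring matrix
#'
#' Wraps a 20x20 integer substitution matrix together with affine gap
#' penalties.  Gap penalties are stored as positive magnitudes and applied
#' subtractively; a gap of length g costs `gap_open + g * gap_extend`.
#' The wildcard residue `X` is added (if absent) with score 0 against every
#' residue, so partially masked sequences can still be aligned.
#'
#' @param scores integer matrix covering at least the 20 standard residues
#'   (row/column names are one-letter codes); must be symmetric over them.
#' @param gap_open,gap_extend positive gap penalty magnitudes.
#' @param name identifier for the matrix.
#' @return an object of class `scoring_matrix` with fields `name`, `scores`
#'   (21x21, including `X`), `gap_open`, `gap_extend` and `mean_diagonal`
#'   (the mean of the 20 standard diagonal entries, the quantity `a` used by
#'   the seed-score rule).
#' @export
scoring_matrix <- function(scores, gap_open = 11, gap_extend = 1,
                           name = "custom") {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  if (!all(AA_STANDARD %in% rownames(scores)) ||
      !all(AA_STANDARD %in% colnames(scores)))
    stop("scoring matrix must cover the 20 standard residues")
  m <- scores[AA_STANDARD, AA_STANDARD, drop = FALSE]
  storage.mode(m) <- "integer"
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop("scoring matrix must be symmetric over the 20 standard residues")
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties are positive magnitudes")
  full <- matrix(0L, 21, 21,
                 dimnames = list(c(AA_STANDARD, AA_WILDCARD),
                                 c(AA_STANDARD, AA_WILDCARD)))
  full[AA_STANDARD, AA_STANDARD] <- m
  if (AA_WILDCARD %in% rownames(scores)) {
    full[AA_WILDCARD, AA_STANDARD] <- 0L  # wildcard policy overrides
    full[AA_STANDARD, AA_WILDCARD] <- 0L
  }
  structure(
    list(name = name, scores = full,
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         mean_diagonal = mean(diag(m))),
    class = c("scoring_matrix", "pepgrasp_obj"))
}

#' @export
format.scoring_matrix <- function(x, ...) {
  sprintf("<scoring_matrix %s: gap %d/%d, mean diagonal a = %.3f>",
          x$name, x$gap_open, x$gap_extend, x$mean_diagonal)
}

#' BLOSUM62 with the default -11/-1 affine gap penalties
#'
#' The published BLOSUM62 substitution scores (taken from the Biostrings data
#' matrix, subset to the 20 standard residues) with gap opening and extension
#' penalty magnitudes 11 and 1 — the default alignment model of the search
#' engine.
#'
#' @param gap_open,gap_extend gap penalty magnitudes.
#' @return a [scoring_matrix()].
#' @export
blosum62 <- function(gap_open = 11, gap_extend = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  scoring_matrix(env$BLOSUM62[AA_STANDARD, AA_STANDARD],
                 gap_open = gap_open, gap_extend = gap_extend,
                 name = "BLOSUM62")
}

#' Read an NCBI-format substitution matrix file
#'
#' Parses the plain-text matrix format used by NCBI BLAST (`#` comment lines,
#' a header row of residue letters, then one labelled row per residue).
#'
#' @param path file path.
#' @inheritParams scoring_matrix
#' @return a [scoring_matrix()].
#' @export
read_score_matrix <- function(path, gap_open = 11, gap_extend = 1,
                              name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a matrix file: ", path)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labs <- vapply(rows, `[[`, "", 1L)
  vals <- lapply(rows, function(r) as.integer(r[-1]))
  if (any(lengths(vals) != length(header)))
    stop("malformed matrix row in ", path)
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labs, header)
  scoring_matrix(m, gap_open = gap_open, gap_extend = gap_extend, name = name)
}

#' Mean of the diagonal substitution scores
#'
#' The quantity `a` entering the seed acceptance rule `k * factor * a`
#' (default `6 * 0.7 * a`, i.e. 24.36 for BLOSUM62).
#'
#' @param matrix a [scoring_matrix()].
#' @return the arithmetic mean of the 20 standard diagonal entries.
#' @export
mean_diagonal <- function(matrix) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  matrix$mean_diagonal
}

#' Seed acceptance score threshold
#'
#' @param matrix a [scoring_matrix()].
#' @param k seed length (residues).
#' @param factor score fraction per residue.
#' @return `k * factor * mean_diagonal(matrix)`.
#' @export
seed_score_threshold <- function(matrix, k = 6L, factor = 0.7) {
  k * factor * mean_diagonal(matrix)
}

#' Karlin-Altschul search statistics
#'
#' Houses the scale parameters lambda and K together with the search-space
#' dimensions: `m` is the query length in residues and `n` the total number
#' of residues in the read database (fixed per database so E-values are
#' comparable across contigs of one search).  Defaults are the standard NCBI
#' gapped BLOSUM62(11,1) constants.
#'
#' @param m query length (residues).
#' @param n total database residues.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @return an object of class `scoring_stats`.
#' @export
scoring_stats <- function(m, n, lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0, m > 0, n > 0)
  structure(list(lambda = lambda, K = K, m = as.numeric(m), n = as.numeric(n)),
            class = c("scoring_stats", "pepgrasp_obj"))
}

#' @export
format.scoring_stats <- function(x, ...) {
  sprintf("<scoring_stats lambda=%.3f K=%.3f m=%g n=%g>",
          x$lambda, x$K, x$m, x$n)
}

#' Bit score of a raw alignment score
#'
#' `(lambda * raw - log(K)) / log(2)`, as in BLAST.
#'
#' @param raw raw alignment score(s).
#' @param stats a [scoring_stats()].
#' @export
bit_score <- function(raw, stats) {
  stopifnot(inherits(stats, "scoring_stats"))
  (stats$lambda * raw - log(stats$K)) / log(2)
}

#' E-value of a bit score
#'
#' `m * n * 2^-bits`, as in BLAST.
#'
#' @param bits bit score(s).
#' @param stats a [scoring_stats()].
#' @export
e_value <- function(bits, stats) {
  stopifnot(inherits(stats, "scoring_stats"))
  stats$m * stats$n * 2^(-bits)
}

# raw-score drop corresponding to a bit drop-off (X-drop pruning)
dropoff_raw <- function(bits, stats) bits * log(2) / stats$lambda

## ---- reduced alphabets -----------------------------------------------------

# Shipped 10-group reduction: the Murphy/Wallqvist/Levy BLOSUM50-derived
# 10-letter clustering {LVIM, C, A, G, ST, P, FYW, EDNQ, KR, H}; the standard
# 10-group table used for conservative-substitution-tolerant seeding.
# "gbmr10" is accepted as an alias for this shipped default.
REDUCED_GROUPS <- list(
  murphy10 = c(L = "LVIM", C = "C", A = "A", G = "G", S = "ST", P = "P",
               F = "FYW", E = "EDNQ", K = "KR", H = "H"),
  identity = setNames(AA_STANDARD, AA_STANDARD)
)

#' Reduced amino-acid alphabet
#'
#' A total mapping of the 20 standard residues onto a smaller group alphabet,
#' used to make k-mer seeding tolerant to conservative substitutions.  The
#' shipped 10-group default (`"murphy10"`, alias `"gbmr10"`) is the standard
#' BLOSUM50-derived clustering LVIM / C / A / G / ST / P / FYW / EDNQ / KR / H.
#' The wildcard `X` maps to a dedicated letter (`#`) whose windows are never
#' indexed or seeded.  A custom alphabet can be supplied as a named character
#' vector `group letter -> residues`.
#'
#' @param name `"murphy10"` (default; `"gbmr10"` is an alias), `"identity"`,
#'   or a named character vector defining custom groups.
#' @return an object of class `reduced_alphabet` with fields `name`, `groups`
#'   and `map` (named vector residue -> group letter).
#' @export
reduced_alphabet <- function(name = "murphy10") {
  if (is.character(name) && length(name) == 1L && is.null(names(name))) {
    key <- if (identical(tolower(name), "gbmr10")) "murphy10" else tolower(name)
    groups <- REDUCED_GROUPS[[key]]
    if (is.null(groups)) stop("unknown reduced alphabet: ", name)
    label <- key
  } else {
    groups <- name
    label <- "custom"
  }
  map <- character(0)
  for (g in names(groups)) {
    res <- strsplit(groups[[g]], "")[[1]]
    map[res] <- g
  }
  if (!setequal(names(map), AA_STANDARD) || anyDuplicated(names(map)))
    stop("reduced alphabet must map each of the 20 standard residues exactly once")
  map <- map[AA_STANDARD]
  map[AA_WILDCARD] <- "#"
  structure(list(name = label, groups = groups, map = map),
            class = c("reduced_alphabet", "pepgrasp_obj"))
}

#' @export
format.reduced_alphabet <- function(x, ...) {
  sprintf("<reduced_alphabet %s: %d groups>", x$name,
          length(unique(x$map[AA_STANDARD])))
}

#' Map sequences into a reduced alphabet
#'
#' @param seq character vector of amino-acid sequences (standard residues,
#'   plus the wildcard `X`).
#' @param alphabet a [reduced_alphabet()].
#' @return character vector of the same lengths over the group letters.
#' @export
reduce_sequence <- function(seq, alphabet = reduced_alphabet()) {
  stopifnot(inherits(alphabet, "reduced_alphabet"), is.character(seq))
  bad <- grepl(sprintf("[^%s]", paste(names(alphabet$map), collapse = "")), seq)
  if (any(bad))
    stop("sequence contains non-standard residues without a wildcard policy: ",
         seq[bad][[1]])
  chartr(paste(names(alphabet$map), collapse = ""),
         paste(unname(alphabet$map), collapse = ""), seq)
}
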