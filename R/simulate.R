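# Synthetic peptide-read simulator with recorded provenance, emulating
# shotgun sampling of short peptides (~100 bp reads => ~33 aa peptides at
# 10X coverage with 1 % substitution errors) so every downstream stage is
# testable without external data.

#' Simulation configuration
#'
#' Defaults state the emulated sampling model: 10X coverage, expected read
#' length 33 aa (~100 bp translated), 1 % per-residue substitution error.
#'
#' @param sources named character vector of source protein sequences (or a
#'   FASTA path).
#' @param coverage fold coverage (> 0).
#' @param read_length_aa expected peptide read length in residues.
#' @param error_rate per-residue substitution probability in `[0, 1)`.
#' @param abundance_weights optional positive per-source relative abundances
#'   (recycled name-matched to sources; default equal).
#' @param rng_seed integer seed; fixed seed gives a byte-identical database.
#' @param length_jitter logical; if `TRUE` read lengths are geometrically
#'   jittered around the expected length instead of fixed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(sources, coverage = 10, read_length_aa = 33L,
                       error_rate = 0.01, abundance_weights = NULL,
                       rng_seed = 1L, length_jitter = FALSE) {
  if (is.character(sources) && length(sources) == 1L && file.exists(sources))
    sources <- read_queries(sources)
  stopifnot(is.character(sources), length(sources) >= 1L)
  if (is.null(names(sources)))
    names(sources) <- sprintf("source_%d", seq_along(sources))
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (is.null(abundance_weights))
    abundance_weights <- setNames(rep(1, length(sources)), names(sources))
  if (is.null(names(abundance_weights)))
    names(abundance_weights) <- names(sources)
  w <- abundance_weights[names(sources)]
  if (any(!is.finite(w)) || any(w <= 0))
    stop("abundance weights must be positive and finite")
  structure(list(sources = sources, coverage = coverage,
                 read_length_aa = as.integer(read_length_aa),
                 error_rate = error_rate, abundance_weights = w,
                 rng_seed = as.integer(rng_seed),
                 length_jitter = isTRUE(length_jitter)),
            class = c("sim_config", "pepgrasp_obj"))
}

#' @export
format.sim_config <- function(x, ...) {
  sprintf("<sim_config: %d sources, %gX, len %d aa, error %.3f, seed %d>",
          length(x$sources), x$coverage, x$read_length_aa, x$error_rate,
          x$rng_seed)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

substitute_residues <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < error_rate)
  for (i in hit) {
    alt <- AA_STANDARD[AA_STANDARD != chars[[i]]]
    chars[[i]] <- alt[[sample.int(length(alt), 1L)]]
  }
  paste(chars, collapse = "")
}

#' Simulate a peptide read database with provenance
#'
#' Draws `round(coverage * total source residues / read length)` reads;
#' each read's source is chosen with probability proportional to
#' `abundance_weight * source length`, its start uniformly so the read lies
#' inside the source, and substitutions are applied i.i.d. per residue
#' (uniform over the 19 alternatives; no indels).  Per-read provenance
#' (source, 0-based half-open interval) is recorded exactly.  Sources
#' shorter than the read length yield truncated whole-source reads with a
#' warning.
#'
#' @param config a [sim_config()].
#' @return list with `db` (a [peptide_db()] with provenance) and `truth`
#'   (a ground-truth scaffold: sources, per-query homolog intervals in
#'   planted mode, and the interval rule).
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  src <- config$sources
  slen <- nchar(src)
  L <- config$read_length_aa
  n_reads <- max(1L, round(config$coverage * sum(slen) / L))
  with_seed(config$rng_seed, {
    p <- config$abundance_weights * slen
    which_src <- sample.int(length(src), n_reads, replace = TRUE,
                            prob = p / sum(p))
    lens <- if (config$length_jitter)
      pmax(1L, stats::rgeom(n_reads, 1 / L) + 1L)
    else rep(L, n_reads)
    short <- unique(names(src)[which_src][lens > slen[which_src]])
    if (length(short) > 0L)
      warning("sources shorter than the read length (truncated reads): ",
              paste(short, collapse = ", "))
    reads <- character(n_reads)
    starts <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      s <- which_src[[i]]
      li <- min(lens[[i]], slen[[s]])
      starts[[i]] <- sample.int(slen[[s]] - li + 1L, 1L) - 1L
      reads[[i]] <- substitute_residues(
        substr(src[[s]], starts[[i]] + 1L, starts[[i]] + li),
        config$error_rate)
    }
  })
  lens_actual <- nchar(reads)
  prov <- data.frame(source = names(src)[which_src], start = starts,
                     end = starts + lens_actual)
  db <- peptide_db(reads, provenance = prov)
  truth <- structure(
    list(sources = src,
         intervals = setNames(lapply(names(src), function(nm)
           data.frame(source = nm, start = 0L, end = nchar(src[[nm]]))),
           names(src)),
         mode = "planted", min_sampled_fraction = 0.6),
    class = c("ground_truth", "pepgrasp_obj"))
  list(db = db, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
format.ground_truth <- function(x, ...) {
  sprintf("<ground_truth (%s): %d sources, %d queries with intervals>",
          x$mode, length(x$sources), length(x$intervals))
}

#' Define homolog intervals for a query by alignment against the sources
#'
#' The alternative to planted intervals: local alignment of the query against
#' every source (Biostrings, same matrix and gap model), keeping aligned
#' source spans whose bit score clears `min_bits`.  The resulting truth
#' object records `mode = "aligned"`.
#'
#' @param query amino-acid string.
#' @param query_id identifier to register the intervals under.
#' @param truth a ground-truth scaffold from [simulate_reads()].
#' @param matrix a [scoring_matrix()].
#' @param min_bits bit-score threshold for accepting a source span.
#' @param stats a [scoring_stats()] for the bit conversion.
#' @return the updated ground-truth object.
#' @export
homolog_intervals_align <- function(query, query_id, truth,
                                    matrix = blosum62(), min_bits = 35,
                                    stats = scoring_stats(nchar(query), 1e6)) {
  sub <- matrix$scores
  iv <- lapply(names(truth$sources), function(nm) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(truth$sources[[nm]]),
      substitutionMatrix = sub, gapOpening = matrix$gap_open,
      gapExtension = matrix$gap_extend, type = "local")
    if (bit_score(Biostrings::score(al), stats) < min_bits) return(NULL)
    rng <- al@subject@range
    data.frame(source = nm, start = BiocGenerics::start(rng) - 1L,
               end = BiocGenerics::end(rng))
  })
  iv <- do.call(rbind, iv[!vapply(iv, is.null, NA)])
  if (is.null(iv)) iv <- data.frame(source = character(0), start = integer(0),
                                    end = integer(0))
  truth$intervals[[query_id]] <- iv
  truth$mode <- "aligned"
  truth
}

#' Ground-truth homolog reads of a query
#'
#' Exactly the reads with strictly more than `min_sampled_fraction` (60 %)
#' of their residues sampled from the query's homolog intervals.
#'
#' @param query query id with registered intervals in `truth`.
#' @param truth ground-truth object from [simulate_reads()] (optionally
#'   extended by [homolog_intervals_align()]).
#' @param db the simulated [peptide_db()] (must carry provenance).
#' @return character vector of read ids.
#' @export
truth_homolog_reads <- function(query, truth, db) {
  stopifnot(inherits(truth, "ground_truth"), inherits(db, "peptide_db"))
  iv <- truth$intervals[[query]]
  if (is.null(iv)) stop("no homolog intervals registered for query: ", query)
  prov <- db$provenance
  if (is.null(prov)) stop("database has no provenance")
  frac <- numeric(nrow(prov))
  for (j in seq_len(nrow(iv))) {
    same <- prov$source == iv$source[[j]]
    ov <- pmax(0L, pmin(prov$end, iv$end[[j]]) - pmax(prov$start, iv$start[[j]]))
    frac[same] <- frac[same] + ov[same] / (prov$end - prov$start)[same]
  }
  db$ids[frac > truth$min_sampled_fraction]
}
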