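# Banded Needleman-Wunsch with affine gaps (Rcpp backend).

#' Banded global alignment with affine gaps
#'
#' Global Needleman-Wunsch restricted to the diagonal band
#' `|i - j - shift| <= band` (i = query position, j = target position).  A
#' gap of length g costs `gap_open + g * gap_extend`.  Whenever
#' `band >= max(nchar(query_segment), nchar(target))` the result equals the
#' unbanded global optimum; an unreachable end cell (band too narrow for the
#' length difference) yields `-Inf`.
#'
#' @param query_segment,target amino-acid strings.
#' @param matrix a [scoring_matrix()].
#' @param band band half-width (>= 1).
#' @param shift diagonal offset of the band (default 0, the main diagonal).
#' @return list with `score` (raw), `q_end` (last query row of the optimum)
#'   and `best` (best in-band cell value, for drop-off bookkeeping).
#' @export
banded_align <- function(query_segment, target, matrix = blosum62(),
                         band = 40L, shift = 0L) {
  stopifnot(inherits(matrix, "scoring_matrix"), band >= 1L)
  cpp_banded_align(query_segment, target, matrix$scores,
                   paste(rownames(matrix$scores), collapse = ""),
                   matrix$gap_open, matrix$gap_extend,
                   as.integer(band), as.integer(shift), FALSE)
}

# glocal variant used during contig extension and re-scoring: the contig
# (target) is fully aligned, leading/trailing unaligned query-window residues
# are free; returns the raw score of the best full-contig placement
glocal_align <- function(query_window, target, matrix, band, shift) {
  cpp_banded_align(query_window, target, matrix$scores,
                   paste(rownames(matrix$scores), collapse = ""),
                   matrix$gap_open, matrix$gap_extend,
                   as.integer(band), as.integer(shift), TRUE)
}

# score a contig against the query given its nominal query start; the query
# window is the nominal span widened by the band and clamped at query ends
score_contig <- function(seq, ns, query, matrix, band) {
  qlen <- nchar(query)
  ws <- max(0L, ns - band)
  we <- min(qlen, ns + nchar(seq) + band)
  if (we <= ws) return(-Inf)
  win <- substr(query, ws + 1L, we)
  glocal_align(win, seq, matrix, band, shift = ns - ws)$score
}
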