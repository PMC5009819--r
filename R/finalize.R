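# Recalibration (greedy re-merging of locally assembled contig pieces with
# re-scoring) and post-mapping (recruiting constituent reads onto final
# contigs), producing the homolog read set.

# merge chains: shift the second chain and drop duplicated (read, offset) rows
merge_chains <- function(chain_a, chain_b, shift) {
  chain_b$offset <- chain_b$offset + shift
  out <- rbind(chain_a, chain_b)
  out <- out[!duplicated(out[c("read", "offset")]), , drop = FALSE]
  out <- out[order(out$offset, out$read), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# can contig b be absorbed into contig a (b's sequence occurs inside a's at a
# band-compatible diagonal)?  Returns the 0-based position in a, or -1L.
absorb_pos <- function(a, b, band) {
  la <- nchar(a$sequence); lb <- nchar(b$sequence)
  if (la < lb) return(-1L)
  hits <- gregexpr(b$sequence, a$sequence, fixed = TRUE)[[1]]
  if (hits[[1]] == -1L) return(-1L)
  pos <- hits - 1L
  diagdiff <- abs(a$ns + pos - b$ns)
  j <- which(diagdiff <= band)
  if (length(j) == 0L) return(-1L)
  pos[j][which.min(diagdiff[j])]
}

# absorb any contig whose sequence occurs inside another at a band-compatible
# diagonal; returns the reduced contig list (longest survivor keeps the
# absorbed chains)
absorb_contained <- function(contigs, band) {
  n <- length(contigs)
  if (n <= 1L) return(contigs)
  lens <- vapply(contigs, function(x) nchar(x$sequence), 0L)
  ord <- order(-lens, seq_len(n))  # hosts scanned longest-first
  alive <- rep(TRUE, n)
  for (b in rev(ord)) {            # shortest candidates absorbed first
    for (a in ord) {
      if (a == b || !alive[[a]] || !alive[[b]]) next
      if (lens[[a]] < lens[[b]] || (lens[[a]] == lens[[b]] && a >= b)) next
      pos <- absorb_pos(contigs[[a]], contigs[[b]], band)
      if (pos < 0L) next
      contigs[[a]]$chain <- merge_chains(contigs[[a]]$chain,
                                         contigs[[b]]$chain, pos)
      alive[[b]] <- FALSE
      break
    }
  }
  contigs[alive]
}

# longest exact suffix(a)/prefix(b) overlap >= min_ov at a band-compatible
# diagonal, located via occurrences of b's min_ov-prefix inside a
max_suffix_prefix <- function(a, b, min_ov, band) {
  la <- nchar(a$sequence); lb <- nchar(b$sequence)
  upper <- min(la, lb) - 1L
  if (upper < min_ov) return(0L)
  hits <- gregexpr(substr(b$sequence, 1L, min_ov), a$sequence,
                   fixed = TRUE)[[1]]
  if (hits[[1]] == -1L) return(0L)
  ovs <- la - hits + 1L
  ovs <- ovs[ovs >= min_ov & ovs <= upper &
               abs(a$ns + la - ovs - b$ns) <= band]
  for (ov in sort(ovs, decreasing = TRUE)) {
    if (substr(a$sequence, la - ov + 1L, la) == substr(b$sequence, 1L, ov))
      return(ov)
  }
  0L
}

#' Recalibrate a contig list by greedy overlap merging and re-scoring
#'
#' Local assembly breaks long homologous contigs into depth-capped pieces;
#' recalibration repairs them by repeatedly merging the pair of contigs with
#' the longest exact suffix/prefix sequence overlap (at least
#' `min_merge_overlap` residues and band-compatible query diagonals, to
#' prevent chimeric merges between paralog hits) until no such pair remains.
#' Contigs contained in a longer contig are absorbed.  Merged contigs are
#' re-scored against the query by banded glocal alignment and receive fresh
#' bit scores and E-values; finally contigs failing `evalue_cutoff` (or
#' shorter than the seed length) are dropped.
#'
#' @param contigs output of [search_query()].
#' @param query amino-acid string.
#' @param matrix a [scoring_matrix()].
#' @param stats a [scoring_stats()] (defaults to the attribute carried by
#'   `contigs`).
#' @param params a [grasp_params()] (`min_merge_overlap`, `band`,
#'   `evalue_cutoff`, `k`).
#' @param merge logical; `FALSE` skips merging/absorption (direct-alignment
#'   mode) and only applies re-scoring and the E-value filter.
#' @return contig list (same element shape as the input), ordered by
#'   descending bit score; attribute `merge_log` records the overlap length
#'   of every merge in execution order.
#' @export
recalibrate <- function(contigs, query, matrix = blosum62(),
                        stats = attr(contigs, "stats"),
                        params = grasp_params(), merge = TRUE) {
  if (is.null(stats)) stats <- scoring_stats(nchar(query), 1e6,
                                             params$lambda, params$K)
  band <- params$band
  min_ov <- params$min_merge_overlap
  merge_log <- integer(0)
  if (merge && length(contigs) > 1L) {
    contigs <- absorb_contained(contigs, band)
    n <- length(contigs)
    ov_mat <- matrix(0L, n, n)  # cached best overlap per ordered pair
    for (a in seq_len(n)) for (b in seq_len(n)) if (a != b)
      ov_mat[a, b] <- max_suffix_prefix(contigs[[a]], contigs[[b]],
                                        min_ov, band)
    while (length(contigs) > 1L && max(ov_mat) > 0L) {
      hit <- which(ov_mat == max(ov_mat), arr.ind = TRUE)
      hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
      a <- contigs[[hit[[1L]]]]; b <- contigs[[hit[[2L]]]]
      ov <- ov_mat[hit[[1L]], hit[[2L]]]
      shift <- nchar(a$sequence) - ov
      seq <- paste0(a$sequence,
                    substr(b$sequence, ov + 1L, nchar(b$sequence)))
      raw <- score_contig(seq, a$ns, query, matrix, band)
      merged <- new_contig(seq, merge_chains(a$chain, b$chain, shift),
                           a$ns, raw, query, stats, a$seed)
      merge_log <- c(merge_log, ov)
      drop <- c(hit[[1L]], hit[[2L]])
      contigs <- contigs[-drop]
      ov_mat <- ov_mat[-drop, -drop, drop = FALSE]
      # absorb contigs now contained in the merged one, then splice it in
      absorbed <- logical(length(contigs))
      for (i in seq_along(contigs)) {
        pos <- absorb_pos(merged, contigs[[i]], band)
        if (pos >= 0L) {
          merged$chain <- merge_chains(merged$chain, contigs[[i]]$chain, pos)
          absorbed[[i]] <- TRUE
        }
      }
      contigs <- contigs[!absorbed]
      ov_mat <- ov_mat[!absorbed, !absorbed, drop = FALSE]
      m <- length(contigs) + 1L
      ov_new <- matrix(0L, m, m)
      if (m > 1L) ov_new[-m, -m] <- ov_mat
      contigs[[m]] <- merged
      for (i in seq_len(m - 1L)) {
        ov_new[i, m] <- max_suffix_prefix(contigs[[i]], merged, min_ov, band)
        ov_new[m, i] <- max_suffix_prefix(merged, contigs[[i]], min_ov, band)
      }
      ov_mat <- ov_new
    }
  }
  # fresh alignment score and statistics for every surviving contig
  contigs <- lapply(contigs, function(ct) {
    raw <- score_contig(ct$sequence, ct$ns, query, matrix, band)
    new_contig(ct$sequence, ct$chain, ct$ns, raw, query, stats, ct$seed)
  })
  keep <- vapply(contigs, function(ct)
    ct$evalue <= params$evalue_cutoff && nchar(ct$sequence) >= params$k, NA)
  contigs <- contigs[keep]
  o <- order(-vapply(contigs, `[[`, 0, "bits"),
             vapply(contigs, `[[`, "", "sequence"))
  contigs <- contigs[o]
  attr(contigs, "stats") <- stats
  attr(contigs, "merge_log") <- merge_log
  contigs
}

#' Assemble a final contig set for one query
#'
#' @param contigs recalibrated contig list.
#' @param query_id query identifier.
#' @param fingerprint database/parameter fingerprint string.
#' @return an object of class `contig_set`.
#' @export
contig_set <- function(contigs, query_id = "query", fingerprint = "") {
  structure(list(contigs = contigs, query_id = query_id,
                 fingerprint = fingerprint),
            class = c("contig_set", "pepgrasp_obj"))
}

#' @export
format.contig_set <- function(x, ...) {
  sprintf("<contig_set %s: %d contigs>", x$query_id, length(x$contigs))
}

#' Post-map database reads onto final contigs
#'
#' Assigns a read to a contig when some ungapped sliding placement aligns at
#' least `min_fraction` of the read's residues (default 60 %) within the
#' contig with at most `max_substitutions` mismatches (default 3) and no
#' gaps.  All qualifying (read, contig) pairs are reported with the read's
#' best placement; reads collapsed during index deduplication are naturally
#' restored because every database read is scanned.
#'
#' @param db a [peptide_db()].
#' @param contigs a [contig_set()] or a plain contig list.
#' @param min_fraction minimum aligned fraction of the read length.
#' @param max_substitutions maximum substitution count.
#' @return data.frame (`read_id`, `contig`, `offset`, `aligned`, `fraction`,
#'   `substitutions`), with `offset` the 0-based contig position of the read
#'   start (negative when the read overhangs the contig start).
#' @export
post_map <- function(db, contigs, min_fraction = 0.6, max_substitutions = 3L) {
  stopifnot(inherits(db, "peptide_db"))
  cts <- if (inherits(contigs, "contig_set")) contigs$contigs else contigs
  if (length(cts) == 0L)
    return(data.frame(read_id = character(0), contig = integer(0),
                      offset = integer(0), aligned = integer(0),
                      fraction = numeric(0), substitutions = integer(0)))
  seqs <- vapply(cts, `[[`, "", "sequence")
  hits <- cpp_postmap(db$reads, seqs, min_fraction,
                      as.integer(max_substitutions))
  data.frame(read_id = db$ids[hits$read], contig = hits$contig,
             offset = hits$offset, aligned = hits$aligned,
             fraction = hits$fraction, substitutions = hits$substitutions)
}

#' Collect the homolog read set from post-mapping assignments
#'
#' The union over all contigs of their assigned reads; these reads inherit
#' the query's annotation.
#'
#' @param assignments output of [post_map()].
#' @return character vector of unique read ids (sorted).
#' @export
collect_homologs <- function(assignments) {
  sort(unique(assignments$read_id))
}

#' Verify that a contig is spelled by its read chain
#'
#' Checks that every chained read matches the contig sequence exactly at its
#' recorded offset, that consecutive reads agree on their recorded overlaps,
#' and that the chain covers the whole contig.
#'
#' @param contig a contig (element of a [search_query()] result).
#' @param db the [peptide_db()] it was assembled from.
#' @return `TRUE` (invisibly); errors otherwise.
#' @export
check_contig_chain <- function(contig, db) {
  ch <- contig$chain
  stopifnot(nrow(ch) >= 1L)
  for (j in seq_len(nrow(ch))) {
    rd <- db$reads[[ch$read[[j]]]]
    sub <- substr(contig$sequence, ch$offset[[j]] + 1L,
                  ch$offset[[j]] + nchar(rd))
    if (sub != rd)
      stop("chain read ", j, " does not spell the contig at offset ",
           ch$offset[[j]])
  }
  ends <- ch$offset + db$lens[ch$read]
  if (min(ch$offset) != 0L || max(ends) != nchar(contig$sequence))
    stop("chain does not span the contig")
  o <- order(ch$offset)
  if (any(ch$offset[o][-1L] > cummax(ends[o])[-nrow(ch)]))
    stop("chain has a coverage gap")
  invisible(TRUE)
}
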