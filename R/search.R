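# The simultaneous alignment-and-assembly core: seed identification and
# link-guided contig extension with banded DP, bit-score drop-off pruning and
# the local-assembly depth cap.

#' Search parameter set
#'
#' Defaults are the engine's standard configuration: 6-mer seeds in the
#' 10-group reduced alphabet accepted when the full-alphabet seed score is at
#' least `k * 0.7 * a` (`a` = mean diagonal of the scoring matrix, so 24.36
#' for BLOSUM62), minimum link overlap 10 aa, local-assembly depth 20 per
#' direction, band 40, 25-bit drop-off, BLOSUM62 with gap penalties 11/1 and
#' the standard gapped Karlin-Altschul constants.
#'
#' @param k seed length.
#' @param seed_factor per-residue fraction of `a` in the seed score rule.
#' @param band alignment band half-width.
#' @param dropoff_bits X-drop pruning threshold in bits (`Inf` disables).
#' @param max_depth maximum link traversals per direction (0 = direct
#'   alignment, the single-read special case).
#' @param evalue_cutoff final contig E-value cutoff.
#' @param min_overlap minimum link overlap (residues).
#' @param max_links link fan-out cap.
#' @param min_merge_overlap minimum exact overlap for recalibration merging.
#' @param postmap_min_fraction minimum aligned fraction of read length for
#'   post-mapping.
#' @param postmap_max_sub maximum substitutions for post-mapping.
#' @param lambda,K Karlin-Altschul parameters.
#' @return an object of class `grasp_params`.
#' @export
grasp_params <- function(k = 6L, seed_factor = 0.7, band = 40L,
                         dropoff_bits = 25, max_depth = 20L,
                         evalue_cutoff = 10, min_overlap = 10L,
                         max_links = 20L, min_merge_overlap = 10L,
                         postmap_min_fraction = 0.6, postmap_max_sub = 3L,
                         lambda = 0.267, K = 0.041) {
  p <- list(k = as.integer(k), seed_factor = seed_factor,
            band = as.integer(band), dropoff_bits = dropoff_bits,
            max_depth = as.integer(max_depth), evalue_cutoff = evalue_cutoff,
            min_overlap = as.integer(min_overlap), max_links = max_links,
            min_merge_overlap = as.integer(min_merge_overlap),
            postmap_min_fraction = postmap_min_fraction,
            postmap_max_sub = as.integer(postmap_max_sub),
            lambda = lambda, K = K)
  num <- unlist(p[c("k", "seed_factor", "band", "max_links", "lambda", "K",
                    "min_overlap", "min_merge_overlap")])
  if (any(num <= 0)) stop("all numeric search parameters must be positive")
  if (p$max_depth < 0L || p$dropoff_bits <= 0) stop("invalid search parameters")
  structure(p, class = c("grasp_params", "pepgrasp_obj"))
}

#' @export
format.grasp_params <- function(x, ...) {
  sprintf("<grasp_params k=%d factor=%.2f band=%d dropoff=%g bits depth=%d>",
          x$k, x$seed_factor, x$band, x$dropoff_bits, x$max_depth)
}

new_counters <- function() {
  as.environment(list(seeds = 0L, seeds_visited = 0L, extensions = 0L,
                      pruned_dropoff = 0L, capped_depth = 0L))
}

#' Identify seed pairs between a query and the database
#'
#' Exact k-mer matches in the reduced-alphabet space whose full-alphabet
#' substitution score is at least `k * seed_factor * a` (e.g. a `WWWWWW`
#' self-match scores 66 and passes the BLOSUM62 threshold 24.36 while
#' `AAAAAA` scores 24 and is rejected).
#'
#' @param query amino-acid string.
#' @param seed_index a [build_seed_index()] result.
#' @param matrix a [scoring_matrix()].
#' @param params a [grasp_params()].
#' @return data.frame (`query_pos`, `read`, `read_pos`, `score`) with 0-based
#'   positions, ordered by (query_pos, read, read_pos).
#' @export
find_seeds <- function(query, seed_index, matrix = blosum62(),
                       params = grasp_params()) {
  stopifnot(inherits(seed_index, "seed_index"))
  k <- seed_index$k
  empty <- data.frame(query_pos = integer(0), read = integer(0),
                      read_pos = integer(0), score = numeric(0))
  if (nchar(query) < k) {
    warning("query shorter than the seed length k = ", k)
    return(empty)
  }
  red <- reduce_sequence(query, seed_index$alphabet)
  nwin <- nchar(query) - k + 1L
  qpos <- 0:(nwin - 1L)
  kmers <- substring(red, qpos + 1L, qpos + k)
  ok <- !grepl("#", kmers, fixed = TRUE)
  hits_q <- integer(0); hits_row <- integer(0)
  for (i in which(ok)) {
    rows <- seed_index$table[[kmers[[i]]]]
    if (!is.null(rows)) {
      hits_q <- c(hits_q, rep(qpos[[i]], length(rows)))
      hits_row <- c(hits_row, rows)
    }
  }
  if (length(hits_q) == 0L) return(empty)
  reads <- seed_index$occ$read[hits_row]
  rpos <- seed_index$occ$pos[hits_row]
  # full-alphabet k-mer score, vectorized via paired character indexing
  qk <- substring(query, hits_q + 1L, hits_q + k)
  tk <- substring(seed_index$reads[reads], rpos + 1L, rpos + k)
  qc <- matrix(unlist(strsplit(qk, "")), nrow = k)
  tc <- matrix(unlist(strsplit(tk, "")), nrow = k)
  sc <- colSums(matrix(matrix$scores[cbind(as.vector(qc), as.vector(tc))],
                       nrow = k))
  thr <- seed_score_threshold(matrix, k, params$seed_factor)
  keep <- sc >= thr
  out <- data.frame(query_pos = hits_q[keep], read = reads[keep],
                    read_pos = rpos[keep], score = sc[keep])
  out <- out[order(out$query_pos, out$read, out$read_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_contig <- function(seq, chain, ns, raw, query, stats, seed) {
  bits <- bit_score(raw, stats)
  list(sequence = seq, chain = chain, ns = ns,
       query_start = max(0L, ns),
       query_end = min(nchar(query), ns + nchar(seq)),
       raw = raw, bits = bits, evalue = e_value(bits, stats), seed = seed)
}

#' Extend one seed pair into contigs via the extension links
#'
#' The seed read is the initial contig; right extension follows the right
#' links from the last chained read, then each right result is extended left
#' from its first chained read.  After every link traversal the grown contig
#' is re-scored by banded glocal alignment against the query window implied
#' by the seed diagonal.  A branch is pruned when its bit score falls more
#' than `dropoff_bits` below the best score on its path since the seed
#' (X-drop), and each direction stops after `max_depth` traversals.  Each
#' surviving path reports its best-scoring state (trim-back).
#'
#' @param seed one row of [find_seeds()] output (list or data.frame row).
#' @param query amino-acid string.
#' @param db a [peptide_db()].
#' @param links_right,links_left [build_extension_links()] tables.
#' @param matrix a [scoring_matrix()].
#' @param stats a [scoring_stats()].
#' @param params a [grasp_params()].
#' @param counters optional environment collecting audit counters.
#' @return list of contigs (each with `sequence`, `chain`, `query_start`,
#'   `query_end`, `raw`, `bits`, `evalue`, `seed`), deduplicated and ordered
#'   by descending raw score then sequence.
#' @export
extend_seed <- function(seed, query, db, links_right, links_left,
                        matrix = blosum62(),
                        stats = scoring_stats(nchar(query), db_residues(db)),
                        params = grasp_params(), counters = new_counters()) {
  band <- params$band
  drop_raw <- if (is.finite(params$dropoff_bits))
    dropoff_raw(params$dropoff_bits, stats) else Inf
  ns0 <- as.integer(seed$query_pos - seed$read_pos)
  r0 <- as.integer(seed$read)
  seq0 <- db$reads[[r0]]
  chain0 <- data.frame(read = r0, offset = 0L, overlap = NA_integer_)
  raw0 <- score_contig(seq0, ns0, query, matrix, band)
  state0 <- list(seq = seq0, chain = chain0, ns = ns0, raw = raw0)
  seed_info <- list(query_pos = as.integer(seed$query_pos), read = r0,
                    read_pos = as.integer(seed$read_pos))

  dfs <- function(state, depth, best, links, side, acc) {
    from <- if (side == "right") state$chain$read[[nrow(state$chain)]]
            else state$chain$read[[1L]]
    sinks <- links_for(links, from)
    expanded <- FALSE
    if (!is.null(sinks) && nrow(sinks) > 0L) {
      if (depth >= params$max_depth) {
        counters$capped_depth <- counters$capped_depth + 1L
      } else {
        for (i in seq_len(nrow(sinks))) {
          t <- sinks$sink[[i]]; ov <- sinks$overlap[[i]]
          counters$extensions <- counters$extensions + 1L
          if (side == "right") {
            ext <- substr(db$reads[[t]], ov + 1L, db$lens[[t]])
            nseq <- paste0(state$seq, ext)
            nns <- state$ns
            nchain <- rbind(state$chain,
                            data.frame(read = t,
                                       offset = nchar(state$seq) - ov,
                                       overlap = ov))
          } else {
            ext <- substr(db$reads[[t]], 1L, db$lens[[t]] - ov)
            nseq <- paste0(ext, state$seq)
            nns <- state$ns - nchar(ext)
            shifted <- state$chain
            shifted$offset <- shifted$offset + nchar(ext)
            nchain <- rbind(data.frame(read = t, offset = 0L, overlap = ov),
                            shifted)
          }
          nraw <- score_contig(nseq, nns, query, matrix, band)
          if (best$raw - nraw > drop_raw) {
            counters$pruned_dropoff <- counters$pruned_dropoff + 1L
            next
          }
          nstate <- list(seq = nseq, chain = nchain, ns = nns, raw = nraw)
          nbest <- if (nraw > best$raw) list(raw = nraw, state = nstate)
                   else best
          acc <- dfs(nstate, depth + 1L, nbest, links, side, acc)
          expanded <- TRUE
        }
      }
    }
    if (!expanded) acc[[length(acc) + 1L]] <- best$state
    acc
  }

  dedup_states <- function(states) {
    if (length(states) <= 1L) return(states)
    key <- vapply(states, function(s) paste0(s$ns, "|", s$seq), "")
    raws <- vapply(states, `[[`, 0, "raw")
    o <- order(key, -raws)
    states <- states[o][!duplicated(key[o])]
    states
  }

  right <- dedup_states(dfs(state0, 0L, list(raw = raw0, state = state0),
                            links_right, "right", list()))
  final <- list()
  for (st in right) {
    final <- c(final, dfs(st, 0L, list(raw = st$raw, state = st),
                          links_left, "left", list()))
  }
  final <- dedup_states(final)
  out <- lapply(final, function(s)
    new_contig(s$seq, s$chain, s$ns, s$raw, query, stats, seed_info))
  o <- order(-vapply(out, `[[`, 0, "raw"),
             vapply(out, `[[`, "", "sequence"))
  out[o]
}

#' Search one query against an indexed database (pre-recalibration)
#'
#' Runs seeding and seed extension over all accepted seeds, suppressing
#' duplicate extensions with a per-query visited set keyed by
#' (read, nominal query start).  Results are deterministic (descending bit
#' score, then contig sequence) and independent of worker count.
#'
#' @param query amino-acid string.
#' @param index a [build_index()] result.
#' @param params a [grasp_params()]; must be compatible with the index
#'   fingerprint (k, min_overlap, max_links, matrix).
#' @param matrix a [scoring_matrix()].
#' @param stats a [scoring_stats()]; defaults to the query/database sizes
#'   with the parameter-set constants.
#' @param counters optional audit-counter environment.
#' @return list of contigs with attributes `stats` and `counters`.
#' @export
search_query <- function(query, index, params = grasp_params(),
                         matrix = blosum62(),
                         stats = scoring_stats(nchar(query),
                                               db_residues(index$db),
                                               params$lambda, params$K),
                         counters = new_counters()) {
  stopifnot(inherits(index, "grasp_index"))
  ip <- index$params
  if (ip$k != params$k || ip$min_overlap != params$min_overlap ||
      !identical(as.numeric(ip$max_links), as.numeric(params$max_links)) ||
      !identical(ip$matrix, matrix$name))
    stop("parameter/index fingerprint mismatch: index was built with ",
         index$fingerprint)
  seeds <- find_seeds_indexed(query, index, matrix, params)
  counters$seeds <- counters$seeds + nrow(seeds)
  visited <- new.env(parent = emptyenv())
  contigs <- list()
  for (i in seq_len(nrow(seeds))) {
    sd <- seeds[i, ]
    key <- paste0(sd$read, "|", sd$query_pos - sd$read_pos)
    if (!is.null(visited[[key]])) {
      counters$seeds_visited <- counters$seeds_visited + 1L
      next
    }
    res <- extend_seed(sd, query, index$db, index$links_right,
                       index$links_left, matrix, stats, params, counters)
    for (ct in res) {
      for (j in seq_len(nrow(ct$chain))) {
        kj <- paste0(ct$chain$read[[j]], "|", ct$ns + ct$chain$offset[[j]])
        visited[[kj]] <- TRUE
      }
    }
    contigs <- c(contigs, res)
  }
  # global dedup (different seeds can settle on the same assembled state)
  if (length(contigs) > 1L) {
    key <- vapply(contigs, function(s) paste0(s$ns, "|", s$sequence), "")
    raws <- vapply(contigs, `[[`, 0, "raw")
    o <- order(key, -raws)
    contigs <- contigs[o][!duplicated(key[o])]
  }
  o <- order(-vapply(contigs, `[[`, 0, "bits"),
             vapply(contigs, `[[`, "", "sequence"),
             vapply(contigs, `[[`, 0L, "ns"))
  contigs <- contigs[o]
  attr(contigs, "stats") <- stats
  attr(contigs, "counters") <- as.list(counters)
  contigs
}

find_seeds_indexed <- function(query, index, matrix, params) {
  find_seeds(query, index$seeds, matrix, params)
}

#' Summarize a contig list as a data.frame
#'
#' @param contigs output of [search_query()] or [recalibrate()].
#' @return data.frame with one row per contig (`sequence`, `length`,
#'   `n_reads`, `query_start`, `query_end`, `raw`, `bits`, `evalue`).
#' @export
contigs_to_df <- function(contigs) {
  if (length(contigs) == 0L)
    return(data.frame(sequence = character(0), length = integer(0),
                      n_reads = integer(0), query_start = integer(0),
                      query_end = integer(0), raw = numeric(0),
                      bits = numeric(0), evalue = numeric(0)))
  data.frame(
    sequence = vapply(contigs, `[[`, "", "sequence"),
    length = vapply(contigs, function(x) nchar(x$sequence), 0L),
    n_reads = vapply(contigs, function(x) nrow(x$chain), 0L),
    query_start = vapply(contigs, `[[`, 0L, "query_start"),
    query_end = vapply(contigs, `[[`, 0L, "query_end"),
    raw = vapply(contigs, `[[`, 0, "raw"),
    bits = vapply(contigs, `[[`, 0, "bits"),
    evalue = vapply(contigs, `[[`, 0, "evalue"))
}
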