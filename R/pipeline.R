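# End-to-end orchestration: index -> search -> recalibrate -> post-map ->
# evaluate, with deterministic result files.

params_fingerprint <- function(index, params) {
  paste0(index$fingerprint,
         ";seed_factor=", params$seed_factor, ";band=", params$band,
         ";dropoff_bits=", params$dropoff_bits, ";max_depth=", params$max_depth,
         ";evalue_cutoff=", params$evalue_cutoff,
         ";min_merge_overlap=", params$min_merge_overlap,
         ";postmap=", params$postmap_min_fraction, "/", params$postmap_max_sub,
         ";lambda=", params$lambda, ";K=", params$K)
}

safe_id <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Run the full search pipeline
#'
#' Builds (or reuses) the index, searches every query, recalibrates, filters
#' at the E-value cutoff, post-maps reads onto the final contigs, collects
#' the homolog read set, and — when ground truth is supplied — evaluates
#' recall/precision/AUC.  Outputs are deterministic: identical inputs and
#' configuration give byte-identical result files regardless of the worker
#' count.  When `params$max_depth == 0` the engine is in direct-alignment
#' mode (every reported item is a single read) and recalibration merging is
#' disabled so the single-read contract holds end to end.
#'
#' @param queries named character vector of query proteins, or a FASTA path.
#' @param db a [peptide_db()] or a FASTA path.
#' @param out_dir output directory (created); `NULL` skips file output.
#' @param params a [grasp_params()].
#' @param matrix a [scoring_matrix()].
#' @param alphabet a [reduced_alphabet()] (used when the index is built here).
#' @param index optional pre-built [build_index()] result or a [save_index()]
#'   directory; built from `db` when missing.
#' @param truth optional ground-truth object from [simulate_reads()]; every
#'   query id must have registered homolog intervals.
#' @param cutoffs ascending E-value cutoffs for the evaluation curve.
#' @param workers number of parallel workers (per-query parallelism; results
#'   are independent of this setting).
#' @return (invisibly) list with `results` (per query: `contigs`,
#'   `assignments`, `homologs`, `metrics`, `counters`), `index`, `files`.
#' @export
run_pipeline <- function(queries, db, out_dir = NULL,
                         params = grasp_params(), matrix = blosum62(),
                         alphabet = reduced_alphabet(), index = NULL,
                         truth = NULL, cutoffs = default_cutoffs(),
                         workers = 1L) {
  if (is.character(queries) && length(queries) == 1L && file.exists(queries))
    queries <- read_queries(queries)
  if (is.null(names(queries)))
    names(queries) <- sprintf("query_%d", seq_along(queries))
  if (is.character(db) && length(db) == 1L) db <- read_peptide_db(db)
  if (is.null(index)) {
    index <- build_index(db, matrix = matrix, alphabet = alphabet,
                         k = params$k, min_overlap = params$min_overlap,
                         max_links = params$max_links)
  } else if (is.character(index)) {
    index <- load_index(index)
  }
  stopifnot(inherits(index, "grasp_index"))
  fp <- params_fingerprint(index, params)
  do_merge <- params$max_depth > 0L

  run_one <- function(qid) {
    query <- queries[[qid]]
    counters <- new_counters()
    raw <- search_query(query, index, params, matrix, counters = counters)
    final <- recalibrate(raw, query, matrix, attr(raw, "stats"), params,
                         merge = do_merge)
    cset <- contig_set(final, query_id = qid, fingerprint = fp)
    assignments <- post_map(index$db, cset, params$postmap_min_fraction,
                            params$postmap_max_sub)
    metrics <- NULL
    if (!is.null(truth)) {
      tset <- truth_homolog_reads(qid, truth, index$db)
      metrics <- evaluate_search(assignments, cset, tset, cutoffs)
    }
    list(contigs = cset, assignments = assignments,
         homologs = collect_homologs(assignments), metrics = metrics,
         counters = as.list(counters))
  }

  qids <- names(queries)
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    setNames(parallel::mclapply(qids, run_one, mc.cores = workers,
                                mc.preschedule = TRUE), qids)
  } else {
    setNames(lapply(qids, run_one), qids)
  }
  for (r in results) if (inherits(r, "try-error")) stop(r)

  files <- NULL
  if (!is.null(out_dir)) files <- write_results(results, out_dir, fp, truth)
  invisible(list(results = results, index = index, files = files))
}

write_results <- function(results, out_dir, fingerprint, truth) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  files$fingerprint <- file.path(out_dir, "fingerprint.txt")
  writeLines(fingerprint, files$fingerprint)

  # contigs FASTA: id | query | bits | E-value in the header
  seqs <- character(0)
  for (qid in names(results)) {
    cts <- results[[qid]]$contigs$contigs
    if (length(cts) == 0L) next
    nm <- sprintf("%s|contig_%d query=%s bits=%.2f evalue=%.3g reads=%d",
                  safe_id(qid), seq_along(cts), qid,
                  vapply(cts, `[[`, 0, "bits"),
                  vapply(cts, `[[`, 0, "evalue"),
                  vapply(cts, function(x) nrow(x$chain), 0L))
    seqs <- c(seqs, setNames(vapply(cts, `[[`, "", "sequence"), nm))
  }
  files$contigs <- file.path(out_dir, "contigs.fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), files$contigs)

  files$assignments <- file.path(out_dir, "assignments.tsv")
  con <- file(files$assignments, "w")
  writeLines(paste0("# fingerprint: ", fingerprint), con)
  writeLines(paste("query_id", "read_id", "contig_id", "offset", "aligned",
                   "fraction", "substitutions", sep = "\t"), con)
  for (qid in names(results)) {
    a <- results[[qid]]$assignments
    if (nrow(a) > 0L)
      writeLines(sprintf("%s\t%s\t%s|contig_%d\t%d\t%d\t%.4f\t%d",
                         qid, a$read_id, safe_id(qid), a$contig, a$offset,
                         a$aligned, a$fraction, a$substitutions), con)
  }
  close(con)

  for (qid in names(results)) {
    f <- file.path(out_dir, sprintf("homologs_%s.txt", safe_id(qid)))
    writeLines(results[[qid]]$homologs, f)
    files[[paste0("homologs_", qid)]] <- f
  }

  if (!is.null(truth)) {
    metrics <- lapply(results, function(r) {
      m <- r$metrics
      list(counts = m$counts[c("tp", "fp", "fn", "recall", "precision",
                               "f_measure")],
           auc = m$curve$auc, points = m$curve$points)
    })
    files$metrics <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(metrics, files$metrics, auto_unbox = TRUE,
                         digits = NA)
  }
  files
}
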