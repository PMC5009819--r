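# Recalibration merging and post-mapping.

mk_contig <- function(seq, ns, query, stats, reads = NULL) {
  # a synthetic single-piece contig whose chain is one pseudo-read
  m <- blosum62()
  structure(list(sequence = seq,
                 chain = data.frame(read = reads %||% 1L, offset = 0L,
                                    overlap = NA_integer_),
                 ns = ns, query_start = max(0L, ns),
                 query_end = min(nchar(query), ns + nchar(seq)),
                 raw = 0, bits = 0, evalue = 0,
                 seed = list(query_pos = ns, read = 1L, read_pos = 0L)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("disjoint contigs pass through recalibration unchanged", {
  set.seed(83)
  query <- rand_prot(100)
  st <- scoring_stats(100, 1e4)
  a <- mk_contig(substr(query, 1, 30), 0L, query, st)
  b <- mk_contig(substr(query, 61, 100), 60L, query, st, reads = 2L)
  out <- recalibrate(list(a, b), query, stats = st)
  expect_length(out, 2L)
  expect_setequal(vapply(out, `[[`, "", "sequence"),
                  c(a$sequence, b$sequence))
  expect_length(attr(out, "merge_log"), 0L)
})

test_that("overlapping pieces merge and are re-scored like the oracle", {
  set.seed(89)
  m <- blosum62()
  query <- rand_prot(50)
  st <- scoring_stats(50, 1e4)
  a <- mk_contig(substr(query, 1, 30), 0L, query, st)
  b <- mk_contig(substr(query, 21, 50), 20L, query, st, reads = 2L)
  out <- recalibrate(list(a, b), query, stats = st)
  expect_length(out, 1L)
  expect_equal(out[[1]]$sequence, query)
  expect_equal(attr(out, "merge_log"), 10L)
  # merged raw score equals the full-NW oracle of contig vs query
  expect_equal(out[[1]]$raw, nw_affine_full(query, query, m))
  expect_equal(out[[1]]$evalue, e_value(bit_score(out[[1]]$raw, st), st))
})

test_that("greedy merging follows descending overlap length", {
  set.seed(97)
  query <- rand_prot(90)
  st <- scoring_stats(90, 1e4)
  # overlaps: a/b = 15, b/c = 12; after merging a+b the a+b/c overlap is 12
  a <- mk_contig(substr(query, 1, 40), 0L, query, st, reads = 1L)
  b <- mk_contig(substr(query, 26, 65), 25L, query, st, reads = 2L)
  c <- mk_contig(substr(query, 54, 90), 53L, query, st, reads = 3L)
  out <- recalibrate(list(c, a, b), query, stats = st)
  expect_length(out, 1L)
  expect_equal(out[[1]]$sequence, query)
  expect_equal(attr(out, "merge_log"), c(15L, 12L))
})

test_that("band-incompatible overlaps are not merged (paralog guard)", {
  set.seed(101)
  seg <- rand_prot(20)
  query <- paste0(seg, rand_prot(150), seg, rand_prot(20))
  st <- scoring_stats(nchar(query), 1e4)
  # two contigs ending/starting with the same 20-mer but from query positions
  # ~170 apart: exact overlap exists, diagonals are incompatible
  a <- mk_contig(paste0(rand_prot(15), seg), 0L, query, st, reads = 1L)
  b <- mk_contig(paste0(seg, rand_prot(15)), 170L, query, st, reads = 2L)
  out <- recalibrate(list(a, b), query, stats = st,
                     params = grasp_params(evalue_cutoff = Inf))
  expect_length(out, 2L)
})

test_that("post-mapping boundary cases follow the printed rule exactly", {
  set.seed(103)
  contig <- rand_prot(200)
  cs <- contig_set(list(list(sequence = contig)), "q")
  flip <- function(s, i) {
    alt <- setdiff(AA_STANDARD, substr(s, i, i))[[1]]
    paste0(substr(s, 1, i - 1), alt, substr(s, i + 1, nchar(s)))
  }
  # exact substring: assigned with fraction 1, substitutions 0
  r_exact <- substr(contig, 21, 60)
  # 3 vs 4 substitutions on a fully aligned read
  r_sub3 <- flip(flip(flip(r_exact, 5), 15), 25)
  r_sub4 <- flip(r_sub3, 35)
  # 100-residue read overhanging the contig start: 60 aligned / 59 aligned
  r_60 <- paste0(rand_prot(40), substr(contig, 1, 60))
  r_59 <- paste0(rand_prot(41), substr(contig, 1, 59))
  db <- peptide_db(c(r_exact, r_sub3, r_sub4, r_60, r_59),
                   ids = c("exact", "sub3", "sub4", "f60", "f59"))
  asn <- post_map(db, cs)
  expect_setequal(asn$read_id, c("exact", "sub3", "f60"))
  expect_equal(asn$fraction[asn$read_id == "exact"], 1.0)
  expect_equal(asn$substitutions[asn$read_id == "exact"], 0L)
  expect_equal(asn$substitutions[asn$read_id == "sub3"], 3L)
  expect_equal(asn$fraction[asn$read_id == "f60"], 0.6)
  expect_equal(asn$offset[asn$read_id == "f60"], -40L)
})

test_that("post-mapping agrees with the exhaustive sliding-window oracle", {
  set.seed(107)
  contigs <- replicate(2, rand_prot(60))
  cs <- contig_set(lapply(contigs, function(s) list(sequence = s)), "q")
  # reads: noisy copies of contig windows plus unrelated reads
  reads <- character(0)
  for (i in 1:10) {
    src <- sample(2, 1)
    st <- sample(40, 1)
    r <- substr(contigs[[src]], st, st + 19)
    nerr <- sample(0:5, 1)
    for (e in seq_len(nerr)) {
      p <- sample(20, 1)
      r <- paste0(substr(r, 1, p - 1), sample(AA_STANDARD, 1),
                  substr(r, p + 1, 20))
    }
    reads <- c(reads, r)
  }
  reads <- c(reads, replicate(5, rand_prot(20)))
  db <- peptide_db(reads)
  asn <- post_map(db, cs)
  for (i in seq_along(reads)) {
    for (j in seq_along(contigs)) {
      oracle <- brute_postmap_hits(reads[[i]], contigs[[j]])
      row <- asn[asn$read_id == db$ids[[i]] & asn$contig == j, ]
      if (nrow(oracle) == 0L) {
        expect_equal(nrow(row), 0L)
      } else {
        # soundness + completeness: reported best placement is a qualifying
        # oracle placement with the maximal aligned length
        expect_equal(nrow(row), 1L)
        expect_true(any(oracle$offset == row$offset &
                          oracle$aligned == row$aligned &
                          oracle$substitutions == row$substitutions))
        expect_equal(row$aligned, max(oracle$aligned))
      }
    }
  }
})

test_that("collect_homologs is a deduplicated union", {
  expect_identical(collect_homologs(data.frame(read_id = character(0))),
                   character(0))
  asn <- data.frame(read_id = c("r2", "r1", "r2"), contig = c(1L, 1L, 2L))
  expect_identical(collect_homologs(asn), c("r1", "r2"))
  expect_length(collect_homologs(asn), length(unique(asn$read_id)))
})

test_that("error-free self-search reaches the single-contig fixpoint", {
  set.seed(109)
  prot <- rand_prot(300)
  db <- tiled_db(prot)
  idx <- build_index(db)
  res <- search_query(prot, idx)
  fin <- recalibrate(res, prot, stats = attr(res, "stats"))
  expect_length(fin, 1L)
  expect_equal(fin[[1]]$sequence, prot)
  check_contig_chain(fin[[1]], db)
  # recalibration never decreased the best bit score
  expect_gte(max(vapply(fin, `[[`, 0, "bits")),
             max(vapply(res, `[[`, 0, "bits")))
  # post-mapping assigns every fragment
  asn <- post_map(db, contig_set(fin, "prot"))
  expect_setequal(unique(asn$read_id), db$ids)
})
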