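# Seeding, link-guided extension, drop-off, depth cap, and search-level
# determinism.

test_that("seed rule accepts WWWWWW (66) and rejects AAAAAA (24)", {
  m <- blosum62()
  ab <- reduced_alphabet()
  dbW <- peptide_db("WWWWWW")
  sW <- find_seeds("WWWWWW", build_seed_index(dbW, ab), m)
  expect_equal(nrow(sW), 1L)
  expect_equal(sW$score, 66)      # 6 x 11, above 24.36
  dbA <- peptide_db("AAAAAA")
  sA <- find_seeds("AAAAAA", build_seed_index(dbA, ab), m)
  expect_equal(nrow(sA), 0L)      # 6 x 4 = 24 < 24.36 despite exact identity
})

test_that("short queries and empty matches give empty seed lists", {
  ab <- reduced_alphabet()
  si <- build_seed_index(peptide_db("ACDEFGHIKL"), ab)
  expect_warning(res <- find_seeds("ACD", si), "shorter")
  expect_equal(nrow(res), 0L)
  # no shared k-mers
  expect_equal(nrow(find_seeds("WWWWWWWWWW", si)), 0L)
})

test_that("seeds are exactly the reduced k-mer matches above threshold", {
  set.seed(47)
  m <- blosum62()
  ab <- reduced_alphabet()
  db <- rand_db(15, c(10L, 25L))
  query <- rand_prot(60)
  si <- build_seed_index(db, ab)
  got <- find_seeds(query, si, m)
  # brute-force re-derivation
  redq <- reduce_sequence(query, ab)
  redr <- reduce_sequence(db$reads, ab)
  expected <- 0L
  for (qp in 0:(nchar(query) - 6L)) {
    for (r in seq_along(db$reads)) {
      if (db$lens[[r]] < 6L) next
      for (rp in 0:(db$lens[[r]] - 6L)) {
        if (substr(redq, qp + 1L, qp + 6L) !=
            substr(redr[[r]], rp + 1L, rp + 6L)) next
        qc <- strsplit(substr(query, qp + 1L, qp + 6L), "")[[1]]
        tc <- strsplit(substr(db$reads[[r]], rp + 1L, rp + 6L), "")[[1]]
        sc <- sum(m$scores[cbind(qc, tc)])
        if (sc >= 24.36) {
          expected <- expected + 1L
          expect_true(any(got$query_pos == qp & got$read == r &
                            got$read_pos == rp & got$score == sc))
        }
      }
    }
  }
  expect_equal(nrow(got), expected)
})

test_that("a seed read without links yields the single-read contig", {
  set.seed(53)
  query <- rand_prot(40)
  db <- peptide_db(substr(query, 11, 30))
  idx <- build_index(db)
  res <- search_query(query, idx)
  expect_gte(length(res), 1L)
  expect_equal(res[[1]]$sequence, db$reads[[1]])
  expect_equal(nrow(res[[1]]$chain), 1L)
  expect_equal(res[[1]]$query_start, 10L)
  expect_equal(res[[1]]$query_end, 30L)
  check_contig_chain(res[[1]], db)
})

test_that("tiled error-free fragments assemble substrings of the query", {
  set.seed(59)
  query <- rand_prot(120)
  db <- tiled_db(query)
  idx <- build_index(db)
  res <- search_query(query, idx)
  expect_gt(length(res), 0L)
  for (ct in res) {
    expect_true(grepl(ct$sequence, query, fixed = TRUE))
    check_contig_chain(ct, db)
    # depth cap: chain never exceeds 1 + 2 * max_depth reads
    expect_lte(nrow(ct$chain), 1L + 2L * 20L)
    # extension reached the depth cap or the query end
    expect_true(nrow(ct$chain) == 41L ||
                  ct$query_start == 0L || ct$query_end == 120L ||
                  nchar(ct$sequence) >= 15L + 20L * 5L)
  }
})

test_that("max_depth = 0 reduces to single-read alignments", {
  set.seed(61)
  query <- rand_prot(100)
  db <- tiled_db(query)
  idx <- build_index(db)
  res <- search_query(query, idx, grasp_params(max_depth = 0L))
  expect_gt(length(res), 0L)
  expect_true(all(vapply(res, function(ct) nrow(ct$chain), 0L) == 1L))
})

test_that("depth cap bounds the read chain", {
  set.seed(67)
  query <- rand_prot(200)
  db <- tiled_db(query)
  idx <- build_index(db)
  res <- search_query(query, idx, grasp_params(max_depth = 2L))
  expect_true(all(vapply(res, function(ct) nrow(ct$chain), 0L) <= 5L))
})

# Adversarial branch: a chain of junk reads hanging off a genuine hit.  The
# query uses one residue subset, the junk another, so junk aligns only as
# gaps and the path's bit score decays until the X-drop fires.  The genuine
# read's junk-facing overlap is an A-run (self-seed score 24 < 24.36), so the
# hybrid read can never seed on its own and every junk traversal starts from
# the genuine seed.
junk_branch_fixture <- function() {
  qa <- c("D", "E", "G", "K", "N", "Q", "R", "S", "T")
  ja <- c("W", "F", "Y", "H", "M", "C")
  set.seed(71)
  r1 <- paste0(rand_prot(10, qa), strrep("A", 10))
  query <- paste0(rand_prot(20, qa), r1, rand_prot(20, qa))
  junk <- rand_prot(70, ja)
  jreads <- c(paste0(strrep("A", 10), substr(junk, 1, 20)),
              substring(junk, seq(11, 51, by = 10),
                        seq(30, 70, by = 10)))
  db <- peptide_db(c(r1, jreads))
  list(query = query, db = db, idx = build_index(db))
}

test_that("drop-off prunes divergent branches without changing reported contigs", {
  fx <- junk_branch_fixture()
  c_on <- new_counters_list <- NULL
  p_on <- grasp_params(dropoff_bits = 25)
  p_off <- grasp_params(dropoff_bits = Inf)
  res_on <- search_query(fx$query, fx$idx, p_on)
  res_off <- search_query(fx$query, fx$idx, p_off)
  # junk-extended states are never the best state, so outputs agree...
  expect_identical(contigs_to_df(res_on), contigs_to_df(res_off))
  expect_false(any(grepl("W", vapply(res_on, `[[`, "", "sequence"))))
  # ...but pruning is observable in the audit counters
  expect_gt(attr(res_on, "counters")$pruned_dropoff, 0L)
  expect_equal(attr(res_off, "counters")$pruned_dropoff, 0L)
  expect_gt(attr(res_off, "counters")$extensions,
            attr(res_on, "counters")$extensions)
})

test_that("lowering dropoff_bits never adds contigs", {
  fx <- junk_branch_fixture()
  keys <- function(res) vapply(res, function(ct)
    paste0(ct$ns, "|", ct$sequence), "")
  k_small <- keys(search_query(fx$query, fx$idx, grasp_params(dropoff_bits = 5)))
  k_mid <- keys(search_query(fx$query, fx$idx, grasp_params(dropoff_bits = 25)))
  k_big <- keys(search_query(fx$query, fx$idx, grasp_params(dropoff_bits = Inf)))
  expect_true(all(k_small %in% k_mid))
  expect_true(all(k_mid %in% k_big))
})

test_that("search rejects an incompatible index", {
  set.seed(73)
  db <- rand_db(5, c(12L, 20L))
  idx <- build_index(db, k = 5L)
  expect_error(search_query(rand_prot(30), idx, grasp_params(k = 6L)),
               "fingerprint mismatch")
})

test_that("empty database/seed situations give empty results", {
  set.seed(79)
  db <- peptide_db("WWWWWWWWWWWW")
  idx <- build_index(db)
  expect_length(search_query(rand_prot(30, c("A", "D", "E")), idx), 0L)
})
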