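# Peptide database, suffix/LCP arrays, extension links, seed index, and the
# on-disk index bundle.

test_that("peptide_db validates input and computes offsets", {
  db <- peptide_db(c("AC", "CDE"))
  expect_equal(db$offsets, c(0L, 3L))
  expect_equal(nchar(db$text), sum(db$lens) + 2L)
  expect_equal(db_residues(db), 5L)
  expect_error(peptide_db(character(0)))
  expect_error(peptide_db(c("AC", "")), "length")
  expect_error(peptide_db("AC1"), "invalid")
  expect_error(peptide_db(c("AC", "CD"), ids = c("a", "a")), "unique")
})

test_that("suffix order of a single read is lexicographic", {
  db <- peptide_db("AC")
  si <- build_suffix_index(db)
  # text "AC<sent>": suffixes sorted with sentinel lowest
  sufs <- substring(db$text, si$sa + 1L, nchar(db$text))
  expect_identical(sufs, sort(sufs, method = "radix"))
})

test_that("suffix array and LCP match brute force on random databases", {
  set.seed(101)
  for (trial in 1:20) {
    db <- rand_db(sample(2:6, 1), c(5L, 20L))
    si <- build_suffix_index(db)
    oracle <- brute_suffix_index(db$text)
    expect_identical(si$sa, oracle$sa)
    expect_identical(si$lcp, oracle$lcp)
  }
})

test_that("unique right-MES from overlapping reads of one protein", {
  set.seed(7)
  prot <- rand_prot(20)
  db <- peptide_db(c(substr(prot, 1, 15), substr(prot, 6, 20)))
  lr <- build_extension_links(db, min_overlap = 10L)
  expect_equal(lr$links, data.frame(src = 1L, sink = 2L, overlap = 10L))
  # mirrored in the left direction
  ll <- build_extension_links(db, min_overlap = 10L, direction = "left")
  expect_equal(ll$links, data.frame(src = 2L, sink = 1L, overlap = 10L))
  # single-read database has no links
  expect_equal(nrow(build_extension_links(peptide_db("ACDEFGHIKLMNP"))$links),
               0L)
})

test_that("fan-out cap keeps 20 longest-overlap links deterministically", {
  set.seed(11)
  src <- rand_prot(30)
  tails <- replicate(25, rand_prot(12))
  sinks <- paste0(substr(src, 21, 30), tails)  # 25 sinks, overlap 10 each
  db <- peptide_db(c(src, sinks))
  lr <- build_extension_links(db, min_overlap = 10L, max_links = 20L)
  mine <- lr$links[lr$links$src == 1L, ]
  expect_equal(nrow(mine), 20L)
  # equal overlaps: ties broken by ascending read index
  expect_equal(mine$sink, 2:21)
  expect_true(all(mine$overlap == 10L))
  # untruncated table keeps all 25
  lr_inf <- build_extension_links(db, min_overlap = 10L, max_links = Inf)
  expect_equal(nrow(lr_inf$links[lr_inf$links$src == 1L, ]), 25L)
})

test_that("brute_force_mes handles trivial and duplicate cases", {
  db <- rand_db(4, c(10L, 12L))
  set.seed(3)
  lone <- peptide_db(c(rand_prot(20), rand_prot(20)))
  expect_equal(nrow(brute_force_mes(1, lone, 10L)), 0L)
  # two identical reads: collapsed, no mutual links
  dup <- peptide_db(c("ACDEFGHIKLMN", "ACDEFGHIKLMN"))
  expect_equal(nrow(brute_force_mes(1, dup, 10L)), 0L)
  expect_equal(nrow(brute_force_mes(2, dup, 10L)), 0L)
  # read id lookup works
  expect_identical(brute_force_mes("read_1", dup, 10L),
                   brute_force_mes(1, dup, 10L))
})

test_that("extension links equal the brute-force MES oracle (spot check)", {
  set.seed(23)
  for (trial in 1:10) {
    db <- rand_db(sample(5:12, 1), c(12L, 25L))
    si <- build_suffix_index(db)
    for (dir in c("right", "left")) {
      built <- build_extension_links(db, si, min_overlap = 8L,
                                     max_links = Inf, direction = dir)
      for (s in seq_along(db$reads)) {
        mine <- built$links[built$links$src == s, c("sink", "overlap")]
        rownames(mine) <- NULL
        oracle <- brute_force_mes(s, db, 8L, dir)
        expect_equal(mine, oracle)
      }
    }
  }
})

test_that("seed index records every k-window exactly once", {
  ab <- reduced_alphabet()
  # read shorter than k contributes nothing
  db1 <- peptide_db(c("ACD"))
  expect_equal(nrow(build_seed_index(db1, ab, k = 6L)$occ), 0L)
  # read of length k contributes exactly one entry
  db2 <- peptide_db(c("ACDEFG"))
  si2 <- build_seed_index(db2, ab, k = 6L)
  expect_equal(si2$occ, data.frame(read = 1L, pos = 0L))
  # total occurrences = sum over reads of max(0, len - k + 1)
  set.seed(5)
  db <- rand_db(20, c(4L, 30L))
  si <- build_seed_index(db, ab, k = 6L)
  expect_equal(nrow(si$occ), sum(pmax(0L, db$lens - 6L + 1L)))
  # every occurrence's reduced k-mer equals its key
  red <- reduce_sequence(db$reads, ab)
  for (km in head(names(si$table), 25)) {
    rows <- si$table[[km]]
    expect_true(all(substring(red[si$occ$read[rows]],
                              si$occ$pos[rows] + 1L,
                              si$occ$pos[rows] + 6L) == km))
  }
})

test_that("index save/load round-trips and detects corruption", {
  set.seed(9)
  db <- rand_db(30, c(12L, 30L))
  idx <- build_index(db)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_index(idx, d1)
  idx2 <- load_index(d1)
  expect_identical(idx2$db$reads, idx$db$reads)
  expect_identical(idx2$suffix$sa, idx$suffix$sa)
  expect_identical(idx2$links_right$links, idx$links_right$links)
  expect_identical(idx2$links_left$links, idx$links_left$links)
  expect_identical(idx2$seeds$table, idx$seeds$table)
  expect_identical(idx2$fingerprint, idx$fingerprint)
  # byte-identical re-serialization
  save_index(idx2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f), warn = FALSE),
                     readLines(file.path(d1, f), warn = FALSE))
  }
  # truncated artifact -> corrupt-file error
  con <- file.path(d1, "suffix.json")
  txt <- readLines(con, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 40), con)
  expect_error(load_index(d1), "corrupt|mismatch")
  # version mismatch
  save_index(idx, d1)
  meta <- jsonlite::read_json(file.path(d1, "meta.json"))
  meta$format_version <- "999"
  jsonlite::write_json(meta, file.path(d1, "meta.json"), auto_unbox = TRUE)
  expect_error(load_index(d1), "version mismatch")
})

test_that("round-trip preserves provenance", {
  db <- peptide_db(c("ACDEFGHIKL", "MNPQRSTVWY"),
                   provenance = data.frame(source = c("s1", "s2"),
                                           start = c(0L, 5L),
                                           end = c(10L, 15L)))
  idx <- build_index(db)
  d <- withr::local_tempdir()
  save_index(idx, d)
  expect_equal(load_index(d)$db$provenance, db$provenance)
})
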