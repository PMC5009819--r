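# Independent oracles and fixture builders.  These deliberately avoid the
# package's own code paths: full-matrix DP instead of the banded C++ kernel,
# substring sorting instead of the suffix-array builder, interval scans
# instead of the provenance helpers.

rand_prot <- function(n, alphabet = AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_db <- function(n_reads, len_range = c(15L, 40L)) {
  lens <- sample(seq(len_range[[1]], len_range[[2]]), n_reads, replace = TRUE)
  peptide_db(vapply(lens, rand_prot, ""))
}

# full (unbanded) global Needleman-Wunsch with affine gaps; gap of length g
# costs open + g*ext.  Quadratic reference implementation.
nw_affine_full <- function(q, t, matrix, open = matrix$gap_open,
                           ext = matrix$gap_extend) {
  sub <- matrix$scores
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  NEG <- -1e9
  D <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in target (consumes query)
  F_ <- matrix(NEG, m + 1, n + 1) # gap in query (consumes target)
  D[1, 1] <- 0
  if (m > 0) for (i in 2:(m + 1)) {
    E[i, 1] <- -(open + (i - 1) * ext)
    D[i, 1] <- E[i, 1]
  }
  if (n > 0) for (j in 2:(n + 1)) {
    F_[1, j] <- -(open + (j - 1) * ext)
    D[1, j] <- F_[1, j]
  }
  if (m > 0 && n > 0) for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(D[i - 1, j] - open - ext, E[i - 1, j] - ext)
    F_[i, j] <- max(D[i, j - 1] - open - ext, F_[i, j - 1] - ext)
    D[i, j] <- max(D[i - 1, j - 1] + sub[qc[i - 1], tc[j - 1]],
                   E[i, j], F_[i, j])
  }
  D[m + 1, n + 1]
}

# brute-force suffix array + LCP by direct substring comparison
brute_suffix_index <- function(text) {
  n <- nchar(text)
  sufs <- substring(text, 1:n, n)
  o <- order(sufs, method = "radix")  # byte order; sentinel sorts lowest
  lcp <- integer(n)
  for (i in seq_len(n)[-1]) {
    a <- sufs[[o[[i - 1]]]]; b <- sufs[[o[[i]]]]
    l <- 0L
    while (l < nchar(a) && l < nchar(b) &&
           substr(a, l + 1L, l + 1L) == substr(b, l + 1L, l + 1L)) l <- l + 1L
    lcp[[i]] <- l
  }
  list(sa = o - 1L, lcp = lcp)
}

# exhaustive ungapped post-mapping oracle: every (read, contig, offset)
# placement, the printed 60 %/3-substitution rule applied directly
brute_postmap_hits <- function(read, contig, min_fraction = 0.6,
                               max_sub = 3L) {
  lr <- nchar(read); lc <- nchar(contig)
  minaln <- ceiling(min_fraction * lr - 1e-9)
  hits <- list()
  for (d in seq(-(lr - 1L), lc - 1L)) {
    r0 <- max(0L, -d); c0 <- max(0L, d)
    L <- min(lr - r0, lc - c0)
    if (L < minaln) next
    rs <- strsplit(substr(read, r0 + 1L, r0 + L), "")[[1]]
    cs <- strsplit(substr(contig, c0 + 1L, c0 + L), "")[[1]]
    s <- sum(rs != cs)
    if (s <= max_sub)
      hits[[length(hits) + 1L]] <- data.frame(offset = d, aligned = L,
                                              substitutions = s)
  }
  if (length(hits) == 0L)
    data.frame(offset = integer(0), aligned = integer(0),
               substitutions = integer(0))
  else do.call(rbind, hits)
}

# tiled error-free fragment database of a protein (length 15, step 5)
tiled_db <- function(protein, len = 15L, step = 5L) {
  starts <- seq(1L, nchar(protein) - len + 1L, by = step)
  peptide_db(substring(protein, starts, starts + len - 1L))
}

# independently coded trapezoid integration of a recall/precision curve,
# summed over the precision decrements
trapezoid_auc_oracle <- function(recall, precision) {
  total <- 0
  for (k in seq_len(length(recall) - 1L)) {
    total <- total +
      (recall[[k + 1L]] + recall[[k]]) *
      (precision[[k]] - precision[[k + 1L]]) / 2
  }
  total
}
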