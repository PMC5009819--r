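---
title: "pepgrasp: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepgrasp: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Short-read metagenome sequencing followed by gene calling yields databases
of short peptides (typically 20–40 aa). `pepgrasp` solves the *gene-centric
assembly* problem: given a query protein $q$ and a read set $R$, find
contigs $P$ such that each $p \in P$ aligns to $q$ above an E-value
threshold and is an assembly of reads $R^p \subseteq R$. The homolog read
set is $\bigcup_{p \in P} R^p$. Assembling while aligning lets
low-similarity reads be carried by their high-similarity neighbours, which
is where the recall advantage over direct per-read alignment comes from;
direct alignment is the degenerate case $|R^p| = 1$ (exposed as
`max_depth = 0`).

The engine assumes: (i) peptides are given (gene calling is out of scope);
(ii) homology is detectable through exact reduced-alphabet 6-mers somewhere
in the homologous region; (iii) read overlaps of ≥ 10 exact residues are
meaningful assembly evidence; (iv) the substitution model of the scoring
matrix (BLOSUM62 by default) describes residue-level variation.

## Stages and the tunable parameters

| parameter | default | role |
|---|---|---|
| `k` | 6 | seed length (residues, reduced alphabet) |
| `seed_factor` | 0.7 | seed acceptance: full-alphabet score ≥ `k·factor·a`; `a` = mean matrix diagonal (5.8 for BLOSUM62, threshold 24.36) |
| `min_overlap` | 10 aa | minimum exact suffix/prefix overlap for extension links |
| `max_links` | 20 | link fan-out cap per read and direction |
| `max_depth` | 20 | link traversals per direction before local assembly stops |
| `band` | 40 | half-width of the Needleman–Wunsch band |
| `dropoff_bits` | 25 | X-drop pruning threshold |
| `gap_open`/`gap_extend` | 11 / 1 | affine gap magnitudes; a gap of length $g$ costs $11 + g$ |
| `lambda`, `K` | 0.267, 0.041 | Karlin–Altschul constants (standard NCBI gapped BLOSUM62 values) |
| `evalue_cutoff` | 10 | final contig filter, applied after recalibration |
| `min_merge_overlap` | 10 aa | recalibration merge threshold (kept equal to `min_overlap`: the merge should not accept weaker overlap evidence than the assembly itself) |
| postmap rule | 0.6 / 3 | a read is recruited when ≥ 60 % of its length aligns ungapped with ≤ 3 substitutions |

Bit scores are $(\lambda\,\mathrm{raw} - \ln K)/\ln 2$ and E-values
$m\,n\,2^{-\mathrm{bits}}$ with $m$ the query length and $n$ the **total
database residues** — fixed per database, so E-values are comparable across
contigs of one search. No finite-size (edge-effect) correction is applied.

## The index

Reads are concatenated with a sentinel that sorts below every residue. A
suffix array is built by comparison sort (sentinels keep comparisons near
read length), the LCP array by Kasai's algorithm. Extension links are found
by walking the suffix-array neighbourhood of every read suffix of length
≥ `min_overlap`: read starts sharing a common prefix of that length are
sinks, and the maximal overlap per (source, sink) pair is kept. A sink
survives if it is a *maximal extension sequence*: its extension (the part
beyond the overlap) is not contained in any other candidate's extension as
a substring. Ties between identical extensions resolve toward the longer
overlap, then the smaller read index; fan-out truncation keeps the longest
overlaps first, ties by ascending read index — all deterministic, so
re-indexing reproduces identical tables. Left links are derived from a
second suffix array on residue-reversed reads.

Exact duplicate reads and reads fully contained in a longer read are
excluded from link construction (the representative with the smallest index
stays); post-mapping scans *all* reads, so collapsed duplicates are restored
in the homolog set. A read is never its own sink: tandem-repeat
self-extension of one short peptide is degenerate and is excluded in both
the construction and the brute-force oracle, keeping the equivalence test
well defined.

## Extension scoring: a deliberate choice

After each link traversal the *whole* grown contig is re-aligned to a query
window (the contig's nominal span widened by the band and clamped at the
query ends) with a banded affine-gap DP in which the contig is aligned
end-to-end while leading/trailing *query-window* residues are free
("glocal"). Global-in-contig matters: garbage picked up by extension keeps
its penalty and drives the X-drop. The exported `banded_align()` is the
plain global variant and reproduces full Needleman–Wunsch whenever the band
covers the length difference; an end cell outside the band yields `-Inf`.

Drop-off is measured against the best score *on the current path since the
seed* (BLAST X-drop semantics), converted to raw units as
$\mathrm{bits}\cdot\ln 2/\lambda$. Every surviving path reports its
best-scoring state, trimmed back BLAST-style — not the terminal state. One
observable consequence: a divergent branch never appears in output whether
or not drop-off is enabled (it is never the best state); pruning is instead
visible in the audit counters (`pruned_dropoff`, `extensions`), and the
guaranteed property is monotonicity — lowering `dropoff_bits` never adds
contigs.

Within one query, a visited set keyed by (read, nominal query start)
suppresses re-extension of already-assembled regions. This replaces the
original engine's cross-thread shared read pool with per-query state; it is
a documented substitute, not a claim about the original implementation.

## Recalibration and post-mapping

Local assembly caps extension depth, deliberately breaking long homologs
into pieces; recalibration repairs them by repeatedly merging the pair with
the longest exact suffix/prefix overlap (≥ `min_merge_overlap`), requiring
band-compatible query diagonals so paralog hits sharing a motif are not
chimerically joined. Contigs contained in a longer contig at a compatible
diagonal are absorbed (their read chains are kept). Merged and surviving
contigs are re-scored from scratch; the E-value filter runs after
recalibration. With `max_depth = 0` the pipeline also disables merging:
direct-alignment mode promises single-read items end to end, and merging
would silently re-assemble them.

Post-mapping is ungapped by design — the recruitment rule counts
substitutions only, and an $O(nm)$ sliding scan is exactly
brute-forceable, which the test suite exploits. The minimum aligned length
is `ceil(0.6 · read length)` computed with an epsilon-guarded ceiling so
binary representation cannot flip the boundary (60 % aligns, 59 % does
not). A read may map to several contigs; its E-value for evaluation is the
minimum over them.

## The simulator: what a green test does and does not establish

`simulate_reads()` draws `round(coverage · total residues / read length)`
reads; sources are chosen with probability ∝ abundance weight × length,
start positions uniformly, and substitutions i.i.d. per residue (uniform
over the 19 alternatives). Defaults state the emulated world: 10× coverage,
33-aa reads (≈ 100 bp translated), 1 % substitutions. Provenance (source,
0-based half-open interval) is recorded exactly; the ground-truth homolog
set of a query is the reads with **strictly** more than 60 % of their
residues sampled from the query's homolog intervals. In the default
"planted" mode those intervals are whole source spans; an "aligned" mode
derives them by local alignment against the sources instead (used when the
query is not itself a source).

Deliberate simplifications: no indels (matching the post-mapping model), no
nucleotide stage, no gene-caller artefacts (frameshifts, truncations,
miscalls), fixed read length by default (geometric jitter behind a flag),
and no attempt to reproduce any particular published community profile —
abundance weights are free parameters. A green planted-homolog test
therefore establishes that the engine recovers substitution-perturbed
fragments of a known protein at the stated coverage; it does not establish
performance on real gene-called peptides, on indel-rich data, or across
genuine evolutionary distance.

## Numerical and tie-break conventions

- Coordinates are 0-based, half-open everywhere; the sentinel is a single
  reserved character below every residue.
- Seeds are ordered (query position, read, read position); contigs
  (descending bits, then sequence, then query start); links (source,
  descending overlap, sink). Every stage is deterministic and independent
  of the worker count — parallelism is per-query and purely an
  optimisation.
- The wildcard `X` scores 0 against everything, reduces to a dedicated
  letter, and any k-mer window touching it is excluded from seeding;
  all-wildcard sequences are rejected as unalignable input.
- Zero-denominator recall/precision are reported as 0 with an `undefined`
  flag, keeping evaluation curves total.
- The AUC is the precision-decrement trapezoid
  $\sum_k (r_{k+1}+r_k)(p_k-p_{k+1})/2$ over ascending E-value cutoffs —
  *not* the classical ROC integral. A curve with constant precision has
  AUC 0; no deduplication of identical points is performed.

## Open design points, resolved

- **Reduced alphabet.** The 10-group table used by the original tool is not
  printed in the available material, so the shipped default is the standard
  Murphy–Wallqvist–Levy BLOSUM50-derived 10-letter clustering
  (LVIM, C, A, G, ST, P, FYW, EDNQ, KR, H), which serves the same purpose —
  conservative-substitution-tolerant seeding — and is verifiable offline.
  It is exposed in configuration (`reduced_alphabet()`), accepts custom
  tables, and `"gbmr10"` is accepted as an alias for the shipped default.
- **Karlin–Altschul constants** are not printed either; the standard NCBI
  gapped BLOSUM62(11,1) values are used and overridable.
- **Re-seeding inside assembled contigs**: suppressed via the visited set
  (above); whether the original suppresses them identically is unknown.

## Known limitations

- The suffix array is comparison-sorted: fine for the intended
  10⁴–10⁶-residue in-memory databases, not for 10⁸-residue ones (no
  streaming or compressed index).
- Contig counts can be inflated by near-duplicate error variants that
  cannot exact-merge; they are harmless to the homolog set (post-mapping
  unions) but make `contigs.fasta` verbose.
- Translated nucleotide queries, profile queries, gapped post-mapping, and
  composition-adjusted statistics are out of scope.
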