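Package: pepgrasp
Title: Simultaneous Alignment and Assembly Homology Search of Short-Peptide Databases
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-centric assembly homology search for metagenomic short-peptide
    read databases. Given a query protein, assembles homologous contigs directly
    from a database of short peptide reads via a pre-built extension-link index
    (suffix array + LCP), reduced amino-acid alphabet k-mer seeding, banded
    Needleman-Wunsch extension with BLAST-style bit-score drop-off pruning,
    depth-capped local assembly with greedy recalibration, and a post-mapping
    step that recruits constituent reads onto final contigs. Ships a peptide
    read simulator with per-read provenance for ground-truth evaluation, and
    precision/recall/AUC metrics across E-value cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
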