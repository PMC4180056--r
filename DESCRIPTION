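Package: novasm
Title: Novel Sequence Discovery in De Novo Genome Assemblies
Version: 0.1.0
Authors@R: person("novasm", "maintainers", email = "novasm@example.org", role = c("aut", "cre"))
Description: A three-phase seed-and-chain aligner for locating novel
    sequences, i.e. regions of a de novo whole-genome assembly that are
    absent from a reference genome. Phase one builds per-chromosome k-mer
    hash indexes; phase two assigns each contig or scaffold a candidate
    chromosome and orientation using gapped (non-consecutive) seeds,
    maximal unique match chaining, anchor-distance pruning and a Gaussian
    outlier test over per-target alignment scores; phase three re-aligns
    each query at full seed density, extends matches by direct base
    comparison and reports the final unaligned regions as novel-sequence
    candidates. Post-filters subtract homology evidence parsed from BLAST
    tabular output and repeat annotations parsed from RepeatMasker output,
    screen for contaminant sequence, and a percentile-sorted overlap
    viewer renders candidate comparisons. A seeded simulator generates
    reference genomes and derived assemblies with known ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    IRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
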