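Package: polyamap
Title: Mapping mRNA Polyadenylation Sites and Profiling Signal Motifs and
    Base-Composition Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps poly(A)-tailed transcript sequences to a reference genome by
    exact matching of the 100-nucleotide anchor upstream of the poly(A) tail,
    collapses the matches into unique polyadenylation sites, and characterizes
    the 201-nucleotide region around each site: per-position base-frequency
    matrices and sequence-logo information content, base-abundance peak
    detection (the U-A-U-A-U pattern), windowed k-mer motif tables and
    per-position motif location profiles, whole-genome k-mer baselines and
    enrichment ratios, and 3'UTR lengths from an open-reading-frame rule that
    admits negative lengths when the stop codon overlaps the tail. Includes a
    synthetic pre-mRNA generator with planted signal motifs, positional
    composition templates, transcript redundancy, and an internal-priming
    artifact channel, so that every pipeline stage has a parameter-recovery
    test without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    graphics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
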