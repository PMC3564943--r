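Package: pasScout
Title: Discovery of Unannotated 3' Gene Ends from Conservation and
    Transcriptional Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies putative cleavage and polyadenylation sites (PAS)
    that are missing from reference gene annotations. EST 3' extremes are
    clustered into potential mature transcript extremes (PTEs) and scored
    with a Conservation Drop Index (CDI), the difference in mean per-base
    conservation between the terminal window of the mature transcript and
    a window just downstream. Orthologous transcript models projected onto
    the same genome propose 3'UTR extensions that are scored with a
    Coverage Difference (CD) statistic from RNA-seq depth, and putative
    sites are assessed with an empirical cross-database false discovery
    rate curve. A seeded synthetic-scenario generator produces complete
    truth-labelled inputs (annotation, conservation track, ESTs, ortholog
    models, coverage) for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
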