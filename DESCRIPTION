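Package: backsplicer
Title: Seed-Anchored Annotation and Quantification of Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for annotating and quantifying circular RNAs (circRNAs)
    from backsplice-junction evidence. Candidate junctions reported by
    multiple upstream detection pipelines are merged and re-annotated
    against an exon model, junction-centred circular and linear reference
    windows are built from the genome, and junction-spanning reads are
    counted with a seed-anchored exact-match rule plus genome/transcriptome
    exclusion filtering. Candidates are classified as bona fide circRNAs by
    their RNase R resistance: the normalized treated/mock ratio is compared
    with an empirical-quantile threshold derived from the linear splice
    junctions of the host genes. A synthetic-data generator (toy genome,
    planted circles and decoys, mock and RNase R libraries) supports
    desk-scale validation of every stage, and helpers export count matrices
    for external differential-expression testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
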