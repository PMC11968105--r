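Package: editome
Title: A-to-I RNA Editing Site Detection, Annotation and miRNA Seed Impact
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects adenosine-to-inosine (A-to-I) RNA-editing sites from
    aligned RNA-seq reads against a haploid reference genome: a mismatch
    pileup engine with PCR-duplicate-aware support counting, editing-level
    and mapping-quality filters, genic-region annotation with
    synonymous/nonsynonymous classification by codon translation, editome
    summary tables and density tracks, and an edit-aware miRNA seed-match
    scanner that decides whether an edit destroys or creates a target site.
    Includes a fully seeded synthetic-data generator (genome, gene models,
    planted editing sites, SAM reads) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr,
    stats,
    utils
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
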