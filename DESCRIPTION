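Package: regionops
Title: Native Genomic Interval Algebra on BED-Style Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for genomic interval arithmetic on
    BED-style half-open regions: sorting in natural or lexicographic
    chromosome order, merging with bookend and gap-distance control,
    left-outer interval joins, multi-set partition joins with membership
    truth tables, subtraction (whole-interval and base-level), base-level
    intersection, membership tests, flank construction, tabix-style VCF
    region queries, BED input/output, and multi-set overlap summaries
    backing 2- to 5-way Venn counts. All operations are implemented
    natively in R (no external engine) and exposed both as library
    functions and through a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
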