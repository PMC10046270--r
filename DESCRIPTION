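Package: melwgs
Title: Post-Variant-Calling Analysis of Melanoma Whole-Genome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of somatic variant and copy-number calls from
    cutaneous melanoma whole-genome sequencing, aimed at cohorts lacking the
    common BRAF/RAS/KIT drivers. Builds 96-channel trinucleotide mutation
    catalogs, refits a fixed COSMIC-style signature matrix by
    expectation-maximization with per-mutation UV attribution, computes tumor
    mutational burden with a WES-to-panel conversion, classifies mutations
    into clonal/polyclonal/subclonal categories from variant allele fractions,
    summarises allele-specific copy-number segments (LOH fraction and an
    HRD-LOH scar score), and derives cohort-level gene recurrence and
    over-representation tables. Includes seeded synthetic-data generators so
    every stage is testable without access to patient sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    GenomicRanges,
    IRanges,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
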