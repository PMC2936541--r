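Package: lofcohort
Title: Rare Loss-of-Function Variant Characterization in Small Sequenced Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize protein-truncating (loss-of-function)
    variation in small whole-genome sequencing cohorts. Provides functional
    annotation of SNVs and indels against gene models (stop gain, stop loss,
    frameshift and related classes), case/control gene prioritization by
    counts of affected cases with qualifying homozygous or hemizygous
    truncating variants, permutation-averaged variant- and knockout-gene
    discovery saturation curves, exact Hardy-Weinberg excess-heterozygosity
    diagnostics with read-depth copy-number states to flag
    segmental-duplication artifacts, sequencing-versus-genotyping-chip
    concordance QC, and a fully specified synthetic diploid cohort generator
    (including an X-linked causal-gene scenario) used to exercise the whole
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
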