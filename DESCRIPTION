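Package: paneldepth
Title: Sequencing Depth Requirements and Variant Prioritization for Targeted Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for estimating the minimal sequencing depth
    required to recover SNPs and indels from targeted gene-panel data, and for
    prioritizing candidate disease variants in Mendelian families. Provides a
    synthetic panel simulator (reference, targets, planted variants, pedigree
    genotypes and error-bearing paired reads), a self-contained diploid pileup
    genotype caller with Phred-scaled confidence, a read down-sampling
    rarefaction engine with C95 coverage brackets and per-variant minimal
    callable fractions, a frequency/functional/predictor/inheritance filter
    cascade with pedigree segregation checks under incomplete penetrance, and
    recall/precision benchmarking of call sets against a truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
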