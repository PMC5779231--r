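Package: aneusilence
Title: Aneuploidy and Chromatin Silencing Analysis for Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis pipeline linking aneuploid karyotypes to
    loss of chromatin silencing in Saccharomyces cerevisiae. Provides
    karyotype representation and qPCR-based copy-number calling, exact
    binomial enrichment tests for chromosome-specific aneuploidies,
    per-cell fluorescence reporter quantification (Tukey-fence outlier
    classification, Mann-Whitney comparisons, coefficient-of-variation
    dispersion, lineage state-transition detection, DNA-content G2
    gating), three-zone radial nuclear locus positioning with chi-square
    tests, chromosome-copy-number-aware expression and histone-modification
    comparison (count normalization, RPKM, fold-change categories,
    peak-to-TSS assignment, Z-score differences, subtelomeric Fisher
    enrichment, background-variant filtering), and a synthetic-data module
    that generates every input the pipeline consumes for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    limma,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
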