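Package: rrachstrat
Title: Sequence-Composition Stratification of Differential-Expression Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis pipeline for RNA-seq perturbation studies of
    the m6A epitranscriptome: a simplified negative-binomial differential
    expression stage (median-of-ratios normalization, Wald test,
    Benjamini-Hochberg adjustment), multi-line shared gene-list construction
    with hypergeometric overlap tests, category and keyword enrichment screens
    (hypergeometric and two-tailed Fisher exact), and stratification of
    upregulated, downregulated and random transcript sets by sequence
    composition (adenosine frequency, region length, and density of the
    degenerate m6A consensus motif RRACH in 5'UTR, CDS and 3'UTR). Includes a
    synthetic transcriptome and counts generator with planted motif densities
    and category effects that serves as a parameter-recovery oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.3)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
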