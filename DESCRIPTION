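Package: permDE
Title: Permutation-Based Empirical t-Tests and EASE Enrichment for FPKM
    Expression Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential-expression inference for small bulk RNA-seq designs
    quantified as FPKM. Expressed genes (FPKM > 1 in at least one sample) are
    log2(FPKM + 1) transformed and quantile normalized, per-gene pooled
    two-sample t-statistics are referred to an empirical null distribution
    built by permuting group labels and pooling the permuted statistics across
    all genes, and genes are called differentially expressed by a
    Benjamini-Hochberg adjusted empirical p-value together with a data-driven
    (or fixed) absolute log2 fold-change cutoff. Gene-set enrichment of the
    resulting gene lists uses the EASE score, a conservative jackknifed
    one-sided Fisher exact test, against user-supplied GMT collections. A
    seeded synthetic-data generator emulating two-group lognormal-like FPKM
    matrices with planted effects, and a reproducible simulate/run/enrich
    pipeline with manifests, make the whole analysis testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
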