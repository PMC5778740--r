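Package: methwindow
Title: Sliding-Window Differential DNA Methylation Analysis for Array EWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An epigenome-wide association (EWAS) pipeline for Illumina
    450K-style beta-value matrices: probe quality filtering, covariate
    normalisation with a logistic-link model, reference-free cell-type
    correction by sparse principal components, per-probe case/control
    logistic regression with likelihood-ratio testing and genomic-inflation
    diagnostics, differentially methylated region (DMR) discovery by a
    1 kb sliding window combining probe P values with Fisher's method and
    Storey q-value FDR control, a bump-hunting cross-check with bootstrap
    family-wise error rates, and genomic-feature and gene-set enrichment of
    the resulting regions. Includes a synthetic-data generator that emulates
    450K probe geography, cell-type mixture confounding and spiked regional
    case/control differences, so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
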