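Package: gestmeth
Title: Promoter DNA Methylation Drift Across Placental Gestation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome-scale promoter DNA methylation
    (beta-value) data across placental gestational ages. Computes beta-values
    from methylated/unmethylated signal pairs, applies detection-p and
    sex-chromosome quality control, shift-and-scale normalization and
    group-protected batch correction; summarises per-sample Methylation
    Index and beta-band composition; calls differentially methylated probes
    by delta-beta thresholding with Benjamini-Hochberg adjustment; classifies
    inter-individual variability by per-trimester probe variance with
    quadrant and Venn partitions; tests CpG-island context enrichment;
    integrates methylation with gene-level expression by quartiling; cleans
    EpiTYPER validation tables by three ordered rules; and clusters samples
    with purity scoring. Includes a synthetic-cohort generator with planted
    progressive-methylation and variance-inflation effects so the whole
    pipeline is recovery-testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
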