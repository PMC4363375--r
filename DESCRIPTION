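Package: founderseq
Title: Founder-Population Rare-Variant Analysis: Kinship, Gene-Drop
    Simulation, Pedigree-Aware Association and Burden Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for rare-variant studies in isolated founder
    populations: pedigree parsing and validation with recursive kinship
    and inbreeding coefficients; an exome variant filter cascade
    (read-evidence quality, consequence, novelty against known-variant
    catalogues, affected-sharing, linkage-region annotation) built on a
    binomial read-depth model; a pedigree-aware quasi-likelihood score
    test for case-control association among related individuals with
    prevalence-transformed phenotypes and ungenotyped-relative
    enrichment; Monte-Carlo gene-drop simulation of founder allele
    frequencies with an exact enumeration oracle; two-tailed Fisher's
    exact rare-variant burden comparisons against reference panels; and
    a synthetic cohort generator (multi-generation pedigrees, incomplete
    penetrance with phenocopies, per-sample exome variant tables) so the
    whole pipeline is testable without access to restricted genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
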