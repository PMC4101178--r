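Package: ryegs
Title: Genomic Selection and Marker-Assisted Selection in Hybrid Rye Testcross Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genomic selection studies in
    bi-parental testcross populations of hybrid rye. Simulates half-sib F3:4
    populations with multi-environment testcross phenotypes, performs marker
    quality control, imputation and linkage-disequilibrium estimation,
    estimates BLUEs, variance components and heritability by two-stage REML,
    predicts genotypic values by ridge-regression BLUP (RR-BLUP) and by
    QTL-based marker-assisted selection (composite interval mapping), and
    quantifies prediction accuracy under cross-validation schemes spanning
    genotypes, environments, locations and years.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
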