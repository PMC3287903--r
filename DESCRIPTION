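Package: wincurse
Title: Winner's Curse and Effect-Size Attenuation in Two-Stage Genetic
    Association Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seeded simulation and estimation pipeline for quantifying
    selection bias (the winner's curse) and linkage-disequilibrium
    attenuation in two-stage genetic association study designs, in which
    a tag SNP is tested in a GWAS-like first stage and effect sizes are
    then estimated at causal variants or at a rare-variant collapsing
    (burden) statistic in a sequencing-like second stage.  Includes an
    LD-constrained genotype generator with feasibility bounds on the
    tag-causal allelic correlation, additive linear and logistic
    single-SNP regressions, the r_i/n_i collapsing regression, selection
    rules and threshold calibration, analytic truncated-normal oracles,
    and CSV/VCF input-output for real-data application.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
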