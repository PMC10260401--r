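Package: admixqtl
Title: Ancestry-Aware Cis-eQTL Mapping, Heritability and TWAS for Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how genetic ancestry shapes the genetic
    architecture of gene expression in admixed cohorts. Includes a
    synthetic admixed-cohort generator with labeled ground truth
    (ancestral allele-frequency divergence, block linkage
    disequilibrium that can differ between ancestries, global and
    local ancestry, cis-eQTL effects under shared and
    ancestry-specific scenarios), unconstrained REML estimation of
    cis-heritability and genetic variance with kinship options,
    stepwise global/local ancestry association, cis-eQTL discovery
    with beta-approximated permutation calibration and LD clumping,
    single-causal-variant fine-mapping with credible sets, a tiered
    classifier of ancestry-specific eQTLs, and elastic-net
    transcriptome prediction models with summary-statistic TWAS.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
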