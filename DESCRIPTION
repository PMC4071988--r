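Package: snpmeta
Title: Genotype-Level Case-Control Meta-Analysis for Biallelic SNPs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Meta-analysis of case-control genetic association studies at the
    genotype level. Builds the four standard genetic-model contrasts
    (homozygote, heterozygote, dominant, recessive) from per-study genotype
    counts, computes per-study odds ratios with Wald confidence intervals,
    tests Hardy-Weinberg equilibrium in controls, pools across studies by
    Mantel-Haenszel or inverse-variance fixed effects and DerSimonian-Laird
    random effects with a heterogeneity-gated model choice, and provides
    leave-one-out sensitivity analysis, Egger and Begg publication-bias
    tests, funnel-plot coordinates, a five-category study-quality rubric,
    and a multinomial simulator for case-control genotype counts with known
    per-genotype odds ratios. Ships the genotype tables of a published
    XRCC3 ovarian-cancer meta-analysis as fixtures for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
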