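Package: poefam
Title: Parent-of-Origin Effect Analysis in Nuclear-Family Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based analysis of parent-of-origin effects (POE) on
    quantitative traits. Parses and validates nuclear-family pedigrees with
    candidate-SNP genotypes, runs per-SNP quality control (call rate, exact
    Hardy-Weinberg test, Mendelian consistency), infers the parental origin of
    minor alleles from trio and duo genotypes, applies standard lipid and
    obesity trait derivations (Friedewald LDL, ApoB/ApoA1 ratio, BMI, WHR,
    WHtR) with natural-log and Blom rank-based inverse-normal transformations,
    and fits maternal, paternal, and parent-of-origin contrasts with
    family-clustered generalized estimating equations. Also provides
    parent-offspring correlation comparisons (Spearman/partial correlation,
    family random-intercept slopes, Fisher r-to-z and Wald comparisons), a
    heterozygote variance-inflation POE screen for unrelated individuals,
    fixed-effects meta-analysis across cohorts, and a synthetic nuclear-family
    cohort generator with tracked allele origins for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
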