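---
title: "Parent-of-origin effect analysis in nuclear families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin effect analysis in nuclear families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poefam)
```

## The scientific problem

A parent-of-origin effect (POE) exists when a variant's phenotypic effect
depends on whether the allele was inherited from the mother or the father —
genomic imprinting being the classic mechanism. In a standard association
study of unrelated individuals a maternal effect of $+\beta$ and a paternal
effect of $-\beta$ average out to nothing, so POEs are invisible or their
effect sizes underestimated. Family data change that: with parental genotypes
in hand, the origin of an offspring's minor allele can often be determined,
and maternally versus paternally inherited copies can be contrasted directly.

`poefam` implements this family-based workflow for quantitative lipid and
obesity traits in nuclear-family cohorts: pedigree QC, origin inference,
trait normalisation, family-clustered association contrasts, a
variance-based POE screen usable without pedigrees, and cross-cohort
meta-analysis — together with a synthetic-cohort generator that provides
ground truth for every stage.

## Origin inference from trios and duos

For each offspring–SNP pair with a non-missing offspring genotype we
enumerate the ordered transmission configurations (maternal allele, paternal
allele) compatible with the observed parental genotypes (a missing parent is
unconstrained). The call is:

* **assigned** — exactly one configuration survives. A heterozygote is
  assigned whenever at least one parent is informative (e.g. mother `0`,
  father `1` or `2`); homozygotes are assigned whenever no Mendelian
  inconsistency arises, because their origin split (0/0 or 1/1) is logically
  certain regardless of parental data.
* **ambiguous** — more than one configuration survives with at least one
  parent observed (the classic both-parents-heterozygous trio).
* **untestable** — a heterozygote with both parents missing.
* **mendelian_error** — no configuration survives; such offspring are
  excluded from association rather than "corrected".

Two deliberate restrictions: no sibling-aided phasing (a both-het trio stays
ambiguous even when siblings could resolve phase; only configuration-unique
calls are assigned) and no population-based statistical phasing. Only
abstention is possible, never false assignment — a property the test suite
verifies against recorded simulation truth.

Under Hardy–Weinberg equilibrium and random mating the probability that a
heterozygous offspring is ambiguous in a full trio equals
$P(\text{both parents het} \mid \text{offspring het}) = pq$, so the
assignable fraction is $1 - pq$ — $3/4$ at minor-allele frequency $0.5$.
The acceptance suite checks convergence to this enumeration-derived value.

## Trait derivation and normalisation

Derived traits follow the standard definitions: BMI $= w/h^2$ (kg/m²),
waist–hip ratio, waist–height ratio, ApoB/ApoA1, and Friedewald LDL
($\mathrm{TC} - \mathrm{HDL} - \mathrm{TG}/5$ in mg/dL, valid only when
TG $< 400$ mg/dL; in mmol/L the divisor is 2.2 and the threshold 4.52 —
the unit must be declared explicitly, never guessed). TG, ApoB, LDL and all
obesity measures receive the Blom rank-based inverse-normal transform
$z_i = \Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$ with average ranks for
ties (Blom's published offset; average ranks keep the map monotone); the
remaining lipid measures are natural-log transformed. A single-pass
5-SD filter then runs on the transformed scale: mean and SD are computed
once and values beyond 5 SD set missing. One pass suffices in this data
regime (surviving values lie within 3 SD), making the filter idempotent;
a raw-scale mode is available behind a flag.

## The association model

For each SNP × trait × stratum, three contrasts are fitted with an
identity-link Gaussian GEE grouped by nuclear-family id:

* **maternal**: origin-assigned heterozygotes carrying a *maternally*
  inherited minor allele (exposure 1) versus major-allele homozygotes
  (exposure 0);
* **paternal**: the symmetric comparison;
* **POE**: assigned heterozygotes only, paternal versus maternal origin.

Minor-allele homozygotes are excluded from the marginal contrasts (the
comparison is against major-homozygote carriers); a joint-dosage mode —
maternal and paternal minor-allele counts as two regressors over all
assigned offspring — is available behind a flag and is convenient for power
studies. Lipid traits are adjusted for BMI, sex, age, age², and diabetes
affection status; obesity traits for the same set minus BMI; the
BMI-adjusted WHR analysis appends BMI to the covariates rather than
pre-residualising (covariate adjustment is the minimal consistent reading;
sex-stratified runs drop sex and re-use transforms computed on the full
cohort so trait values agree across strata).

The GEE is authored in the package (no suitable GEE implementation is
available among its dependencies): independence working correlation by
default — point estimates then coincide with ordinary least squares — with
an exchangeable option whose common correlation is estimated by moments and
iterated to convergence. Standard errors are cluster-robust sandwich
estimates,
$\widehat V = B \big(\sum_c X_c^\top r_c r_c^\top X_c\big) B$ with
$B = (X^\top X)^{-1}$.

**Small-sample reference.** With a candidate-SNP panel the POE contrast
often involves only 100–300 heterozygous offspring in a similar number of
family clusters, and the raw normal reference on the sandwich z statistic is
measurably anti-conservative there (null rejection around 0.065–0.075 at
nominal 0.05 in our calibration runs). The default reference is therefore
the standard small-sample correction: the z statistic is scaled by
$\sqrt{G/(G-1)}$ ($G$ clusters) and referred to a $t_{G-p}$ distribution,
restoring the type-I error to ≈ 0.05–0.06; the plain normal reference
remains selectable (`p_ref = "normal"`). Reported standard errors are the
unadjusted sandwich estimates in either case.

Discovery/replication splits assign whole families at random to two
near-equal subsets, deterministically given a seed. Replication requires a
replication p-value below the nominal level *with the same direction of
effect*. Bonferroni flags use $m$ = the number of SNP × trait tests in the
executed sweep by default; printed corrected thresholds of specific studies
are reproduced by configuring $m$ directly.

## Parent–offspring resemblance

Three models quantify father–offspring versus mother–offspring resemblance:

1. Spearman (optionally partial) rank correlation using the oldest child per
   family. Partial correlations residualise the ranks on rank-transformed
   covariates; the partialling set for the base model is taken as
   {age, age², sex} (the minimal demographic set), with BMI added in model 3.
2. A family random-intercept linear model (`lme4`) of the offspring trait on
   the parent trait over all offspring.
3. Model 2 plus sex, age, age² and BMI of the offspring.

Correlations are compared with the Fisher r-to-z statistic
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$ and slopes with the Wald statistic
$(b_1 - b_2)/\sqrt{se_1^2 + se_2^2}$. The father- and mother-based samples
share offspring, so the independent-samples Fisher test is anti-conservative
in principle; it is provided as the conventional method, with a
dependent-correlation variant (Steiger's test on offspring with both parents
measured) behind a flag. Mixed-model p-values use the Wald normal reference
on the t statistic; when every family contributes a single pair the random
intercept is unidentifiable and the fit collapses, by construction, to
ordinary least squares.

## The heterozygote-variance screen

Hidden opposite-direction parental effects leave a fingerprint in unrelated
individuals: among heterozygotes the phenotype is a 50:50 mixture of
"maternal-origin" and "paternal-origin" carriers with means $\pm\delta$,
$\delta = |\beta_{pat} - \beta_{mat}|/2$, inflating the heterozygote
residual variance by $\delta^2$ while homozygote variances are unchanged.
With $\beta_{mat} = +0.3\sigma$, $\beta_{pat} = -0.3\sigma$ the expected
heterozygote/homozygote variance ratio is $1.09$.

Two method tags are provided, and every result records which was used:

* `levene_het` (default): Brown–Forsythe-style comparison of median-centred
  absolute residual deviations, heterozygotes versus pooled homozygotes,
  one-sided in the inflation direction. Transparent and robust.
* `mixture_het`: a likelihood-ratio test of the heterozygote residuals as an
  equal-weight two-component normal mixture with means $\mu \pm \delta$
  against $\delta = 0$, maximised by an EM algorithm with an exactly solved
  constrained M-step and multiple starts, referred to a half-$\chi^2_1$
  boundary distribution. This captures the mechanism of the published
  mean-genotype POE tests for unrelateds without claiming bit-compatibility
  with any particular program.

Covariates are removed once by least-squares residualisation before
grouping. Imputed (fractional) dosages are mapped to genotype-group weights
by linear interpolation and enter weighted variance estimates; integer
dosages reduce exactly to hard-call grouping. Both tests are invariant to
affine rescaling of the trait.

## Meta-analysis

Per-cohort POE contrasts are combined by fixed-effects inverse-variance
weighting ($w_i = se_i^{-2}$, $\hat\beta = \sum w_i \beta_i / \sum w_i$,
$se = (\sum w_i)^{-1/2}$), the default because the strata tables carry betas
and SEs; a sample-size-weighted z mode
($z = \sum z_i \sqrt{n_i} / \sqrt{\sum n_i}$) serves SE-less inputs. A
direction string and a strict shared-sign consistency flag accompany every
result. No heterogeneity modelling (random effects, $I^2$, $Q$) is
attempted in this version.

## The synthetic-data generator

`sim_config()`/`simulate_families()` emulate the structure of the large
family cohorts this methodology targets: 2257 nuclear families by default
(an HTB-like preset uses 2264), offspring counts $1 + \mathrm{Pois}(0.5)$
truncated at 5 (offspring ≈ 43% of individuals), parents drawn under HWE,
Mendelian transmission with recorded origins, and trait values produced on
a latent analysis scale
$$z = \big(\beta_{mat}\,a_{mat} + \beta_{pat}\,a_{pat}\big)\cdot s_{sex}
 + \text{covariates} + b_{fam} + \varepsilon$$
then mapped to published cohort means/SDs by a location–scale transform
(`table1_defaults()`), so that configured effect sizes stay in trait-SD
units directly comparable to reported betas. Defaults, chosen once as
realistic for this setting: family-intercept SD 0.3 and residual SD
$\sqrt{1 - 0.09}$ (unit latent variance under the null); covariate
coefficients 0.2 (standardised age), 0.05 (age²), 0.2 (sex), 0.3 (diabetes,
prevalence 0.27 in offspring and 0.41 in parents), 0.3 (BMI, lipid traits
only); element-wise genotype missingness 0.05 (mirroring >90% genotyping
success), whole-parent non-genotyping 0.15 with at least one typed parent
per family, phenotype missingness 0.05. Sex-specific POE is a
multiplicative scaling of $(\beta_{mat}, \beta_{pat})$ by offspring sex.
`simulate_unrelateds()` draws each individual from unobserved HWE parents,
keeps the origin-dependent phenotype but exposes only the genotype; the
unobserved family effect folds into the residual so the latent variance
matches the family cohorts.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium between panel SNPs,
assortative mating, genotyping error (Mendelian cleanliness is exact by
construction, so error handling is exercised only through hand-built
fixtures), non-normal trait shapes beyond what the location–scale map
induces, age- or cohort-structured missingness, and any epigenetic
mechanism behind the simulated POEs.

## Numerical choices and degenerate inputs

* Exact HWE test: the full conditional distribution of the heterozygote
  count given allele counts is enumerated in log space; the two-sided
  p-value sums probabilities not exceeding the observed one (with a
  $1+10^{-12}$ tie guard). Monomorphic SNPs return $p = 1$ with a warning.
  Founders-only is the default (offspring are correlated with parents).
* GEE: rank-deficient designs are a hard error naming the aliased columns;
  a single cluster is an error; the exchangeable correlation estimate is
  clamped to $(-0.99, 0.99)$.
* Variance screen: groups with effective size below 10 are flagged
  untested; identical residuals give statistic 0, $p = 1$.
* Blom transform: constant input is a hard error (ranks carry no
  information); missing values are preserved in place.
* All randomness (splits, simulations) flows from explicit seeds through a
  local RNG scope that leaves the caller's stream untouched; identical
  seeds give byte-identical cohorts and pipeline bundles.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely on synthetic
cohorts sized for quick, reproducible calibration: 10,000 single-offspring
trios for the assignability check, 300-family cohorts for null calibration
(1,000 replicates) and effect recovery (200 replicates), 3,000 unrelateds
for the variance screen (200 replicates), and full 2257/2264-family cohorts
for the end-to-end and meta-analysis examples. These sizes give
Monte-Carlo errors comfortably below the tolerances being checked.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  seed = 2, n_families = 500,
  snps = data.frame(snp_id = "rs_demo", maf = 0.3,
    beta_mat = 0, beta_pat = 0.3),
  traits = list(bmi = c(26.69, 4.61)), focal_trait = "bmi"
)
out <- run_pipeline("demo_run", cfg)
out$report
```

## Known limitations

The package analyses quantitative traits only (no logistic GEE); it targets
candidate-SNP panels, not genome-wide scans; extended pedigrees are handled
only through nuclear-family decomposition; there is no genotype imputation,
no sibling-aided or population phasing, and the variance screen's mixture
method requires hard-call genotypes. The independent-samples Fisher
comparison of parent–offspring correlations is anti-conservative when the
offspring overlap is substantial; use the dependent variant where that
matters.
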