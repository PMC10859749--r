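---
title: "Validating lipid variants and building genetic risk scores with lipidgrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating lipid variants and building genetic risk scores with lipidgrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidgrs)
```

## The problem

Candidate-variant validation studies ask whether loci discovered in large,
mostly European GWAS also influence a trait in a different population. The
setting `lipidgrs` addresses is a rural–urban North Indian cohort
(n = 2,117) in which 12 established lipid loci were genotyped and tested
against five serum lipid traits: total cholesterol (TC), triglycerides
(TG), HDL-C, LDL-C and VLDL-C. The package implements that whole analysis
as reusable, tested components — variant QC, trait transformation,
additive-model association under two covariate models, dual-significance
selection, unweighted and weighted genetic risk scores, stratified and
gene–environment interaction screens, and analytic power — together with a
calibrated synthetic-cohort generator so the pipeline can be exercised end
to end without access to the controlled genotype data.

## The statistical model

Each variant is coded as the dosage $d \in \{0, 1, 2\}$ of its minor
allele. For a trait $y$ (z-standardized after an optional log transform)
the additive association model is ordinary least squares:

$$ z(y) = \beta\, d + \gamma' x + \varepsilon, $$

with $x$ either the minimal covariate set (Model 1: age, gender, site) or
the fully adjusted set (Model 2: plus fat intake, physical activity, BMI,
alcohol, smoking, hypertension, diabetes). $\beta$ is the per-minor-allele
effect in trait-SD units; p-values use the t reference with residual
degrees of freedom on complete cases.

Variants significant for a trait in **both** models are aggregated into
risk scores. Each selected variant is oriented so its counted allele moves
the trait in the adverse direction (an increase for TC/TG/LDL/VLDL, a
decrease for HDL); a counted major allele has dosage $2 - d$. Then

$$ \mathrm{uGRS} = \sum_i a_i, \qquad \mathrm{wGRS} = \sum_i w_i a_i, $$

where $a_i$ is the counted-allele dosage and $w_i = |\hat\beta_i|$ from
the weight-source model (fully adjusted by default; configurable). The
score is regressed on the trait under the minimal adjustment, exactly like
a single variant. Because weights are positive and HDL counts
HDL-*lowering* alleles, the HDL score coefficient is negative — the sign
structure the adverse-direction rule is chosen to produce. The raw
weighted sum is reported by default; a count-normalized rescaling
($\times\, i / \sum w$) is available but off, since the displayed score
equation is a plain weighted sum.

### Trait scales and unit back-transformation

TG and VLDL-C are right-skewed and analysed on the natural-log scale; the
automatic rule transforms any trait whose sample skewness exceeds 1 (a
log-normal with geometric SD 1.60 has skewness ≈ 1.55) and can be forced
per trait. Since VLDL-C = TG/5 and z-scores are shift-invariant under
log, the TG and VLDL association rows are *identical* — a structural
identity the tests assert on every dataset.

Standardized coefficients convert back to interpretable units via
`effect_in_original_units()`: for a normal-scale trait, $\beta \times SD$
mg/dL; for a log-scale trait, the per-allele fold-change
$GSD^{\beta}$. The fold-change reading reproduces the reported per-allele
TG changes (e.g. $1.60^{0.21} = 1.10$) and is labelled as a fold-change
rather than an additive mg/dL difference, which a log-scale coefficient
cannot provide. Normal-scale conversions from 2-dp rounded inputs agree
with reported values to within ~1% (rounding-limited), which is what the
tests assert.

## Quality control

Per variant: call rate (observed/total), minor-allele-frequency estimation
with automatic re-orientation when the labelled minor allele exceeds 0.5,
and Hardy–Weinberg tests in three strata (rural, urban, combined — all
must pass). Two HWE tests are provided: the 1-df Pearson chi-square, and a
heterozygote-conditional exact test computed by full enumeration with log
factorials (mid-p optional). The default `"auto"` method uses the exact
test when the expected minor-homozygote count is below 5 — standard
small-count practice. The Sidak threshold $1 - (1-\alpha)^{1/m}$ is
implemented; note that the filter value 0.0018 used in the source analysis
is *not* the Sidak threshold for 12 tests at $\alpha = 0.05$ (that is
0.00427), so the literal 0.0018 is exposed separately as
`paper_hwe_threshold()` rather than silently derived from a guessed family
size.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study's statistical structure:

* **Genotypes** — Binomial(2, MAF) per variant with site-specific MAFs
  from the bundled panel, independent across variants. No linkage
  disequilibrium is simulated: the 12 variants lie on 9 chromosomes and
  the analysis treats them marginally.
* **Covariates** — gender × site drawn jointly from the cohort
  cross-tabulation; age 47.07 (12.99) y, BMI 24.91 (5.25) kg/m², fat
  intake 31.09 (5.05) g/day as clipped normals; physical activity,
  alcohol, smoking, diabetes and hypertension at the cohort proportions.
  Covariate–covariate correlations beyond gender × site are not emulated
  (only marginals are published) — a known fidelity limit.
* **Phenotypes** — for TC, TG and HDL a standardized latent trait
  $z = \sum_j \beta_j d_j + \gamma' x + \varepsilon$ with residual
  variance completing the total to 1 (explicitly overridable, including
  zero-noise). Defaults use the fully adjusted published effect sizes as
  truth and zero covariate effects, keeping the lipid marginals calibrated
  to the cohort summaries. Normal traits are rescaled to (mean, SD); TG is
  $\exp(\log GM + \log GSD \cdot z)$ with GM 125.96, GSD 1.60. VLDL-C is
  TG/5 exactly and LDL-C is derived per person by the Friedewald equation
  (TC − HDL − TG/5, invalid at TG ≥ 400 mg/dL), so the derived-trait
  identities hold by construction and the LDL genetic effects are the ones
  Friedewald induces from TC/HDL/TG — numerically close to the reported
  LDL estimates, as expected when the original LDL was itself
  Friedewald-derived.
* **Missingness** — each genotype is masked independently with probability
  1 − call rate. The default call rate is 0.98: the emulated study
  describes its post-QC data as having ≥95% call rates, i.e. data that
  passes the 0.95 filter, and simulating exactly at the threshold would
  put every variant on the filter boundary.

Fixing the seed fixes every output bit for bit. What passing tests on this
generator do **not** show: robustness to LD, population structure,
relatedness, genotyping batch effects, or covariate confounding beyond the
emulated marginals.

## Interactions and stratified analysis

`stratified_association()` refits the additive model within gender or site
strata (the stratifier dropped from the design; strata under 100 samples
skipped with a flag). `interaction_test()` adds a product term
$d \times m$ to the fully adjusted model and reports only that
coefficient. Modifiers: gender, site, obesity (BMI ≥ 25 kg/m², the
Asian-Indian cut-off, configurable), fat intake (standardized continuous)
and physical activity (ordinal 0–3). The covariate a modifier derives from
is removed from the adjustment set so the modifier main effect is not
collinear with it. No multiplicity correction is applied — mirroring the
validation design — and the screen annotates how many tests it ran.

## Power

`power_additive()` uses the score-test noncentral chi-square formulation:
a variant explaining a fraction $r^2$ of a unit-variance trait gives a
1-df noncentrality $\lambda = n r^2 / (1 - r^2)$; with
$r^2 = \beta^2\, 2\,\mathrm{MAF}(1-\mathrm{MAF})$ under HWE. At the study
size (n = 2,117, $r^2$ = 1%, $\alpha$ = 0.05 two-sided) power is ≈ 99.6%,
comfortably above the 80% design bound; the minimum detectable $r^2$ at
80% power is ≈ 0.37%. The tests cross-check the analytic value against
the empirical rejection rate of the full simulate-and-fit stack.

## Numerical and design choices

* Sample SD uses the n − 1 denominator; natural logs throughout.
* Complete-case analysis per fit; the score layer instead imputes missing
  genotypes at the expected oriented dosage (2 × counted-allele
  frequency), standard polygenic-score practice that keeps n — complete
  case available by flag.
* Monomorphic dosages are skipped with a flag, not an error; monomorphic
  HWE tests return p = 1 with a warning.
* Rank-deficient designs raise an error naming the collinear terms.
* p-values only reported as "< 0.001" in the bundled estimate table are
  stored as 0.0005; every use compares them against thresholds ≥ 0.05.
* Scores are regressed raw (not standardized): per-unit effects near 1 SD
  in the reported weighted-score rows indicate the raw-score scale.
* The published table's allele-coding footnote for the three
  major-allele-risk variants is not fully consistent with its results
  prose; the orientation layer works on whatever dosage coding the matrix
  uses and is invariant to coding flips (tested), so scores are unaffected.
* Report writers offer 2-dp ("report") and full-precision ("machine")
  modes; 2-dp rounding is presentation only and is never used in
  computation.

## Problem sizes used in the test-suite simulations

Sampling-distribution checks use cohorts of the study size (n = 2,117)
with 200–500 replicates for SE calibration and type-I error, 2,000
replicates for the power cross-check, and n = 10⁵ single draws for
frequency calibration — sizes at which the asserted tolerances (±2% on
rejection rates, 2-dp equality on average SEs) are comfortably stable.

## Limitations

Beyond the generator's fidelity limits above: LDL handling assumes
Friedewald validity (no direct-LDL or Martin/Sampson equations),
covariates enter linearly, no mixed models or relatedness adjustment, and
the package makes no attempt to model food-frequency questionnaire
processing or genotyping chemistry upstream of the dosage matrix.
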