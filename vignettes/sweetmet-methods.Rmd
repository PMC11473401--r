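---
title: "Methods: dietary biomarker discovery with sweetmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary biomarker discovery with sweetmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sweetmet)
```

## The problem

Self-reported intake of sweetened beverages and added sugar is noisy and
systematically under-reported, which blurs their association with adiposity.
Untargeted metabolomics offers objective intake biomarkers: features of the
urine or plasma metabolome that track what a person actually consumed.
`sweetmet` implements the full discovery chain for this setting — high
dimensional feature tables, zero-inflated exposure distributions, repeated
measures, detection-limit missingness, analytical batch structure — together
with a synthetic cohort generator so that every stage can be tested and
scored against a known truth without access to restricted cohort data.

## The synthetic cohort generator

The generator emulates three sampling designs: children with two urine
collections about a year apart (297 participants by default, with
participant-level random intercepts in both features and outcomes,
intra-class correlation 0.4), adolescents with a single urine collection
(339), and young adults with a single plasma draw preceded by 3–6 dietary
assessments (195).

**Intakes.** Each food's g/d intake is a zero-inflated log-normal mixture:
a point mass at zero (non-consumers) and a log-normal consumer
distribution. The published distributions report only medians and quartiles,
so the family is our choice; it reproduces the characteristic heavy zero
mass (LNCSB median 0) and right skew. Defaults are matched to the adolescent
arm: added sugar median ≈ 62 g/d (IQR ≈ 36–90, essentially no
non-consumers: `p_zero = 0.02`, `meanlog = log 62.2`, `sdlog = 0.68`); SSB
median ≈ 133 g/d with 30% zeros (`meanlog = 5.57`, `sdlog = 1.2`); LNCSB
60% zeros. SSB and AS are coupled through a latent bivariate Gaussian
copula. Because the raw-scale Pearson correlation of the transformed
margins is attenuated relative to the latent correlation, the latent value
is calibrated by root-finding on a fixed common-random-numbers stream
(10^5 draws, internal seed) so that the *raw* sample correlation converges
to the configured target (default 0.65, the adolescent value; 0.78 matches
the plasma arm).

**Features.** Log intensity of feature *j* in sample *i* is
`mu_j + beta_j * intake_i + small age/sex terms (+ participant intercept) +
N(0, 1)`, then per-(batch, feature) additive shifts (SD 0.3) and
multiplicative scales (`exp(N(0, 0.1))`) are applied on the log scale and
the matrix exponentiated, so intensities are strictly positive. Planted
effects are expressed per g/d on the standardized-log scale; the standard
scenario plants effects of 0.3 SD of log intensity per SD of intake, which
for added sugar corresponds to per-g/d slopes of ≈ 0.005 — the same order
as published food–metabolite coefficients.

**Censoring.** Detection-limit missingness masks, per feature, the
`floor(q n)` smallest values (default q = 0.10), so censoring is strictly
left-tail and the missing fraction is within 1/n of the target.

**Outcomes.** BMI, body-fat % and waist circumference are linear in a
planted subset of standardized-log features plus age/sex/energy terms, a
latent shared adiposity factor (SD 0.45 on the scaled-SD metric) and
Gaussian noise. The shared factor induces the moderate positive
correlation among the three measures (mean pairwise r ≈ 0.2) that the
correlation-adjusted significance threshold relies on; with fully
independent noise the three "adiposity" measures would be uncorrelated,
which no real anthropometry exhibits.

**What the generator does not emulate:** chromatography and spectra,
annotation confidence, non-linear diet–metabolite kinetics, confounding of
intakes by covariates (intakes are drawn independently of age, sex and
energy), and seasonal or storage effects. Passing tests therefore show
that the *statistical machinery* behaves as specified under the assumed
data-generating model, not that any particular real-world biomarker would
be recovered.

## Preprocessing decisions

* The >30% missingness filter is evaluated **per food group among that
  food's consumers**, and retention is food-specific; the rule is a strict
  `>`, so exactly 30% is retained.
* Half-minimum imputation operates within each analytical batch. The
  censored-quantile alternative fits a per-feature Gaussian on the log
  scale by regressing the observed order statistics on normal
  plotting-position quantiles offset by the known censored count, then
  draws from the truncated left tail — for a feature with its bottom 20%
  censored the imputed log values average `E[Z | Z < Φ⁻¹(0.2)] ≈ −1.40`.
  The random-forest alternative is chained imputation on the log scale
  (≤ 10 sweeps, tolerance 10⁻³ on the standardized change).
* Standardization uses the population-SD convention so worked examples are
  exact. Standardization precedes batch correction; the reverse order is
  available (`batch_correct` toggle plus manual call) for sensitivity.
* Batch correction is a per-feature location/scale regression: batch means
  are removed exactly and per-batch residual SDs rescaled to the pooled SD.
  The correction is affine and increasing within each batch, so it can
  never reorder samples within a batch. Acceptance of this component is
  behavioural (post-correction batch means 0, SD ratios 1), not
  bit-compatibility with any particular published implementation.
* Covariate KNN uses a Gower distance (via `cluster::daisy`) because
  smoking and alcohol are categorical; k = 10; categorical ties break
  alphabetically. Previously missing rows never serve as donors.

## Selection decisions

The repeated double cross-validation scheme uses 5 outer / 4 inner folds,
eliminating 20% of variables per round. PLS is fitted by an internal SIMPLS
routine (univariate response) because the backward-elimination loop needs
thousands of fits; a unit test pins its predictions to an independent PLS
implementation at 10⁻⁸. PLS importance is VIP at the inner-tuned number of
components (1–5 by inner RMSEP); random-forest importance is permutation
importance, with the forest's out-of-bag error serving as the inner
validation signal (the forest has no tuned hyperparameter at this stage).
The "min" model size minimises the **mean** inner validation error across
all repetition × outer-segment models — the elimination schedule is
deterministic, so sizes align — with ties resolved to the smaller model;
per-model selections at that size are combined by majority vote.

The bagged LASSO resamples rows with replacement, tunes the penalty per
bootstrap by 5-fold cross-validation at the CV minimum (a `"1se"` flag is
provided), and counts nonzero coefficients. The elbow rule on the sorted
frequency curve treats a drop as *sharp* when it is a local maximum of the
successive drops exceeding both the mean drop and 80% of the largest drop;
the cutoff is the **last** sharp drop, and when no drop qualifies (flat or
smooth curves) the single largest drop is used. The 80% factor is our
operationalisation of "sharp": on realistic frequency curves the drops form
a dense noise floor, and weaker thresholds (for example mean + 2 SD of the
drops, or half the largest drop) let late tail drops qualify, which pushes
the last-elbow cutoff deep into the noise and floods the selection with
null features. Features tied with the frequency at the cutoff are retained.
Consensus keeps features selected by ≥ 2 distinct methods; adding a method
can only grow the consensus.

Intakes enter the selectors untransformed in g/d, matching the association
models. A consequence worth knowing: for extremely skewed zero-inflated
exposures (the SSB mixture), raw-scale sample correlations at n = 300 are
dominated by a handful of tail observations, in-sample spurious
correlations of null features approach the planted signal, and *any*
selector's precision degrades. The package's standard recovery scenario
therefore plants its effects on the added-sugar exposure, whose
near-continuous moderate-skew distribution matches the linear working
model; the SSB setting remains available and is exercised by the
calibration tests.

## Association and adiposity decisions

* Wald (normal-approximation) 95% CIs and p-values for both OLS and mixed
  models; mixed models are fitted by REML, falling back to OLS with a
  warning when the random-intercept variance hits the zero boundary.
* Covariate sets are design-locked and requesting anything else raises an
  error. BH-FDR is applied within each (food, design) family.
* VIF is computed from the inverse correlation matrix of the predictors
  (with a direct-regression fallback for singular designs); pruning removes
  one metabolite at a time — the highest VIF above 10, ties broken by
  removing the alphabetically last id — and recomputes after every removal.
  Covariates are never removed.
* The correlation-adjusted threshold is the Sankoh form
  `α_adj = 1 − (1−α)^(1/k^(1−r̄))`. The published per-design thresholds
  (0.0199–0.0211) depend on the restricted cohorts' outcome correlations
  and cannot be reproduced at desk scale, so verification is formula-level
  (closed forms, monotonicity in r̄ and k) rather than value-level.
* The adaptive elastic net residualises the outcome and the metabolites on
  the covariates (Frisch–Waugh), takes ridge weights `1/|b|` (capped at
  10⁶), fixes the mixing parameter at 0.5 (configurable), and selects the
  one-SE penalty by 5-fold CV — the sparser CV-supported choice, which
  keeps the null case honestly empty.

## Problem sizes and reproducibility

The package's simulation studies run at n = 300 participants, p = 500
features, 10 planted biomarkers of standardized effect 0.3, with a scaled
selection profile: 10 rdCV repetitions, 200 LASSO bootstraps, 100-tree
forests eliminating 50% per round, and a 50-knot penalty path (the
full-scale defaults of 50 repetitions / 1000 bootstraps / 500 trees / 20%
elimination remain the exported defaults). Null error-control studies use
500 generated datasets of 200 features each. These sizes are the package's
chosen benchmark conditions; they keep a complete study reproducible in
minutes on a single core.

Every source of randomness descends from one master seed via a documented
counter scheme (`derive_seed`): child = `(master mod 2^20)·1024 + stage
offset`, so each stage is independently re-runnable and two runs with the
same master seed produce byte-identical artifacts and manifests.

## Known limitations

* Selection, association and adiposity modelling reuse the same data set,
  as in the emulated design; the association-stage FDR among *selected*
  features is therefore optimistic, and the benchmark suite scores
  false-discovery proportion against the generator's truth instead. For the
  same reason the multi-method consensus does not empty out under a global
  null: all three selectors see the same in-sample spurious correlates, so
  a handful of null features (typically a few out of 500 at the benchmark
  scale) survive the ≥ 2-method rule even when nothing is planted.
* The mixed models support a single random intercept (participant); no
  crossed or nested structures, no GEE.
* The recovery benchmarks characterise behaviour under the generator's
  linear Gaussian working model only.
* The per-seed bias of association estimates shares a common component
  within a data set (all features share one intake draw and one censoring
  pattern), so bias summaries averaged over few seeds have wider Monte
  Carlo error than the per-feature standard errors suggest.
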