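---
title: "Methods: candidate-SNP case-control analysis with unweighted risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-SNP case-control analysis with unweighted risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskallele)
```

`riskallele` implements the statistical core of a replication-style
candidate-SNP study of childhood obesity: an ascertained sample of
normal-weight, overweight and obese children is genotyped at a panel
of GWAS-derived loci, and the analysis asks whether the variants
replicate individually, act cumulatively, and add predictive value.
This vignette explains each model, its assumptions, the tunable
parameters, and the numerical and design choices; it quotes no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Phenotyping

BMI is weight (kg) divided by squared height (m). Weight class comes
from an age- and sex-specific cutoff table (bundled: the Chinese
school-age screening reference, ages 7–18; the overweight and obesity
columns are its 85th and 95th BMI percentiles). Two conventions are
ours to fix because screening references do not state them:

- **Age banding.** Rows are half-open integer bands $[k, k+1)$; ages
  are floored, ages at or above the oldest band reuse it, and ages
  below the youngest are `unclassified` with a warning. Flooring (not
  rounding) matches how school-age screening tables are indexed by
  "age at last birthday".
- **Boundaries.** A BMI exactly equal to a cutoff goes to the *higher*
  class, making classification monotone and right-continuous in BMI.

The reference's 15th-percentile lower bound for "normal weight" is not
part of the bundled table (those values are not published alongside the
cutoffs); `normal_lower_cutoff` is an optional column and absent by
default rather than invented.

BMI-SDS uses the LMS (Box–Cox) transform
$z = ((\mathrm{BMI}/M)^L - 1)/(L S)$, with the $L = 0$ limit
$z = \log(\mathrm{BMI}/M)/S$ taken when $|L|$ is below machine
precision$^{1/2}$. Growth references (e.g. the WHO 5–19y BMI-for-age
tables) are external user-supplied data; the bundled
`lms_reference_synthetic.csv` is a smooth synthetic stand-in for tests
and examples only and must not be used for real subjects. Reference
rows are matched on sex and nearest tabulated age; ages outside
coverage are an error naming the subject, not a silent extrapolation.

## Genotype quality control

Dosage is always the count of the panel's *effect allele* (0/1/2,
`NA` missing). VCF input is reconciled against the panel: records
whose REF/ALT match the panel alleles only after base complementation
are accepted with a strand warning (never silently flipped); records
matching neither way are an error; records with more than one ALT are
carried as missing and failed as triallelic.

Exclusions apply per SNP in a fixed order — call rate < 0.95, then
triallelic, then monomorphic, then MAF < 0.01 — so each SNP has exactly
one status and the class counts partition the panel. Call rate is
computed per SNP over all loaded subjects (the attempted-sample
denominator is not recoverable from shipped data).

Hardy–Weinberg screening runs in the **normal-weight group only**:
under a disease model, cases are enriched for risk genotypes, so HWE
is a genotyping-quality check only in controls. The default test is
the 1-df Pearson χ² with expected counts $n(p^2, 2pq, q^2)$ from the
estimated allele frequency and no continuity correction; an exact
(conditional-on-allele-counts) test is available via
`hwe_method = "exact"` for small samples. A nominally significant HWE
p-value in a modest control sample is weak evidence of error on its
own, so HWE failures **flag** rather than exclude by default
(`exclude_hwe = TRUE` switches to exclusion). Monomorphic input is
degenerate (statistic 0, p = 1, flagged) rather than an error.

## Differentiation screen

Between the discovery population (frequency $P_1$) and the study
sample ($P_2$):

$$F_{ST} = \frac{(P_1 - P_2)^2}{(P_1 + P_2)\,(2 - (P_1 + P_2))},$$

symmetric in the two populations and invariant to allele relabelling;
$F_{ST} \ge 0.10$ is read as large differentiation. Two numerical
choices:

- The threshold applies to the **unrounded** value; the reported
  column is rounded half-up to 3 decimals. Values printing as 0.099 or
  0.100 are therefore flagged by their exact magnitude, which is the
  only convention that cannot misflag at the boundary.
- The degenerate case $P_1 = P_2 \in \{0, 1\}$ is defined as 0 (the
  limit of identical frequencies).

For proxy SNPs the stored discovery frequency is the proxy's own
frequency in the discovery population, recorded in the panel file; no
live database lookup happens at run time. Deliberately, no
Weir–Cockerham or Hudson estimator is offered: the screen exists to
mirror published two-frequency tables, which other estimators would
not reproduce.

## Association model

Per SNP, the additive (log-additive) model with the standard
adjustment set — age (years), age² (constructed internally from the
same age column, so it can never disagree), a male indicator, and
reference-coded study-group indicators:

- logistic regression of obese (or overweight) vs normal-weight on
  dosage, fitted by IRLS with convergence tolerance $10^{-12}$ on the
  deviance and up to 50 iterations;
- OLS of BMI-SDS on dosage.

Both arms report Wald 95% CIs and two-sided Wald p-values (the normal
approximation in the linear arm, for consistency); likelihood-ratio
p-values are available with `p_method = "lrt"`. Non-convergence or
exploding estimates (|log OR| > 15 or SE > 100) raise an error naming
quasi-complete separation and suggesting a penalized fit, rather than
returning a meaningless interval. Subjects with a missing dosage are
dropped per SNP (complete-case per test), with `n_used` recorded.

Family-wise control is Bonferroni, $\alpha / K$ with $K$ the number of
SNPs surviving QC. Direction consistency compares the sign of the
study log-OR with the discovery log-OR; an OR of exactly 1 is
boundary — counted inconsistent and flagged indeterminate.

## Genetic risk score

The GRS is the unweighted sum of effect-allele dosages: weighting
requires effect sizes that transfer across ancestries, which is
exactly what such studies are questioning, and published comparisons
find weighting changes little. Missing dosages follow a logged policy:
`mean_impute` (default) substitutes $2\times$EAF of the SNP —
preserving the full sample size, which matters in a fixed-quota
design — while `complete_case` yields integer scores.

The case–control distribution shift is a contingency χ² over integer
score bins (floored), with adjacent bins merged inward from whichever
tail currently has the smaller expected count until all expected
counts reach 5 (the usual Pearson validity rule); df = bins − 1. The
binning rule is our construction — published histograms do not state
one.

Cumulative effects reuse the association arms with the GRS as
exposure. Variance explained is the incremental
$\Delta R^2 = R^2(\text{covariates} + \text{dosages}) -
R^2(\text{covariates})$ with both nested OLS fits on the identical
complete-case subject set, which guarantees $\Delta R^2 \ge 0$ up to
numerical tolerance. Whether a published "variance explained" figure
is covariate-adjusted is often ambiguous, so the unadjusted variant is
available by passing `design = NULL`; the adjusted ΔR² is primary.

## ROC comparison

Both nested logistic models are fitted on the identical subject set
(differing sets are an error, never silently intersected); their
fitted probabilities are the scores. AUC is the rank-sum
(Mann–Whitney) probability that a random case outscores a random
control, ties counted ½; CIs use the DeLong variance, and the paired
DeLong test compares the correlated curves. Comparing a model with
itself has zero variance of the difference; that degenerate case is
defined as p = 1. These are **apparent** (in-sample) AUCs, matching
how such comparisons are usually published — no cross-validation or
optimism correction is applied, and gains should be read accordingly.
The genetic term enters either as the GRS (one column, default) or as
all passing dosages (`roc_mode = "snps"`).

## Power

For the case-control arm, the log-additive penetrance model under HWE
has a convenient closure: if controls carry risk-allele frequency $p$,
case genotypes remain in HWE at the enriched frequency
$p_1 = pR/(1 - p + pR)$ for allelic odds ratio $R$. The per-allele
test then reduces to a two-proportion contrast on $2n_{case}$ vs
$2n_{control}$ alleles, and power is the two-sided normal tail
$\Phi(|\lambda| - z_{1-\alpha/2}) + \Phi(-|\lambda| - z_{1-\alpha/2})$
with $\lambda = (p_1 - p)/SE_1$, $SE_1$ the binomial standard error at
the alternative. For a quantitative trait,
$\lambda = \beta\sqrt{2\,n\,\mathrm{maf}(1-\mathrm{maf})}/\sigma$ with
residual SD $\sigma = 1$ by default (the natural unit for an SDS
outcome; configurable because the residual-variance assumption behind
published figures is usually unstated). `simulate_power_cc()` is the
cross-check authority: it draws genotypes from the same generative
model, applies the per-allele trend test, and its 10,000-replicate
rejection rate agrees with the analytic value within ±0.02 in the test
suite. At the null the analytic power equals α exactly.

## Synthetic cohorts

`simulate_cohort()` generates the structure the analysis assumes,
nothing more:

- genotypes independent across SNPs, HWE at the panel's study
  frequencies (no LD — the panel is one SNP per locus — and no
  population stratification);
- liability BMI-SDS $= \sum_j \beta_j d_j + \gamma_{age}(age -
  \overline{age}) + \gamma_{sex}\,1[\text{male}] + N(0, \sigma)$,
  $\sigma = 1$ by default;
- classes by liability thresholds, default obese $\ge 1.645$ and
  overweight $\ge 1.036$ (normal quantiles of the 95th and 85th
  percentiles, with normal-weight spanning the 15th–85th band) —
  the published Chinese cutoffs cannot be inverted to SDS without the
  underlying Chinese LMS reference, which is not public;
- quota ascertainment: candidates are drawn in batches and accepted
  until each (group × class) quota fills. Defaults reproduce the
  emulated design: ALIR 151/400/386 and CPOOA 456/318/319
  normal/overweight/obese, ages Normal(12.9, 2.7) truncated to
  [7, 19), female fraction 0.40 (the pooled value). An unreachable
  quota errors after a bounded attempt budget instead of spinning.
- anthropometry is realised by inverting the bundled synthetic LMS
  reference at the subject's liability SDS and an age-linear height
  model, so phenotype derivation round-trips in pipeline tests.

What the generator does **not** emulate — and therefore what green
tests do not certify about real data: linkage disequilibrium,
stratification or admixture, genotyping batch artefacts,
class-specific sex ratios (sex enters only through its liability
effect; the default ratio is common to all classes), and the true
recruitment mechanics behind the group quotas. Quota sampling on the
liability scale is a stand-in for the latter. Note that quota
ascertainment *distorts* naive effect estimates relative to the
generating liability betas (by design — the analysis operates on
ascertained samples); parameter-recovery tests therefore use
proportional sampling, where the linear arm is unbiased.
`simulate_case_control()` provides the complementary direct
logistic-disease mode in which the generating per-allele OR is exact.

Determinism: a fixed `seed` plus configuration yields a byte-identical
cohort, and `write_cohort()` emits a provenance sidecar with the full
configuration.

## Verification strategy and problem sizes

Every estimator is checked against an independent oracle written from
the definition: Newton–Raphson for the logistic MLE, closed-form
normal equations for OLS (200 random small instances each, agreement
to $10^{-6}$), all-pairs enumeration for AUC (exact at $n \le 50$),
and first-principles Pearson sums for the contingency tests. Error
rates are verified empirically at the scales the suite can afford on
one CPU: HWE flag rate over 2,000 simulated control samples of 600,
per-SNP type-I error over 1,000 null ascertained cohorts of 120
(two SNPs each), CI coverage of the liability-β recovery over 400
proportional-sampling cohorts of 400, and the ~0.03-AUC-gain detection
regime over 200 cohorts of 1,300. The whole suite runs in about two
minutes.

## Known limitations

- Wald inference throughout; for rare alleles or near-separation,
  penalized likelihood (not provided) is the right tool — the package
  errors rather than approximates there.
- The power model is one defensible reading of "Quanto-style"
  calculations; different baseline-risk conventions shift third-decimal
  results, which is why the simulation cross-check is the stated
  authority.
- Apparent AUC overstates out-of-sample discrimination; no optimism
  correction is attempted.
- The bundled LMS table is synthetic; BMI-SDS values for real children
  require the genuine growth reference for their population.
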