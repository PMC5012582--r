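---
title: "Methods: dose-response trends, meta-analysis, and two-sample Mendelian randomization"
author: "trendmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response trends, meta-analysis, and two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendmr)
```

# Scope

`trendmr` implements the analytic chain used to relate adult height to cancer
risk from summary data, with every effect expressed per 10 cm of height:

1. conversion of per-quantile categorical relative risks into a continuous
   linear trend (Greenland--Longnecker pseudo-counts + generalized least
   squares, with Il'yasova-style scores for open-ended categories);
2. inverse-variance-weighted fixed-effect and REML random-effects pooling
   with Cochran's Q, $\tau^2$, $I^2$, and a Q-between subgroup test;
3. funnel-plot asymmetry diagnostics (Begg rank correlation, Egger
   regression);
4. two-sample summary-statistic Mendelian randomization (MR): allele
   harmonization, the IVW estimator, MR-Egger pleiotropy regression,
   pleiotropy-exclusion sensitivity analysis, and the Burgess power
   approximation.

Because the consortium-level inputs such analyses consume are not
redistributable, the package ships generators
(`simulate_mr_summary()`, `simulate_study_collection()`,
`simulate_cohort_study()`) that produce synthetic inputs with the statistical
structure each stage assumes. All validation in the test suite is
simulation-based parameter recovery and calibration against that structure.

# Dose-response trend conversion

A cohort publishing quantile-specific relative risks $RR_i$ against a shared
reference category provides correlated contrasts: every $\log RR_i$ contains
the same reference-group sampling error. Treating them as independent
overstates the information in the trend. The Greenland--Longnecker method
reconstructs that correlation from the published table:

* **Scores** (`assign_scores()`): supplied category means/medians are used
  verbatim; closed intervals without one get their midpoint; an open-ended
  extreme interval gets its closed boundary plus/minus half the width of the
  adjacent closed interval. The open-interval rule is deterministic and uses
  only the published bounds.
* **Pseudo-counts** (`gl_pseudo_counts()`): per-level pseudo cases are fitted
  so crude level-vs-reference effect measures equal the *adjusted* RRs while
  the total case count and per-level denominators match the observed margins
  exactly. The margin equation is solved by damped Newton iteration on the
  reference cell (tolerance $10^{-10}$, 100 iterations maximum; steps that
  would push a pseudo-count out of its admissible range are halved). For
  risk-ratio and rate designs the non-reference cells are linear in the
  reference cell; odds-ratio designs are genuinely nonlinear.
* **Covariance** (`gl_covariance()`): design-specific formulas on the pseudo
  table, e.g. cumulative incidence
  $\mathrm{var}_i = 1/A_i - 1/N_i + 1/A_0 - 1/N_0$ and
  $\mathrm{cov}_{ij} = 1/A_0 - 1/N_0$. A non-positive-definite result is
  treated as evidence the published numbers are mutually inconsistent and
  raised as an error.
* **Trend** (`gls_trend()`): GLS through the reference point,
  $\hat\beta = x^\top C^{-1} y / x^\top C^{-1} x$,
  $\mathrm{se} = (x^\top C^{-1}x)^{-1/2}$, with $x_i$ the score contrasts.
  Only contrasts matter; the fit is invariant to shifting all scores.

When per-level counts are unavailable the package falls back to
variance-weighted least squares with variances back-calculated from the
published CIs (`method = "independence_fallback"`), with a warning. Because
the shared reference induces *positive* covariance among the contrasts, this
fallback **understates** the standard error relative to the GL fit — that
understatement is the method's reason to exist, and the property suite
asserts the inequality in this direction.

Effects are converted between exposure increments by linear scaling of the
log effect and its se (`rescale_estimate()`); squaring an RR corresponds to
doubling the increment.

# Meta-analysis

Fixed-effect pooling uses weights $w_i = 1/se_i^2$. Heterogeneity is
summarized by Cochran's $Q$ (chi-square, $k-1$ df),
$I^2 = \max(0, (Q - df)/Q)$, and the REML estimate of the between-study
variance $\tau^2$. The REML solver is Fisher scoring with step-halving
(tolerance $10^{-8}$ on $\tau^2$, floor at zero, boundary solution returned
when the score at zero is non-positive); it agrees with a dense grid search
to $10^{-6}$ and with `metafor::rma(method = "REML")` to its tolerance.
Random-effects pooling re-weights by $1/(se_i^2 + \hat\tau^2)$ and reports
Wald-normal confidence limits by default, matching the era of software the
pooled estimates in this literature were computed with; a Knapp--Hartung
flag (`knha = TRUE`) is available. Subgroup differences are tested with a
Q-between statistic on the pooled subgroup estimates (inverse-variance
weights, $J-1$ df); meta-regression is out of scope. Studies contributing
several strata (e.g. sex-specific rows) are treated as independent
estimates, as forest plots in this literature do.

# Publication-bias diagnostics

`begg_test()` standardizes deviates
$u_i = (\beta_i - \beta_{FE})/\sqrt{se_i^2 - se_{FE}^2}$ and rank-correlates
them with the sampling variances; the normal approximation subtracts 1 from
$|P - Q|$ (continuity correction). `egger_bias_test()` regresses
$\beta_i/se_i$ on $1/se_i$ by unweighted OLS (the classical form) and
t-tests the intercept with $k-2$ df.

Two calibration facts are documented deliberately:

* Begg's test is conservative, and *how* conservative depends on the spread
  of study precisions. At $k = 20$ with standard errors spanning 0.1--0.3
  its empirical size is about 0.045; when one very precise study dominates
  the pooled mean (se spanning 0.02--0.3) the deviates become strongly
  negatively correlated and the size drops to about 0.02. The calibration
  test uses the moderate-spread condition.
* Two-sided significance selection applied to a **null** effect truncates
  the funnel symmetrically. Egger's regression still over-rejects under that
  truncation (the surviving errors are bimodal), but Begg's *signed* rank
  correlation has essentially no power against symmetric truncation. The
  Begg positive control therefore uses a directional scenario (a genuine
  positive effect plus significance selection), where surviving small
  studies are the extreme positive ones and the rank correlation is large.

# Two-sample Mendelian randomization

`harmonize()` aligns outcome to exposure effect alleles: swapped alleles
flip the outcome beta's sign and complement its frequency; strand flips are
complemented and re-matched; palindromic (A/T, C/G) variants are dropped by
default or oriented by allele frequency when both frequencies are at least
0.08 from 0.5 (`palindromic = "freq"`); variants missing from the outcome or
with imputation quality below the threshold (default 0.3; a 0.7 consortium
cutoff is supported) are dropped and counted.

The IVW estimator is implemented exactly in its summary-statistic form
$$\hat\beta_{IVW} = \frac{\sum_g X_g Y_g \sigma_{Y_g}^{-2}}
                         {\sum_g X_g^2 \sigma_{Y_g}^{-2}},\qquad
  se(\hat\beta_{IVW}) = \Big(\sum_g X_g^2 \sigma_{Y_g}^{-2}\Big)^{-1/2},$$
i.e. weighted least squares of outcome on exposure betas through the origin.
Exposure-side uncertainty is carried in the data model for diagnostics but
deliberately does not enter the weights, matching the estimator as printed
in the applied literature; no overdispersion scaling is applied. MR-Egger
adds a free intercept (the average directional pleiotropic effect) after
orienting every SNP so $X_g \ge 0$, with $t_{n-2}$ inference. With the
intercept constrained to zero the Egger slope reproduces IVW exactly, which
the tests assert.

Per-10-cm standardization is an explicit user-supplied scale
(`standardize_or(result, exposure_unit_cm)`): the height SD underlying
per-SD GWAS betas is not something the package can know, so it is never
assumed.

Power uses the Burgess non-centrality approximation with
$b = \sqrt{N r^2 \varphi(1-\varphi)}\,|\log OR|$ and
$\mathrm{power} = \Phi(b - z_{1-\alpha/2}) + \Phi(-b - z_{1-\alpha/2})$,
where $\varphi$ is the case fraction. The second term matters only near the
null, where it makes the two-sided power equal $\alpha$ rather than
$\alpha/2$. `or_alt` is interpreted per SD of the exposure, the scale on
which $N r^2 \varphi (1-\varphi)$ is the IVW information; the empirical
rejection rate of the full simulate--harmonize--IVW pipeline matches the
formula within Monte-Carlo error.

# The synthetic-data generators

`simulate_mr_summary()` draws allele frequencies uniformly on the MAF range,
effect magnitudes from a half-normal **truncated below at half its scale**,
and rescales them so $\sum_g 2p_g(1-p_g)\beta_g^2 = r^2 \sigma_h^2$ holds
exactly. The truncation reflects that a real instrument contains only
genome-wide-significant loci: an untruncated half-normal puts mass at zero,
and such near-null SNPs get sign-flipped by exposure-side noise under the
$X_g \ge 0$ MR-Egger orientation, biasing the intercept toward zero — an
artefact of an unrealistic effect-size distribution, not of the estimator.
The effect allele is coded as the height-increasing allele, the usual
instrument convention, so the Egger intercept identifies the mean
pleiotropic effect directly. Outcome standard errors use the balanced
logistic approximation
$\sigma_{Y_g} = \sqrt{(2p_g(1-p_g))^{-1}(1/n_{cases} + 1/n_{controls})}$,
the same approximation the power formula rests on. Pleiotropic effects are
drawn independently of exposure effects (InSIDE) unless `pleiotropy_cor`
is set, which deliberately violates InSIDE for negative controls.

Defaults emulate the motivating study design: 423 SNPs, $r^2 = 0.16$,
exposure GWAS of 253,288, prostate-scale outcome GWAS (14,160 cases /
12,724 controls). The population height SD is not identified by per-10-cm
summary estimates, so it is an explicit parameter; the default 6.5 cm is a
typical sex-specific adult value. The MR-Egger recovery simulations use an
exposure GWAS of 1.5 million — the scale of current height GWAS — because
the Egger slope is consistent only when exposure-side measurement error is
negligible (the NOME condition); at 253k that error attenuates the slope by
roughly 1.5% of its value, visible at Monte-Carlo precision though
immaterial in applications.

`simulate_study_collection()` draws study effects
$N(\beta, \tau^2)$ plus sampling noise, with optional significance
selection: a study with two-sided $p > 0.05$ survives with probability
`selection_prob`. `simulate_cohort_study()` draws heights normally, applies
a log-linear risk model (relative risks, matching the pooling scale —
configurations whose risk leaves $(0,1)$ within $\pm 4$ SD are rejected at
construction), cuts empirical quantiles with open-ended extreme categories,
and reports crude RRs with Woolf-type CIs and category-mean scores.

What the generators do **not** emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium between instrument SNPs,
winner's-curse bias in discovery betas, population stratification, sample
overlap between exposure and outcome GWAS, covariate-adjusted (rather than
crude) categorical RRs, and non-linear dose-response. The GL stage is
validated on tables whose adjusted and crude RRs coincide structurally;
its behaviour on strongly confounded published tables is exercised only
through the fixed-point and margin-preservation contracts.

# Numerical choices

* CI-to-se back-calculation divides the log-CI width by $3.92$; CIs
  asymmetric on the log scale (half-width ratio $> 1.1$) trigger a warning
  and use the average half-width.
* Info-score filtering is strictly-below (`info < threshold` excluded), so a
  variant exactly at the cutoff is kept.
* Newton (pseudo-counts): tolerance $10^{-10}$, max 100 iterations, damped
  steps; REML: Fisher scoring, tolerance $10^{-8}$, max 100 iterations,
  convergence report attached as attributes.
* All p-values are two-sided; IVW uses Wald normal, Egger-type tests
  $t_{k-2}$.
* Simulation sizes in the shipped suite (chosen to give Monte-Carlo
  standard errors well inside the asserted bands): 1,000 replicates for IVW
  coverage, 500 for Egger and trend recovery, 2,000 for REML recovery,
  5,000 for each type-I calibration.

# Known limitations

Only fixed-effect IVW is provided (no weighted-median or mode estimators,
no multiplicative overdispersion); the GL implementation assumes a linear
trend and a single shared reference category; the independence fallback
should be read as a lower bound on uncertainty; and the Begg test's
conservatism under strong precision heterogeneity means a non-significant
Begg p-value there carries little information.
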