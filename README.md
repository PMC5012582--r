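# trendmr

Tools for estimating the association between adult height and cancer risk
from summary data, combining three complementary layers of evidence:

* **Dose-response trend conversion** — published per-quantile relative risks
  are converted into a continuous log-RR per 10 cm via the
  Greenland–Longnecker method: pseudo-counts are fitted so crude
  level-vs-reference contrasts match the adjusted RRs while preserving the
  observed margins, the induced covariance among contrasts (they share a
  reference group) is reconstructed, and a generalized-least-squares line
  through the reference point gives the trend. Open-ended quantiles are
  scored by the Il'yasova rule (boundary ± half the adjacent interval
  width).
* **Meta-analysis** — inverse-variance-weighted fixed-effect and REML
  random-effects pooling with Cochran's Q, τ², I², Q-between subgroup
  homogeneity tests, forest/funnel tables, and Begg and Egger
  funnel-asymmetry tests.
* **Two-sample Mendelian randomization** — allele harmonization of exposure
  and outcome GWAS summary statistics, the IVW estimator

  β̂_IVW = Σ X_g Y_g σ_Yg⁻² / Σ X_g² σ_Yg⁻²,  se(β̂_IVW) = (Σ X_g² σ_Yg⁻²)^(-1/2),

  MR-Egger pleiotropy regression (slope = causal estimate, intercept =
  average directional pleiotropy), pleiotropy-exclusion sensitivity
  analysis, per-10-cm standardization, and instrument power by the Burgess
  non-centrality approximation.

Consortium-level inputs (a GIANT-style height instrument, GAME-ON-style
cancer case-control GWAS, cohort quantile tables) are not redistributable,
so the package ships synthetic-data generators with the statistical
structure each stage assumes; every estimator is validated by parameter
recovery and calibration against them. The intended audience is
epidemiologists and biostatisticians reproducing or extending
anthropometric-trait MR and meta-analyses.

## Worked example

A 423-SNP height instrument (16% of height variance explained) is
harmonized against an outcome GWAS missing 77 of the variants, leaving the
346-SNP instrument; a causal log-OR of 0.02 per cm was simulated.

```r
library(trendmr)

sim <- simulate_mr_summary(mr_sim_config(n_snps = 423, causal_beta = 0.02,
                                         seed = 42))
inst <- harmonize(sim$exposure, sim$outcome[-(1:77), ])
inst
#> Harmonized instrument: 346 SNPs retained of 423 exposure SNPs
#>   dropped: 77 missing from outcome, 0 low imputation quality, 0 palindromic, 0 irreconcilable

standardize_or(ivw_estimate(inst), exposure_unit_cm = 1)
#> MR IVW estimate from 346 SNPs
#>   causal log-OR 0.20427 (SE 0.05217) per 10 cm of exposure, p = 9.018e-05
#>   OR per 10 cm: 1.2266 (95% CI 1.1074, 1.3587)
```

The estimate (OR 1.23 per 10 cm) recovers the simulated truth
(exp(10 × 0.02) = 1.2214) within its confidence interval. The same
pipeline covers the observational layers — a cohort quantile table is
reduced to a trend, and study-level estimates are pooled:

```r
gl_trend(simulate_cohort_study(cohort_sim_config(seed = 42)))
#> Linear trend (gl): log-RR 0.09204 (SE 0.01589) per 10 cm
#>   RR per 10 cm: 1.0964 (95% CI 1.0628, 1.1311)

studies <- simulate_study_collection(
  study_sim_config(n_studies = 25, true_beta = log(1.12), tau2 = 0.003,
                   seed = 42))
random_effects_meta(studies)
#> Random-effect meta-analysis of 25 studies
#>   RR 1.1160 (95% CI 1.0712, 1.1626); log-RR 0.10972 (SE 0.02087)
#>   Q = 61.6421 (df = 24, p = 3.732e-05); tau2 = 0.00568; I2 = 61.1%
```

The cohort was generated under RR 1.10 per 10 cm and the study collection
under RR 1.12; both are recovered. Instrument power at consortium scale
(14,160 cases, 12,724 controls, r² = 0.16) to detect a 9% risk increase:

```r
mr_power(14160, 12724, r2 = 0.16, or_alt = 1.09)
#> [1] 0.805657
```

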