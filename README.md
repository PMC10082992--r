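# clockmr

Bidirectional two-sample Mendelian randomization (MR) between epigenetic
age acceleration (EAA) and kidney function, as a reusable R package.

## The scientific problem

Epigenetic clocks (Horvath-based intrinsic EAA, HannumAA, PhenoAA,
GrimAA) predict biological age from DNA methylation; their residual over
chronological age — age acceleration — is associated cross-sectionally
with kidney function (estimated glomerular filtration rate, eGFR, and
chronic kidney disease, CKD). Whether accelerated epigenetic aging
*causes* kidney-function decline, or the reverse, cannot be resolved by
observational association. Two-sample MR addresses this by using
genome-wide-significant SNPs as instrumental variables: per-SNP effects
on the exposure (γ_j, from one GWAS) are combined with effects on the
outcome (Γ_j, from an independent GWAS) to estimate the causal effect β.

`clockmr` implements the full analysis stack for this design, in both
directions (EAA → kidney function and kidney function → EAA), for anyone
with GWAS summary statistics in tab-delimited form:

* **Data model & harmonization** — validated summary-statistic tables;
  allele alignment with strand-flip resolution and frequency-based
  handling of palindromic SNPs; orientation toward increasing exposure.
* **Instrument construction** — significance filtering with greedy LD
  clumping (500-kb window, r² < 0.1, P < 5×10⁻⁸ by default),
  confounder exclusion lists with LD proxies, dual-marker refinement for
  composite kidney instruments (Bonferroni 0.05/n index SNPs), Steiger
  directionality filtering, and F / I²_GX / R² strength diagnostics.
* **Estimators** — per-SNP Wald ratios; inverse-variance-weighted (IVW)
  regression through the origin, `β̂ = Σ wⱼγⱼΓⱼ / Σ wⱼγⱼ²` with
  `wⱼ = 1/se(Γⱼ)²` and multiplicative random-effects SE inflation
  `√max(1, Q/(J−1))`; MR-Egger with intercept (directional-pleiotropy
  test, t inference on J−2 df); bootstrap weighted median; Rücker model
  selection (switch to MR-Egger iff the Q−Q′ difference has P < 0.05
  *and* the Egger intercept has P < 0.1); MR-PRESSO global, outlier and
  distortion tests; leave-one-out analysis; aggregate Steiger
  directionality test.
* **Multivariable MR & mediation** — two-exposure IVW and the
  difference method (indirect = total − direct; proportion mediated =
  indirect/total).
* **Allele-score MR** — CKD-EPI 2012 creatinine–cystatin eGFR, CKD
  status (eGFR < 60), weighted allele scores from dosages, and
  covariate-adjusted linear/logistic association models (Model 1: age,
  sex, 10 PCs; Model 2: + clinical covariates).
* **Power** — closed-form two-sided power for continuous and binary
  outcomes from n, instrument R², effect size and case fraction.
* **Pipeline & synthetic data** — an orchestrated bidirectional run with
  Benjamini–Hochberg FDR across the clock measures and deterministic
  TSV/JSON reports, plus a fully seeded generator of two-sample summary
  statistics and individual-level cohorts with known ground truth
  (causal effect, pleiotropy regime, mediation, LD blocks).

## Worked example

Simulate an EAA-like instrument (25 SNPs explaining 3% of the exposure,
GWAS sizes matching a 34,710-participant exposure meta-analysis and a
567,460-participant outcome consortium) with a small negative causal
effect, then run the summary-MR stack:

```r
library(clockmr)

cfg <- sim_config(J = 25, n_exp = 34710, n_out = 567460,
                  beta_true = -0.002, r2_gx = 0.03)
sim <- simulate_two_sample(cfg, seed = 2024)

h <- harmonize(sim$exposure, sim$outcome)
instrument_strength(h)
#> Instrument strength diagnostics
#>   SNPs: 25
#>   F-statistic: mean 41.8, min 0.0
#>   I2_GX: 93.8% (Q_GX = 386.37)
#>   Variance explained in exposure: 3.00%

mr_rucker(h)
#> Ruecker model selection
#>   chosen method: IVW
#>   Q - Q' difference p = 0.776 (threshold 0.05) and Egger intercept
#>   p = 0.779 (threshold 0.1): no significant improvement from the Egger
#>   intercept; IVW retained
#>
#> Selected estimate:
#> Two-sample MR estimate (IVW)
#>   exposure -> outcome
#>   beta = -0.006641 (95% CI -0.02167 to 0.008391), p = 0.387, J = 25

scale_effect(mr_rucker(h)$estimate, factor = 5)   # per 5-unit exposure
#> Two-sample MR estimate (IVW)
#>   beta = -0.0332 (95% CI -0.1084 to 0.04196), p = 0.387, J = 25

steiger_directionality(h)
#> Steiger directionality test
#>   instrument r2: exposure 0.0300 vs outcome 0.000042
#>   verdict: valid (z = 30.45, p = 1.28e-203)
```

Reading the output: no directional pleiotropy is detected (Egger
intercept P = 0.78), so the Rücker framework retains the
random-effects IVW estimate; the instrument explains vastly more
variance in the exposure than in the outcome, so the assumed causal
direction is supported; the per-5-unit scaled effect (−0.033, 95% CI
−0.108 to 0.042) is the reporting convention for clock-acceleration
exposures. The difference-method mediation decomposition works the same
way from a univariable total effect and a multivariable (mediator-
conditional) direct effect:

```r
mediation_difference(c(-3.14, 1.066), c(-1.95, 1.2))
#> Difference-method mediation decomposition
#>   total:       -3.14 (95% CI -5.229 to -1.051)
#>   direct:      -1.95 (95% CI -4.302 to 0.402)
#>   indirect:    -1.19 (95% CI -4.336 to 1.956)
#>   proportion mediated: 38%
```

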