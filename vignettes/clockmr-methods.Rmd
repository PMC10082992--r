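---
title: "Methods: bidirectional two-sample MR for epigenetic aging and kidney function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample MR for epigenetic aging and kidney function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockmr)
```

## The design and its assumptions

Two-sample Mendelian randomization estimates the causal effect of an
exposure (here an epigenetic age-acceleration measure, or log-eGFR in
the reverse direction) on an outcome from two independent GWAS: per-SNP
exposure associations $\hat\gamma_j \pm se(\hat\gamma_j)$ and outcome
associations $\hat\Gamma_j \pm se(\hat\Gamma_j)$. Under the three
instrumental-variable assumptions — the SNPs are associated with the
exposure (relevance), independent of confounders (independence), and
affect the outcome only through the exposure (exclusion restriction) —
the per-SNP Wald ratio $\hat\Gamma_j/\hat\gamma_j$ is a consistent
estimate of the causal effect $\beta$, and the estimators below pool
the $J$ ratios with different robustness/power trade-offs.

`clockmr` enforces relevance through genome-wide significance filtering
and strength diagnostics, approximates independence through exclusion
lists (stand-ins for phenotype-database screens), and probes the
exclusion restriction with the Egger intercept, MR-PRESSO and the
Rücker framework. Reverse causation of the instrument itself is
screened by Steiger filtering.

## Harmonization

Summary tables are matched by SNP id (both source GWAS for this design
report rsIDs; positions are used only for clumping). Outcome records
whose alleles are swapped relative to the exposure have their beta
negated and frequency complemented; for non-palindromic variants a
strand flip (A↔T, C↔G) is attempted before declaring a mismatch.
Palindromic variants carry no strand information in their labels, so
they are aligned by minor-allele frequency — and dropped as ambiguous
when either frequency lies within `0.5 ± palindrome_eaf_window` or is
missing. The window defaults to **0.08** (ambiguous in [0.42, 0.58]):
the rule is standard but its width is a convention, and 0.08 is the
width most commonly used by harmonization tools. Finally all pairs are
oriented so the exposure effect is non-negative ("toward increasing
exposure"), which fixes the sign convention of every downstream report.
Dropped SNPs stay in the set with a reason, so retained + dropped =
matched always holds and audits are possible.

## Instrument construction

* **Clumping** (`select_and_clump`): greedy by ascending p-value;
  defaults 500-kb window, r² ceiling 0.1, threshold 5×10⁻⁸. Ties are
  broken by (chr, pos, snp) so results are independent of row order. LD
  is supplied by the user as sparse pairs; absent pairs count as r² = 0
  with a warning, since sparse LD extracts are the norm.
* **Exclusion lists** (`apply_exclusion_list`): removes listed SNPs and
  any instrument SNP with r² > 0.8 to a listed SNP (the conventional
  proxy ceiling).
* **Dual-marker refinement** (`dual_marker_refine`): for kidney
  instruments, creatinine-eGFR index SNPs must also associate with a
  second kidney marker at Bonferroni significance (0.05 divided by the
  number of index SNPs, e.g. 256). Whether the secondary effect must
  also have the expected *direction* is not pinned down by the source
  description; it is exposed as `require_direction` (default `TRUE`,
  with a `marker = "concordant"/"discordant"` switch for markers such
  as cystatin-eGFR vs BUN that move with and against kidney function
  respectively).
* **Steiger filtering** (`steiger_filter`): per SNP, variance explained
  is recovered from the t-statistic, $r^2 = t^2/(t^2+n-2)$, and the
  implied correlations are compared with the Fisher-z statistic. The
  default mode drops SNPs whose point estimates satisfy
  $r^2_{exp} \le r^2_{out}$, reporting the z-test p-value; a
  `"significance"` mode additionally requires p < α. The point-estimate
  default matches the common filtering convention while the test
  statistic is reported for directionality claims. For binary outcomes
  the same t-based formula on the reported N is used — a documented
  approximation.
* **Strength** (`instrument_strength`): per-SNP F statistics (weak
  instrument flagged at mean F < 10), the I²_GX statistic for the
  no-measurement-error assumption relevant to MR-Egger, and total
  variance explained.

## Estimators

With weights $w_j = 1/se(\hat\Gamma_j)^2$:

* **IVW**: $\hat\beta = \sum w_j\hat\gamma_j\hat\Gamma_j / \sum
  w_j\hat\gamma_j^2$; fixed-effect SE $(\sum w_j\hat\gamma_j^2)^{-1/2}$.
  The default is the multiplicative random-effects model: the SE is
  inflated by $\sqrt{\max(1, Q/(J-1))}$ — floored at 1 so overdispersion
  can never *increase* precision. Inference is normal-theory.
* **MR-Egger**: the same weighted regression with an intercept, after
  orienting each SNP so $\hat\gamma_j \ge 0$ (both betas flipped
  together). The intercept estimates directional pleiotropy; inference
  uses the t distribution on J−2 df because small-J intercept tests are
  anticonservative under normal theory. Random-effects inflation by
  $\sqrt{\max(1, Q'/(J-2))}$.
* **Weighted median**: inverse-variance-weighted median of the Wald
  ratios (consistent when ≥ 50% of the weight comes from valid
  instruments), with linear interpolation of the cumulative-weight
  midpoints at probability 0.5 and a parametric bootstrap SE (default
  1,000 draws; the seed is mandatory in pipeline runs so reports are
  bit-reproducible).
* **Rücker selection** (`mr_rucker`): MR-Egger replaces IVW as the
  primary method only when the heterogeneity difference Q − Q′ is
  significant against χ²₁ at P < 0.05 *and* the Egger intercept has
  P < 0.1. Both fits and the decision rationale are always returned.
* **MR-PRESSO** (`mr_presso`): leave-one-out IVW residual contributions
  are compared against `n_sim` parametric simulations of the
  no-pleiotropy null; the global and per-SNP p-values use the add-one
  estimator $(1+k)/(1+n_{sim})$ so they are never exactly zero; per-SNP
  p-values are Bonferroni-adjusted by J; the distortion test compares
  the raw-minus-corrected shift against removals of random subsets of
  the outlier count (two-sided). All randomness flows from one seed and
  the caller's RNG state is restored.
* **Wald ratio SEs** are first-order delta method,
  $se(\hat\Gamma_j)/|\hat\gamma_j|$; the second-order term is omitted.

Rescaling invariance (γ → cγ scales estimates by 1/c and leaves Q, Q′
and p-values unchanged) and exact agreement with generic weighted-least-
squares oracles are enforced by tests.

## Multivariable MR and mediation

`mvmr_fit` regresses $\hat\Gamma_j$ on $(\hat\gamma_j, \hat\delta_j)$
jointly without intercept (weights $w_j$), giving the exposure's direct
effect conditional on the mediator. SEs come from the weighted normal
equations inflated by $\sqrt{\max(1, RSS_w/(J-2))}$; an exactly null
mediator column reduces the model to univariable IVW, and collinear
designs are rejected. The difference method then gives
indirect = total − direct and proportion mediated = indirect/total. The
indirect SE uses the independence approximation
$\sqrt{se_{total}^2 + se_{direct}^2}$ — the covariance between the two
estimates (whose samples overlap) is ignored; a parametric bootstrap
for the proportion's interval is available via `n_boot`. Mediator
instrument derivation is out of scope: mediator summary statistics are
an input.

## Allele-score MR and the CKD-EPI equation

eGFR uses the 2012 combined creatinine–cystatin C equation with
sex-specific knots (κ = 0.7/0.9, α = −0.248/−0.207) and the 0.995^age
term; the race coefficient is configurable and off by default. CKD is
strictly eGFR < 60 ml/min/1.73 m², and the log transform is the natural
log (the base is a convention the source leaves unstated). The allele
score is the dosage-weighted sum of per-allele effect sizes,
standardized by z-score: "standard normal transformed" is read as the
linear-score convention; a rank-based inverse-normal transform is
provided (`rank_inverse_normal`) for users who prefer it. Associations
use `lm` (log-eGFR, per 1 SD of score) or logistic `glm` (CKD). Binary
effects are reported as odds ratios — the described model is logistic
regression, so odds ratios are what it produces. Model 1 adjusts for
age, sex and 10 ancestry PCs; Model 2 adds hypertension, diabetes,
hypercholesterolemia, lipid measures, BMI and smoking.

## Power

For standardized exposure and outcome, the two-sided power of the IVW
Wald test is $\Phi(-z_{1-\alpha/2} + \sqrt{ncp}) +
\Phi(-z_{1-\alpha/2} - \sqrt{ncp})$ with $ncp = n\,R^2_{gx}\,b^2$
(continuous) or $n\,R^2_{gx}\,K(1-K)\log(OR)^2$ (binary, case fraction
K). At the null this reduces to α exactly. Because the source restates
only the calculator's inputs, the implementation is pinned by a
Monte-Carlo oracle rather than transcribed constants: the package's own
generator simulates summary statistics at the stated parameters and the
IVW rejection rate is compared with the closed form on a 3×3×3 grid
(n ∈ {5·10⁴, 10⁵, 2·10⁵} × R² ∈ {0.01, 0.02, 0.04} × b ∈ {0.02, 0.04,
0.06}, 2,000 replicates per cell). The oracle uses fixed-effect IVW —
the closed form *is* the fixed-effect, no-pleiotropy approximation, and
the grid simulates no pleiotropy — and a J = 10 instrument, the scale
of the smaller clock instruments, which keeps per-SNP F high enough
that the no-measurement-error assumption behind the closed form holds
within the comparison tolerance.

## The synthetic-data generator

`simulate_two_sample` draws minor-allele frequencies uniformly on the
configured range, half-normal per-allele exposure effects rescaled so
the instrument explains exactly `r2_gx` of a unit-variance exposure
(effects aligned positive, matching the "toward increasing exposure"
convention), and plants: a causal effect `beta_true`; horizontal
pleiotropy $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha)$ on a
`prop_invalid` fraction of SNPs (balanced or directional; a
`correlated` flag routes it through instrument strength to violate
InSIDE); an optional mediator path X → M → Y whose SNP-level mediator
effects are sign-symmetric (alleles aligned toward increasing exposure
carry no systematic mediator direction — a directional choice here
would masquerade as pleiotropy in the total-effect fit); and binary
outcomes through a logistic link whose intercept is solved numerically
for the target prevalence. Summary statistics come either from two
disjoint simulated samples (`mode = "individual"`, with an overlap knob
to study one-sample bias) or from their asymptotic sampling
distributions (`mode = "asymptotic"`), which the tests verify agree at
matched parameters.

`simulate_individual` additionally builds an individual-level cohort:
dosages Binomial(2, f) (optionally Gaussian-copula LD blocks),
demographics, clinical covariates and synthetic PCs, and biomarkers
constructed by *exact inversion* of the CKD-EPI equation at a target
eGFR that carries the planted allele-score effect — so derived
phenotypes are internally consistent by construction. The baseline
log-eGFR distribution (log 80, SD ≈ 0.18, age slope −0.005/yr, ages
40–70) is chosen so CKD prevalence lands near 8%, enough cases for the
logistic models at moderate n.

What the generator does **not** emulate: realistic genome-wide LD maps,
assortment or population stratification (the PCs are pure noise),
methylation data or clock construction (clocks enter only as summary
statistics), and real CKDGen/EAA effect-size spectra. Passing tests
therefore demonstrate correctness of the estimators and pipeline under
the stated generative model, not reproduction of the source study's
real-data estimates, which require the external summary statistics.

## Numerical choices and problem sizes

* Random-effects floors at 1 (both IVW and Egger/MVMR): overdispersion
  never tightens an interval.
* Clumping tie-breaks, p-value strictness (`p < threshold`), and the
  strict CKD threshold (`eGFR < 60`) are fixed as documented so runs
  are deterministic.
* Empirical p-values use the add-one estimator; every stochastic
  routine takes a seed and restores the caller's RNG state.
* Calibration and recovery experiments run at J = 50, n = 50,000 per
  sample, instrument R² = 3% (within the "up to 4%" range the source
  reports for clock instruments), 1,000 replicates, asymptotic mode;
  model-selection, robustness and directionality experiments use
  J = 20–50 instruments at the same sample sizes with 200 replicates;
  MR-PRESSO checks use 20 valid SNPs plus one lead SNP displaced by 10
  outcome-SEs, 50 replicates of 1,000 simulations. These sizes mirror
  the source design's instrument scales (4–133 SNPs) and GWAS sizes
  (tens to hundreds of thousands).

## Known limitations

* The Egger intercept's power to certify directional pleiotropy in a
  *mixture* regime (a fraction of invalid SNPs sharing a directional
  mean) is intrinsically capped: the mixture's between-SNP variance
  inflates the random-effects intercept SE proportionally to the
  planted mean, so the intercept z-statistic saturates near
  $\sqrt{J\,p/(1-p)}$ (p = invalid fraction) however large the planted
  pleiotropy. With 30% invalid SNPs and J = 50 the Rücker switch to
  MR-Egger is therefore a coin-flip-to-moderate-probability event even
  when the Q − Q′ test fires reliably; the internal reorientation of
  noise-negative weak SNPs further attenuates the intercept. This is a
  property of the method, reproduced faithfully here, not an
  implementation artifact (both fits match generic WLS oracles to
  10⁻¹⁰).
* The weighted median's finite-sample shift under one-sided invalid
  instruments scales with the Wald-ratio noise and does not vanish
  relative to its own Monte-Carlo SD as samples grow; robustness
  comparisons in the tests therefore use instrument sizes at the scale
  of the clock instruments (J ≈ 20).
* Indirect-effect SEs ignore total/direct covariance (documented
  approximation; bootstrap available).
* Binary-trait Steiger r² uses the continuous-trait formula on reported
  N.
* Sample overlap between the two GWAS biases toward the observational
  association; the generator exposes an overlap knob, but the
  estimators make no correction.
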