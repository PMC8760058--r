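---
title: "Methods: Mendelian randomisation and circadian misalignment in chronomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomisation and circadian misalignment in chronomr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronomr)
```

## The scientific question and the causal design

Evening chronotype is observationally associated with depression, anxiety
and lower wellbeing, but chronotype is also entangled with socioeconomic
position, employment, BMI and smoking, and depression itself disturbs
sleep timing. `chronomr` implements Mendelian randomisation (MR): genetic
variants associated with diurnal preference are used as instrumental
variables, exploiting the random assortment of alleles at conception. A
valid instrument must (1) associate robustly with the exposure, (2) be
independent of exposure–outcome confounders, and (3) affect the outcome
only through the exposure. Assumption (3) — no horizontal pleiotropy — is
the fragile one, and the estimator suite is chosen so that each method
fails under a different violation pattern.

The second arm of the package quantifies *behavioural circadian
misalignment* directly from actigraphy-derived sleep episodes via the
Composite Phase Deviation (CPD) metric, and models mental-health outcomes
on CPD observationally.

## Genetic risk scores

With harmonised per-allele morningness weights $\beta_i > 0$ and dosages
$d_i \in [0,2]$,

$$\mathrm{GRS_w} = \sum_{i=1}^{n} \beta_i d_i, \qquad
  \mathrm{GRS_s} = \frac{n\,\mathrm{GRS_w}}{\sum_i \beta_i}.$$

$\mathrm{GRS_s}$ lives on a morningness-allele-count scale in $[0, 2n]$ and
satisfies the exact identity $\mathrm{GRS_s}\sum_i\beta_i = n\,\mathrm{GRS_w}$
for complete data. Harmonisation recodes every variant to count the
morningness allele: dosages are complemented where the counted allele is
the other allele, strand flips are resolved by base complement, and
negative weights are flipped to the opposite allele. These recodings leave
GRS ranks invariant (affine equivalence), which the tests verify.

Genotype calls with probability strictly below 0.9 are set missing.
With missing dosages the weighted sum is, by default, rescaled by
$\sum_{\text{all}}\beta / \sum_{\text{used}}\beta$ so scores remain
comparable across participants; mean imputation is available by flag. The
handling of missing dosages is a package decision — either policy can be
selected explicitly.

**Variance explained.** For a binary exposure no single convention exists;
we report the squared Pearson correlation between the score and the 0/1
exposure as the headline number and McFadden's pseudo-R² alongside.
Dichotomising a latent liability caps the attainable $r^2$ well below the
liability-scale share: at a 62.6% case fraction the attenuation factor is
$\phi(z_p)^2/(p(1-p)) \approx 0.61$, so a generator calibrated to a 5.4%
liability share yields a binary-exposure $r^2$ around 0.03, which is the
band the tests assert.

## One-sample MR: two-stage least squares

Stage 1 regresses the binary exposure linearly on $\mathrm{GRS_s}$ plus
covariates and keeps the fitted values ("predicted morningness"); a
logistic first stage is available by flag. Stage 2 regresses the outcome
on the fitted exposure plus the same covariates — logistic for binary
outcomes, proportional-odds for ordinal ones, linear for continuous ones
(used for CPD). The reported coefficient is the stage-2 slope on the
fitted exposure, a log odds ratio per unit of morningness.

Model-based stage-2 SEs ignore first-stage uncertainty; because whether
that matters depends on instrument strength, a nonparametric bootstrap SE
over both stages is available (`n_boot`). A first-stage F below 10
attaches a `weak_instrument` flag rather than failing silently.

For interpretation, estimates are rescaled to the change per twofold
increase in genetic liability: $\mathrm{OR} = e^{\beta \ln 2} = 2^\beta$,
confidence limits transformed identically.

## Two-sample MR estimators

All two-sample methods consume per-SNP harmonised summary statistics
$(\hat\beta_{X_i}, \hat\sigma_{X_i}, \hat\beta_{Y_i}, \hat\sigma_{Y_i})$.
Harmonisation aligns outcome effects to the exposure's effect allele
(sign flips for swapped alleles, base complements for strand differences)
and drops palindromic SNPs whose EAF lies in (0.42, 0.58) as
strand-ambiguous.

- **Wald ratios**: $r_i = \hat\beta_{Y_i}/\hat\beta_{X_i}$ with first-order
  SE $\hat\sigma_{Y_i}/|\hat\beta_{X_i}|$.
- **IVW**: slope of $\hat\beta_Y$ on $\hat\beta_X$ through the origin with
  weights $w_i = 1/\hat\sigma_{Y_i}^2$. Under the multiplicative
  random-effects model the fixed-effect SE is inflated by
  $\max(1, \sqrt{Q/(n-1)})$, which absorbs balanced pleiotropy without
  moving the point estimate.
- **MR-Egger**: the same weighted regression with a free intercept; the
  intercept estimates mean directional pleiotropy under InSIDE. Exposure
  effects are oriented positive first — without a fixed orientation the
  intercept is not identified. SEs use the $n-2$ version of the same
  inflation.
- **Weighted median**: order the ratios, form standardised cumulative
  weights $s_j = (\sum_{k \le j} w_k - w_j/2)/\sum_k w_k$ with
  $w_j = 1/\mathrm{se}(r_j)^2$, and linearly interpolate the ratio at
  $s = 0.5$. With equal weights and odd $n$ this is the plain median.
  The SE is a seeded parametric bootstrap (default 1000 replicates)
  redrawing each SNP's effects from their sampling distributions — the
  median has no convenient closed-form SE.
- **Penalised weighted median**: with $Q_j = w_j (r_j - \hat\beta_{wm})^2$
  and one-df upper-tail p-values $p_j$, weights become
  $w_j \min(1, 20\,p_j)$ and the median is recomputed. The constant 20 is
  the standard convention; as the penalty grows the estimator returns to
  the unpenalised median wherever $p_j > 0$.
- **Heterogeneity**: $Q = \sum_i w_i (r_i - \hat\beta)^2$ on $n-1$ df.

The suite's agreement contract — every estimator matches a literal
transcription of these formulas (computed through `lm()` fits and explicit
loops rather than the package's closed forms) to $10^{-6}$ on random
datasets — is enforced in the acceptance tests.

## Composite Phase Deviation

Each night's sleep midpoint is `onset + duration/2` expressed in hours
since midnight of the night's calendar date, so a 23:30–07:30 episode has
midpoint 27.5. This continuous axis (values may exceed 24) avoids modular
discontinuities near midnight; durations outside (2 h, 16 h) are rejected
with reason codes. For nights $i = 2..n$,

$$\mathrm{CPD} = \frac{1}{n-1}\sum_{i=2}^{n}
  \sqrt{(\mathrm{MS}_i - \mathrm{ref})^2 +
        (\mathrm{MS}_i - \mathrm{MS}_{i-1})^2},$$

combining mistiming (deviation from a reference midpoint) and
irregularity (night-to-night change) in a per-night Euclidean norm. The
first night has no previous-night term and contributes nothing — an
explicit design choice, since the published description of the metric
names the two components without printing an equation. CPD is
non-negative, zero exactly for constant series, translation-invariant,
and scales linearly with midpoint dispersion about the mean; all four
properties are tested, the last by brute-force enumeration on three-night
series.

The primary reference is the individual's all-night mean midpoint. The
sensitivity variant uses MSFsc, the free-night (Friday/Saturday) mean
midpoint with a one-sided oversleep correction
$\mathrm{MSF} - (\mathrm{SD}_{free} - \mathrm{SD}_{week})/2$ applied only
when free-night sleep is longer on average. The two variants coincide
exactly when every night is free with equal durations.

CPD effects are reported per SD. Standardisation defaults to the
population-SD convention (divide by $n$), with the sample convention
selectable; the SD used is recorded on the result. Participants need at
least 5 of 7 usable nights by default (configurable, minimum 2) to enter
analyses.

## Association models

Binary outcomes use maximum-likelihood logistic regression; ordinal
severity scores use proportional-odds regression (`MASS::polr`, with a
deterministic fallback start at the empirical cumulative log-odds for
sparse high-category outcomes, and an exact collapse to logistic for
two-category outcomes). Wald 95% CIs are used throughout. Missing data are
handled by complete-case analysis with logged exclusion counts. Assessment
centre enters as a categorical fixed effect and smoking as a three-level
categorical. No multiple-testing correction is applied; estimates are
reported with unadjusted CIs.

One numerical subtlety: `summary.glm` computes Wald SEs from the IRLS
weights of the penultimate iteration, which is off by ~1e-7 even when the
coefficients have converged. The package recomputes SEs from the observed
information at the final MLE, so a logistic fit on a saturated 2×2 design
reproduces $\ln(ad/bc) \pm \sqrt{1/a + 1/b + 1/c + 1/d}$ to 1e-8.

Sex differences between stratified fits use Fisher's z,
$z = (\beta_m - \beta_f)/\sqrt{SE_m^2 + SE_f^2}$, two-sided normal p.
Strata are fitted as independent complete-case models (no interaction
terms), matching the stratify-then-compare design.

## The synthetic cohort generator

The generator exists so that every pipeline stage has a ground truth. Its
defaults describe the emulated study conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `case_fraction` | 0.626 | morning-person share of the cohort |
| `grs_liability_r2` | 0.054 | liability variance share of the GRS |
| `outcome_prevalence` | 0.11 | marginal rate of the primary binary outcome |
| `causal_lnor` | −0.12 | true log-OR of morningness on each outcome |
| `confounder_effect_*` | 0.3 | confounding paths into exposure and outcome |
| `n_nights` | 7 | actigraphy nights per participant |
| `act_jitter_morning/evening` | 0.7 / 0.8 h | midpoint SD by chronotype |

Genotypes are drawn at independent biallelic SNPs under Hardy–Weinberg
(no LD — the emulated instruments are GWAS-pruned independent hits, and
independence keeps the test oracles exact). The exposure liability is
$a\,\mathrm{GRS} + b\,C + \varepsilon$ with $a$ solved so the GRS explains
exactly its configured variance share; the published 5.4% figure does not
name its metric for the binary trait, so the generator targets the latent
liability share and documents that choice. Binary outcomes follow
$\mathrm{logit}\,p = \alpha + \beta_{\text{causal}}\,X + b_Y C +
\sum_j \gamma_j d_j$ with $\alpha$ solved numerically for the target
marginal prevalence. Pleiotropy modes draw the $\gamma_j$ for the invalid
fraction of SNPs as mean-zero normal (balanced), folded-normal
(directional), or correlated with the instrument weights
(InSIDE-violating). Ordinal scores come from a proportional-odds latent
model with fixed cutpoints whose baseline category distributions are
geometric-style decays for symptom scores (PHQ9 0–27, GAD7 0–21, CIDI
severity 0–15) and a centred bell for wellbeing (3–17); published sources
give only the score ranges, so the shapes are package choices calibrated
to plausible population means. The wellbeing score receives the negated
linear predictor, higher being better.

Two-sample summary statistics come from two disjoint cohorts sharing the
same variants: per-SNP linear regressions on the continuous liability in
the exposure sample and univariable logistic regressions in the outcome
sample, with a configurable fraction of outcome records reported on the
swapped allele to exercise harmonisation. A faster summary-level generator
(`simulate_summary_stats()`) draws effect estimates directly around their
truths and is used for the calibration studies; its default per-SNP
exposure SEs (0.002–0.006) reflect a discovery GWAS of several hundred
thousand participants, giving per-SNP F statistics comfortably above the
weak-instrument floor.

Actigraphy series stagger wear periods across the Mondays of a calendar
year (so season of wear varies), give morning types earlier mean midpoints
and smaller night-to-night jitter than evening types (0.7 vs 0.8 h), flag
Friday/Saturday as free nights with a 0.4 h oversleep extension, and draw
durations from a truncated normal around 8 h. Every generator is fully
determined by `seed`; each stage draws from its own derived stream so
upstream draws never shift when downstream stages change.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: linkage disequilibrium and clumping artefacts,
imputation quality, winner's curse in the instrument weights, selection
into actigraphy or questionnaire subsamples, relatedness, population
stratification, and raw accelerometer noise (sleep episodes are taken as
given). Calibration results are internal-validity checks of the
estimators, not evidence about any real cohort.

## Problem sizes and runtime choices

The test and acceptance suites use deliberately modest problem sizes —
cohorts of 600–20,000, 8–100 SNPs, 200–1000 simulation replicates — chosen
so the full suite runs in minutes on a single core while keeping
Monte-Carlo error small relative to the tolerances asserted (binomial
99% intervals, 3 Monte-Carlo SEs). The published analyses this package
emulates used hundreds of thousands of participants; their headline
estimates depend on restricted individual-level data and are not
reproducible at desk scale, which is why the acceptance layer asserts
exactly recomputable worked examples and distributional properties rather
than the published effect sizes.

## Known limitations

- The one-sample stage-2 SE does not propagate first-stage uncertainty
  unless the bootstrap is requested.
- The logistic–liability scale mismatch means two-sample slopes (per
  liability unit) and one-sample slopes (per binary exposure unit) are not
  numerically comparable; both are reported on their own scales.
- Instrument-variant subsets (full set, replication-only, actigraphy-
  excluded) are configuration inputs; the package ships only synthetic
  weight files.
- No genetic instrument for CPD is provided: chronotype instruments are
  equivalent to the exposure instrument, and a dedicated CPD instrument
  would need weak-instrument methods out of scope here.
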