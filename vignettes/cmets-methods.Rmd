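---
title: "Methods: the continuous metabolic syndrome score and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the continuous metabolic syndrome score and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pediatric metabolic syndrome (MetS) has no universally agreed definition.
Binary classifications — "at least three of five abnormal components" —
discard information near the thresholds and lose statistical power at the
early stages of metabolic deterioration, where most children sit.  A
*continuous* MetS score (cMetS) addresses this by summing age- and
sex-standardized residuals of the five components:

* waist circumference (WC, cm),
* mean arterial pressure (MAP = (SBP − DBP)/3 + DBP, mmHg),
* HDL cholesterol (mg/dL, entered with a flipped sign because it is
  protective),
* triglycerides (TG, mg/dL),
* fasting blood glucose (FBG, mg/dL).

For each component $x_j$ this package fits by ordinary least squares

$$x_{ij} = \beta_{0j} + \beta_{1j}\,\mathrm{age}_i +
  \beta_{2j}\,\mathrm{male}_i + \varepsilon_{ij},$$

standardizes the residuals, $z_{ij} = \hat\varepsilon_{ij}/\hat\sigma_j$
(residual SD with the $n-p$ denominator), and aggregates

$$\mathrm{cMetS}_i = z_{i,\mathrm{WC}} + z_{i,\mathrm{MAP}}
  - z_{i,\mathrm{HDL}} + z_{i,\mathrm{TG}} + z_{i,\mathrm{FBG}}.$$

Higher values mean a less favorable metabolic profile.  On the fitting
sample every $z_j$ has mean exactly zero, so the score is centred at zero
by construction; its variance exceeds 5 exactly when the components remain
positively correlated after age/sex adjustment.  The score is
**sample-specific**: its location and scale are internal to the analysis
sample, so a cutoff derived in one population does not transfer to another
without revalidation.  `predict.cmets()` warns accordingly when applied to
new data.

### Covariate specification

The phrase "adjusted for age and sex" admits several designs.  The default
is a single pooled regression per component (intercept + continuous age +
sex indicator), the standard construction for this score in the pediatric
literature.  Sex-stratified age regressions (`by_sex_age`) and an
age-by-sex interaction (`pooled_age_sex_interaction`) are available as
configuration options, and the choice is recorded in run metadata.  Age
enters as continuous years; no transformation is applied to TG by default
(an opt-in `log_tg` flag exists for sensitivity analysis).  These defaults
are this package's declared choices, not claims about any particular
historical analysis.

## MetS classification

Two modified-ATP-III presets are first-class, because the pediatric
literature uses both threshold sets:

| component | `methods_text` | `table_footnote` |
|---|---|---|
| high TG | TG ≥ 150 mg/dL | TG > 100 mg/dL |
| low HDL | HDL ≤ 40 mg/dL | HDL < 40 (boys 15–18: < 45) mg/dL |
| high FBG | FBG ≥ 100 mg/dL | FBG > 100 mg/dL |
| abdominal obesity | WHtR > 0.5 | WC > 90th percentile (sex, age) |
| elevated BP | SBP or DBP > 90th percentile (sex, age, height) | same |

MetS is at least three components.  Comparators are applied exactly as
written (strict vs inclusive); the two presets genuinely disagree at the
boundary values and are deliberately not reconciled.  Analyses meant to
mirror percentile-based published tables should use `table_footnote`;
`methods_text` is the default elsewhere.

### Percentile references

Percentile-based rules (BP, WC, BMI) need a normative reference.  Instead
of shipping external reference tables, the default is an **empirical
within-cohort reference**: subjects are binned by sex and integer age-year
(bins under `min_bin = 20` subjects merge with the adjacent year), height
adjustment uses within-bin height tertiles, and all percentiles use the
linear-interpolation estimator (Hyndman–Fan type 7, the `quantile()`
default in R).  With strict `>` comparisons this caps each bin's flagged
fraction near 10% plus an interpolation/tie allowance of one subject.  An
external normative BP table can be supplied as a CSV
(`sex, age_year, height_percentile_band, sbp_p90, dbp_p90`) for fidelity
to published reference standards; height bands are then still the
cohort's tertiles, since external tables do not define them.

Missing measurements follow a complete-case policy per analysis stage:
subjects stay in the output with `NA` flags and are counted in an
`exclusions` attribute and in pipeline metadata.

## The synthetic cohort generator

No subject-level data are distributed with the package (none are publicly
deposited for the survey whose summary statistics calibrate it), so all
testing and the acceptance analysis run on synthetic cohorts from
`simulate_cohort()`.  The generator emulates:

* six sex-by-age-band strata whose means and SDs match the published
  survey table embedded in `reference_strata()` (52.3% boys; band shares
  30/43/27%), with age uniform within band and linear within-band age
  slopes derived from between-band mean differences;
* positive inter-component correlation through a latent severity factor
  (negative loading on HDL), plus a shared BP factor (SBP–DBP correlation
  ≈ 0.6), a body-size factor (weight/height/waist) and a lipid factor
  (TC/LDL);
* right skew in TG and weight via moment-matched lognormals (the age
  slope for weight acts on the log scale with an exact mean correction);
* physiologic support via rejection sampling (whole-subject redraw) at
  floors and `SBP > DBP + 5`, so distributions stay smooth with no point
  masses.

Loadings are *correlations* with each factor; squared loadings sum to
less than one per measurement and the remainder is independent Gaussian
noise, so configured SDs are reproduced exactly.  The severity loadings
(0.06–0.18) were calibrated once so that MetS prevalence under the
`table_footnote` preset with empirical percentiles lands near the
published 5% (within 3–8%) at $n = 50{,}000$.  A structural tension is
worth recording: a Gaussian FBG marginal matching the published mean and
SD (≈ 92 ± 12 mg/dL) necessarily yields a high-FBG rate (> 100 mg/dL) of
roughly 20%, far above the published 4%, which — independence alone —
already pushes the three-component rate near 7%.  Real FBG is sharply
peaked with heavy tails, a feature this Gaussian latent-factor design does
not emulate.  Consequently the calibrated clustering is mild, and
passing tests demonstrate internal consistency of the pipeline, not that
the generator reproduces every joint feature of real pediatric data.
Other features deliberately not modeled: the survey's multistage cluster
sampling and weights, measurement error, non-response, and within-subject
repeat BP averaging (assumed already done upstream).

## ROC validation of cMetS cutoffs

For each stratum (boys/girls/total within the three age bands, plus the
three 7–18 rows — twelve rows in all) the package:

1. builds the empirical ROC curve under the positivity rule
   *score ≥ threshold*, evaluated at every unique score plus a $+\infty$
   sentinel, so the curve spans (sens, spec) = (1, 0) to (0, 1);
2. computes the AUC as the Mann–Whitney probability (ties count one half)
   via midranks — the trapezoidal integral of the curve is mathematically
   identical and the test suite asserts agreement to $10^{-12}$;
3. selects the optimal cutoff maximizing sensitivity + specificity
   (Youden's J + 1), breaking ties toward the **minimum** threshold.
   The comparison uses exact integer arithmetic
   ($\mathrm{TP}\cdot n^- + \mathrm{TN}\cdot n^+$) so that thresholds with
   mathematically equal sums tie exactly instead of being ordered by
   floating-point rounding;
4. attaches confidence intervals: Wald for sensitivity and specificity
   (clipped to [0, 1], boundary-flagged at 0 or 1), DeLong's variance
   estimator for the AUC, and a seeded percentile bootstrap (default
   $B = 1000$, seed 20150101) over the *entire cutoff-selection
   procedure* for the cutoff itself.  Resamples that lose a class are
   redrawn; strata with fewer than 10 positives are flagged unstable;
   single-class strata yield `NA` rows with a warning.

The CI methods are declared package choices — published tables of this
kind typically report intervals without naming a method — and are recorded
in run metadata.  AUC is stored as a proportion and rendered as a
percentage at the report layer.

## Numerical and degenerate-input conventions

* No rounding inside computations; rounding (2 dp, percentages, p-value
  floor "< 0.001") happens only in rendered output.  CSV outputs keep raw
  values.
* Residual SDs use the $n - p$ denominator; a constant response or a
  perfectly collinear design is rejected as degenerate rather than
  producing zero-SD z-scores.
* All randomness is seeded; `simulate_cohort()` and the bootstrap restore
  the caller's RNG state, and the whole pipeline is byte-identical across
  reruns of one configuration.
* `n = 0` cohorts abort the pipeline before any output is written;
  single-subject strata report `NA` SDs.

## Problem sizes used by the test suite

The suite exercises the pipeline at the sizes where its claims are sharp:
oracle equivalence exhaustively on all 3-vs-3 label arrangements and on
1000 random tied instances of up to 20 points; OLS identities, Table-style
monotonicity and null-permutation AUCs on a 50,000-subject cohort;
generator calibration on ~50,000 subjects per stratum; bootstrap CI
shrinkage across $n \in \{500, 5000, 50{,}000\}$; and the acceptance
script reruns the full analysis at the study scale of $n = 3843$
(52.3% boys).  These sizes are the package's own reproducibility
conditions and complete in minutes on a laptop.

## Known limitations

* The score is sample-specific by construction; cross-cohort application
  is supported but warned against.
* Empirical percentile references track the analysis cohort itself; they
  are a self-contained substitute for external normative tables, not a
  reproduction of them.
* The generator's Gaussian marginals (except TG and weight) understate
  tail behavior of some biochemistry, as discussed above; prevalences of
  individual components should be read as order-of-magnitude realistic.
* Survey design effects (clustering, weighting) are out of scope; all
  descriptive tests treat subjects as independent.
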