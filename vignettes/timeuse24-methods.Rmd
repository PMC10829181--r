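---
title: "Methods: compositional time-use analysis with timeuse24"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional time-use analysis with timeuse24}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeuse24)
```

## The model

A day of an older adult splits into four exhaustive behaviours: moderate-
vigorous physical activity (MVPA), light physical activity (LPA), sedentary
behaviour (SB) and sleep. Because the four durations always sum to 1440
minutes they carry only *relative* information — increasing one behaviour
necessarily decreases the others — so ordinary linear modelling of raw
minutes, and ordinary Pearson correlations between behaviours, are both
distorted by the constant-sum constraint. `timeuse24` treats the day as a
composition in the Aitchison geometry:

* **Closure.** `closure(x, kappa = 1440)` rescales any strictly positive
  vector proportionally to the 1440-minute day. Compositional information
  is invariant to this rescaling.
* **Pivot ilr coordinates.** `ilr_pivot()` maps a D-part composition to
  D−1 unconstrained coordinates; coordinate *i* is
  `sqrt((D-i)/(D-i+1)) * log(x_i / gmean(x_{i+1..D}))`. The map is an
  isometry between the simplex (Aitchison metric) and Euclidean space, and
  different pivot orders differ only by an orthogonal rotation. The three
  coordinates of the 4-part day enter every regression as a single 3-column
  term, so whole-composition tests are invariant to the pivot order (the
  test suite verifies this to 1e-8); individual ilr coefficients are *not*
  basis-invariant and are never interpreted in isolation. The default
  order (MVPA, LPA, SB, sleep) is cosmetic.
* **Compositional mean.** Per-part geometric means, closed to 1440 —
  identical to averaging in ilr space and mapping back.
* **Symmetric balances.** For the correlation *between* two behaviours,
  `cor_coda()` builds the unique (up to sign) pair of log-contrast
  coordinates that treat parts *i* and *j* symmetrically against the
  average of the remaining parts, subject to zero sum, unit norm and
  mutual orthogonality; for D = 4 the coefficients are
  `alpha = (2+sqrt(2))/4`, `beta = -(2-sqrt(2))/4`, `gamma = -sqrt(2)/4`.
  The Pearson correlation of the two coordinates reads as dominance of one
  behaviour over the other rather than raw linear association.

## From accelerometer epochs to compositions

The pipeline starts at epoch-level ENMO (the Euclidean norm of acceleration
minus one g, floored at zero, in milli-g). Classification applies, in
order of precedence:

1. manually logged sleep windows (bed-to-wake, plus naps) are sleep
   regardless of ENMO — the sleep log is treated as ground truth and
   therefore also outranks the wear flag;
2. non-wear from the device wear flag or logged removal intervals;
3. cut points for the remaining waking epochs: ENMO > 93 mg is MVPA,
   > 48 mg is LPA, otherwise SB. The printed rules are strict
   inequalities, so an epoch exactly at a cut point falls in the lower
   class (93 mg → LPA, 48 mg → SB).

A wear day is *valid* with at least 600 min of waking wear and strictly
less than 360 min of non-wear (equivalently, at least 18 h of average wear
across the 24-h period). Participants enter analysis with at least three
valid weekdays and one valid weekend day (Saturday/Sunday by the local
calendar of the timestamps), and an average recorded daily total of at
most 1500 min. Behaviour minutes are averaged over valid days only. A
behaviour never observed at all would make the composition degenerate, so
a zero average is replaced by half the smallest observable increment
(half an epoch in minutes) and flagged; the geometry core itself rejects
zeros outright, keeping the mathematical layer total and explicit.

Epoch length is configurable with a 60 s default, which keeps day
summaries exact in whole minutes. Cut points are configuration, not
constants, because published cut points are calibrated to particular
devices and sampling rates. Algorithmic non-wear detection and raw 100 Hz
processing are out of scope: wear information comes from the device flag
and the log.

## Regression stages

ROI volumes (total grey matter, frontal and temporal lobes, hippocampus,
lateral ventricles, in ml) are first residualised on total intracranial
volume, scanner site and the distortion-correction flag, with the sample
mean restored so values stay in ml. Ventricle volumes are right-skewed;
the package log-transforms them *before* this adjustment (adjusting on the
log scale) rather than after, because a residual-plus-mean adjustment can
in principle produce non-positive values that a subsequent log could not
accept. The model class is unchanged by this ordering.

Cognitive composites are means of within-test z-scores (each test scored
against its own non-missing mean and SD, higher = better), and each
outcome model uses listwise deletion, so per-outcome sample sizes differ
under missingness.

The modelling sequence per ROI outcome is: Model 1, covariates only (age,
sex with female = 1, education in years); Model 2, covariates plus the
3-column ilr term; Model 3, Model 2 plus the squared ilr coordinates,
compared to Model 2 by a nested F-test (df1 = 3). "Quadratic" means the
squared coordinates only — cross-products are available via
`compare_quadratic(cross_products = TRUE)` but are off by default, as the
squared-term reading is the conservative interpretation. Moderation models
add an (adjusted) ROI volume and the 3-column ilr × ROI interaction, with
the ROI entered continuously by default, or as a mean-split two-level
factor or quartiles for sensitivity refits.

**Type II F-tests.** Each term is tested by a nested-model comparison that
respects marginality: when testing a term, any interaction containing it
is excluded from both models; multi-column terms are tested jointly (the
composition has df1 = 3). Both the numerator sum of squares and the error
term come from the marginality-respecting model that includes the tested
term — a genuine nested-model F. An alternative convention (used by
`car::Anova`) takes the error from the full model including interactions;
the two coincide exactly for every highest-order term, in particular for
the composition term in Model 2 and for the ilr × ROI interaction, which
carry the scientific conclusions. The test suite checks both the
brute-force nested-RSS oracle and agreement with `car` where the
conventions coincide.

p-values are Benjamini–Hochberg adjusted **within one model's term
table** — the FDR family is a single model, never pooled across models.

**Correlation table.** Pearson correlations with Fisher-z 95% intervals
(`tanh(atanh(r) ± 1.96/sqrt(n-3))`) for pairs outside the composition,
point-biserial (Pearson on 0/1 coding) when one variable is binary, and
symmetric-balance correlations with seeded percentile bootstrap intervals
(1000 resamples) for within-composition pairs. Pairwise-complete deletion
is used, since per-pair deletion maximises the data behind each
coefficient. A correlation of |r| = 1 gets a degenerate interval at r.

## Reallocation response curves

From a reference composition (the analysed sample's compositional mean),
`reallocate()` constructs displaced days: *one-for-remaining* adds Δ
minutes to a target behaviour and rescales the remaining parts by
`(1440 − target_new)/(1440 − target_old)`; *one-for-one* moves Δ minutes
directly between two named behaviours. Any reallocation that would drive
a part to zero or below is refused (and silently dropped from curve
grids). The default grid is −60 to +60 minutes in 15-minute steps — the
step matches the increments used in such response plots and the range
covers the 30-minute swaps usually discussed.

The predicted difference between the displaced and reference day is
`d'β̂`, where `d` differs from zero only in the ilr (and ilr × ROI)
columns — covariates cancel in the difference, so no covariate profile is
needed under a linear model without covariate interactions. Its interval
is `± t(df_resid, 0.975) · sqrt(d'Vd)` with `V` the coefficient
covariance: a *confidence* interval for the mean difference, not a
prediction interval for an individual, since the curves describe expected
differences. At Δ = 0 the difference is exactly zero with a zero-width
interval.

Stratified curves come from the continuous-interaction fit predicted at
the stratum means of the adjusted ROI (the means of the values below and
above the sample mean); with a mean-split categorical fit, prediction is
at the stratum level. Refitting within strata is available through
`roi_form = "mean_split"` plus subsetting, but the single-fit route uses
all the data to estimate the error variance.

## The synthetic cohort

No participant-level data accompany the analysis design, so
`generate_cohort()` emulates the cohort the models assume, with every
effect planted and therefore testable:

* Covariates: age ~ Normal(65.6, 3.0) truncated to [60, 71.2] years;
  education ~ Normal(16.6, 3.2) truncated to [7, 30] years; female
  prevalence 0.67; two scanner sites and a distortion flag, Bernoulli(½).
* Compositions are logistic-normal: Gaussian log-parts projected to pivot
  ilr space. The log-scale location is the target compositional mean
  (90.7, 178.8, 668.2, 502.2) min/day and the per-part coefficients of
  variation (0.50, 0.30, 0.22, 0.08) were calibrated once so the
  arithmetic SDs approximate (47, 51, 92, 58) min/day after closure;
  SB and sleep trade off variance through the closure, so their SDs match
  only to within ~10%. A negative loading of female sex on log-MVPA and a
  small positive one on log-sleep reproduce the observed point-biserial
  correlations (≈ −0.20 and +0.14). By default the realised ilr sample is
  recentred on the target compositional mean (the same idea as
  `MASS::mvrnorm(empirical = TRUE)`): the sample centre is then exact by
  construction while dispersion, covariate effects and all planted
  regression structure are untouched. Set `empirical_center = FALSE` for
  fully random draws.
* ROI volumes are Gaussian (log-normal for ventricles and WMH) with
  age/sex loadings reproducing the observed correlations (e.g. age–GM
  −0.28, age–ventricle +0.21, sex–frontal +0.12), site/distortion shifts
  of 0.2 and 0.1 SD (nuisance structure for the adjustment stage to
  remove), and a residual correlation matrix using the observed
  between-ROI correlations where available (GM–temporal 0.70, GM–frontal
  0.67, …) and modest assumed values for the unreported TIV row — these
  entries are assumptions, not data.
* Cognition follows a linear model in covariates, ilr coordinates, a
  standardised ROI and the ilr × ROI interaction. The default
  long-term-memory model plants a frontal-lobe moderation of the MVPA
  pivot coordinate (γ₁ = 0.37, ω₁ = −0.70 per ROI-SD) sized so that a
  30-minute MVPA reallocation shifts the predicted score by roughly a
  quarter SD in the low-volume stratum and nearly nothing in the high
  stratum; executive function plants a small SB/sleep-by-total-GM
  moderation; processing speed carries a composition main effect only.
  Missingness is MCAR per outcome at rates giving analysis sizes of about
  360/363/368 out of 378.

What the generator does **not** emulate: diurnal activity rhythm and
autocorrelation inside the day (epoch traces place behaviours in random
order within the waking window), non-Gaussian cognitive noise, informative
missingness, and measurement error in the accelerometer classification
itself. Passing recovery tests therefore demonstrate that the estimation
machinery is correct under its own assumptions, not that real cohort
effects of this size would be detected.

`generate_trace()` builds epoch series whose ENMO values sit strictly
inside each behaviour's cut-point band (never on a boundary), with night
sleep split symmetrically around midnight, so classification must recover
the generating labels exactly — any discrepancy is a bug, not noise.

## Numerical choices

* Tolerances: 1e-12 for pure arithmetic identities (closure idempotence,
  basis orthogonality), 1e-9 for geometry identities that accumulate a few
  rounding operations (isometry, norm preservation), 1e-8 for identities
  routed through regression fits.
* Compositions must be strictly positive; zeros are an upstream concern
  (accelerometry zero-replacement), and the core errors loudly.
* Cut-point ties go to the lower class by the strict printed inequalities.
* `symmetric_balance_coords` uses the closed-form solution of the
  constraint system with the sign convention `alpha > 0` (the coordinate
  grows with its highlighted part).
* Bootstrap and simulation randomness is seeded through configuration;
  the pipeline derives per-stage substreams from one master seed, and
  equal-seed runs are byte-identical.

## Problem sizes

The test suite exercises the geometry on 1000 random compositions,
regression oracles on 20–600-row fixtures, and the Monte-Carlo
calibrations (CI coverage of planted coefficients, type-I error of the
interaction test) on 500 replicate cohorts of n = 378 — large enough that
the binomial simulation error on a coverage proportion is about 1
percentage point, keeping the 92–98% acceptance band meaningful.

## Known limitations

* Sleep-log precedence means mislogged windows silently become sleep;
  there is no cross-check of the log against the trace.
* Wrist-worn devices under-detect posture, so SB/LPA separation is only
  as good as the cut points; the defaults come from calibration in younger
  adults.
* The within-strata refit option estimates separate error variances from
  half-samples and is correspondingly noisier than the single-fit route.
* Curves extrapolate linearly in ilr space; far from the reference
  composition (large |Δ| against a small part) the linear model is doing
  the work, not the data.
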