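---
title: "Version-shuffled brain-age modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Version-shuffled brain-age modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Brain age is a person's age as predicted from brain-imaging features by a
regression model; the gap between predicted and chronological age is used as
a biomarker of brain health. The features, however, depend on the software
that produced them: different releases of a cortical surface-reconstruction
pipeline (here called *v5* and *v7*) yield systematically different estimates
of the same regional thickness, surface-area and volume values. `vershuffle`
provides a tested framework to quantify how much of a brain-age model's
behaviour is attributable to the processing release rather than to biology,
and to evaluate *version shuffling* — composing training (and test) sets so
that each participant's feature row is drawn at random from one of the two
releases (50:50) — as a strategy for building release-robust models.

Because two-release paired data on a real cohort are access-restricted, the
package ships a synthetic-data generator as a first-class, tested module.
Every downstream stage (quality control, split construction, the model suite,
the permutation designs, and the statistical comparison battery) runs
identically on real delimited-text tables of the same shape.

# The generator

## Model

The generator is a linear-Gaussian latent-factor model. For participant $i$
with standardised age $z_i$ and feature $f$ (of $p = 34 \times 2 \times 3 =
204$ Desikan-Killiany features), the latent anatomy is

$$ L_{if} = b_f\, z_i + \sqrt{1-b_f^2}\,\big(c\, g_{i,m(f)} +
   \sqrt{1-c^2}\,\varepsilon_{if}\big), $$

where $g_{i,m}$ is a per-measure-type factor (thickness/area/volume,
loading $c = 0.4$) that shapes the principal-component structure, and the
age loadings $b_f$ are positive weights boosted threefold for the thickness
features of the planted strong regions (inferior parietal, superior frontal,
precentral), defining the ground-truth importance ordering.

Each release $v$ observes

$$ X^v_{if} = \sqrt{\rho_{vf}}\, L_{if} + \sqrt{1-\rho_{vf}}\, \nu^v_{if}, $$

with version noise $\nu^v$ that retains the measure-type factor structure
(so both releases decompose into near-identical principal components) and
carries a small age-aligned component $d_{vf}$, independent between releases.
The signal shares $\rho_{vf}$ are solved in closed form: their geometric mean
equals the feature's cross-version agreement target ($0.88$ by default;
$0.60$ for area/volume of the entorhinal, temporal-pole and frontal-pole
regions), and a per-feature log-ratio tilt (sd $0.05$) makes one release the
more reliable measurement of any given feature. The per-release means of
$d_{vf}$ are solved so the mean feature-age correlation hits $-0.17$ (v5) and
$-0.15$ (v7) in expectation; a per-feature jitter (sd $0.03$) gives each
release idiosyncratic feature-age dependencies.

Finally the v7 view passes through a per-feature affine map,
$X^7 \mapsto s_f X^7 + o_f$: scales $s_f$ jittered around 1 (sd $0.03$) and
offsets $o_f$ around $0.25$ SD (relative spread 1) plus a component
proportional to $b_f$ (weight 1). Features are emitted on the z-scale; no
physical units are simulated. Ages are truncated-normal (mean 64.84, SD 7.27,
bounds 49.33–82.84 years); sex ($52.5\%$ female) shifts area/volume features
by $\pm 0.1$ SD by default, and the three scanner sites (weights
$0.554/0.350/0.096$) carry no shift unless one is requested.

## Why the affine map looks the way it does

All calibration targets are Pearson correlations and therefore invariant to
any per-feature affine transform — the map changes what *models* see, not
what the agreement statistics see. The design separates two kinds of
between-release difference deliberately:

* **Compensable differences** (the offsets): because every one of the 204
  features is shifted, the release of a feature row is identifiable from the
  row itself along many low-variance directions, so a model trained on a
  50:50 mixture can absorb the shift almost freely, while a single-version
  model applied to the other release inherits a genuine bias in years —
  amplified by coupling the offsets to the age loadings, since release
  disagreement concentrates in age-sensitive, atrophy-prone cortex. This is
  what produces the characteristic ordering: a cross-version penalty for
  single-version models, near-parity of mixture-trained models on pure
  targets, and a mixture advantage on shuffled targets.
* **Non-compensable differences** (scale jitter, reliability tilt,
  idiosyncratic age channels): these change the optimal regression weights
  per release and cannot be absorbed by any single linear model. They are
  kept small, so that mixture training loses little on pure targets.

What the generator does **not** emulate: real measurement units and
region-specific variance scales, non-linear age trajectories (the cohort is
49–83 years, where feature-age relations are near-linear), site-by-release
interactions, systematically missing releases, longitudinal structure, or
any property of the reconstruction algorithms themselves. Passing tests on
synthetic cohorts therefore demonstrate that the *machinery* is correct and
that the qualitative phenomena follow from the stated generative assumptions
— not that any particular real dataset satisfies those assumptions.

# Quality control and split construction

Feature-level outliers are removed with a single-pass rule: a participant is
excluded when any feature in any release lies more than 5 SD from the
column mean, with moments estimated once on the full (possibly contaminated)
sample — deliberately not re-estimated iteratively. Zero-variance columns are
skipped with a warning. The planted-outlier fixture displaces cells *away
from* the column mean and allocates them evenly across columns: uniform cell
sampling would let sampling clumps inflate some columns' SD estimates enough
for 6-SD displacements to mask themselves below the 5-SD threshold, which is
a property of the contamination pattern, not of the rule under test.

Splits are uniform 50-50 partitions (train receives the extra participant
when $n$ is odd). The shuffling unit is the **participant row**: each
participant contributes all 204 features from a single release. A
column-wise mixing interpretation exists but would create feature vectors no
real pipeline produces; row-wise is the default and the one used throughout.

# Models

Four algorithms sit behind one fit/predict contract with frozen
hyperparameters: ordinary least squares (rank checked, offending columns
named), lasso (`glmnet`, penalty chosen by 5-fold internal cross-validation
over the default logarithmic path, iteration cap $10^5$), epsilon-SVR
(`e1071`, radial kernel, defaults) and gradient-boosted trees (`xgboost`,
100 rounds, defaults, single thread). Lasso and SVR standardise internally
and reuse training-side parameters at prediction; OLS is scale-equivariant
and uses raw features. Prediction refuses matrices whose column order differs
from training. All randomness (CV folds, subsampling) flows from the spec
seed.

On no-version-noise synthetic data the linear model is the strongest of the
suite and boosting the weakest — the near-linear age range rewards the simple
model, and the test suite asserts exactly that ordering rather than a fixed
absolute accuracy.

# The three designs

* **Design A — split permutations.** Per iteration a fresh 50-50 split; one
  model per release; all four source-to-target cells evaluated on both the
  train and test sides (cross-version "train" performance is the source model
  on the train rows of the target release, keeping the split semantics).
* **Design B — version shuffling.** One fixed split (the *initial
  iteration*); single-release models fit once and their four cells evaluated
  once; per iteration, fresh 50:50 release assignments within train and test,
  a mixture model fit per iteration, and every mixture-involved cell of the
  3×3 grid evaluated, so the grid has exactly nine cells.
* **Design C — joint permutations.** As B but the split is redrawn each
  iteration and all nine cells are evaluated every iteration.

Seeds are hierarchical: one master seed deterministically yields
per-iteration split, assignment and model seeds, so any sub-experiment
replays bit-identically. Bagged predictions are per-participant means over
the iterations in which the participant was tested in a cell; participants
never tested in a cell are absent, not imputed.

The package default is $i = 100$ iterations at desk scale; the full-scale
setting is $i = 1000$. The test suite and the acceptance script use
$n = 1000$–$2000$ participants and $i \le 50$ with 50 replicate cohorts,
which keeps a complete run in minutes on a single core while leaving the
Monte-Carlo bands comfortably tighter than the effects under test.

# The statistical battery

* **Performance metrics**: Pearson $R$; adjusted $R^2$ of
  `age ~ predicted` (plain, and with sex + site covariates); MAE and RMSE in
  years on raw residuals; Gaussian information criteria
  $AIC = n\log(RSS/n) + 2k$, $BIC = n\log(RSS/n) + k\log n$ with $k$ the
  feature count, so $BIC - AIC = k(\log n - 2)$ identically.
* **Overlapping dependent correlations**: two prediction vectors on the same
  participants are both correlated with age; differences are tested with
  Zou's (2007) modified-asymptotic confidence interval and the
  Hittner–May–Silver back-transformed-average-Fisher-$z$ statistic. Both are
  implemented from the formulas and validated by Monte-Carlo (type-I error
  and coverage under a trivariate-normal null) rather than against another
  package. The correlation between the two prediction vectors is computed on
  the common test participants, with bagged predictions for bagged cells.
* **Marginal means**: predictions from several cells on the same
  participants are stacked and fit by one OLS
  `predicted ~ cell + age + sex + site`; pairwise cell contrasts use the
  stacked model's residual df. The repeated-measures structure (the same
  participants appear in every cell) is deliberately not modelled — the
  stacked-OLS df convention is flagged here as a simplification.
* **Families for FDR**: Benjamini–Hochberg per reported table — the 12
  correlation comparisons, the 12 marginal contrasts, and the 9 per-cell sex
  differences each form one family.
* **Sex differences**: per cell, the sex coefficient of
  `predicted ~ age + sex + site`, male as the reference level so $b > 0$
  means higher predicted age in females.
* **Site check**: `predicted ~ site + age + sex + (1 | training release)`
  via `lme4`, Wald $z$ p-values for the site terms; a single release group
  degenerates to fixed-effects OLS, and a boundary (zero) group variance is
  reported with a flag rather than an error.
* **Paired feature-age comparison**: per-feature age correlations of the two
  releases compared by paired $t$-test with paired Cohen's
  $d = \bar{\Delta}/SD(\Delta)$. An exactly zero difference vector returns
  $t = d = 0$; a constant non-zero difference vector is an error (no
  variance to test against).

# Structure analyses

Per-feature cross-version correlations (overall and by age decade, bins
closed-open with the last bin absorbing the upper bound; bins under 3
participants are flagged and omitted), per-feature age correlations,
permutation feature importance (mean drop in $R^2 = 1 - RSS/TSS$ over seeded
column permutations; ties broken lexicographically by feature name), and PCA
on z-scored features with per-component loading-mass composition over the
three measure types. The region-level association between importance and
age correlation is exposed as an exploratory routine — region-mean Spearman
correlation per measure type — with its definition documented rather than
claimed canonical.

# Numerical and design choices

* Correlation targets must be strictly inside $(0, 1]$ for agreement and
  $(-1, 1)$ for age correlations; the boundary value 1 (no version noise)
  is allowed and collapses the two releases up to the affine map.
* The published site percentages (55.38/34.99/9.62) sum to 99.99 after
  rounding; weights within 1% of 1 are renormalised, anything further off is
  rejected.
* Odd split sizes: train gets the extra participant; shuffled assignments
  give the v5 side the extra row.
* `compute_metrics` accepts $n \ge 2$ (the two-point toy case is exact) and
  refuses constant predictions, for which a correlation is undefined.
* AIC/BIC use the RSS form without additive constants; $k$ defaults to the
  feature count of the dataset under evaluation.
* Degenerate inputs fail loudly and early: rank-deficient OLS designs name
  the offending columns, non-PSD correlation triples are rejected, missing
  values are rejected at fit and predict time.

# Known limitations

* The generator's penalty mechanisms are stylised; their magnitudes (offset
  0.25 SD, spread 1, age coupling 1, scale jitter 0.03, reliability tilt
  0.05, age-dependency jitter 0.03) are design choices — only the
  correlation-level targets are calibrated quantities.
* The mixture model's ability to absorb release offsets depends on the
  release being identifiable from the feature row; mechanisms that alter
  optimal weights per release (scale, reliability) are not absorbable and
  any real pipeline pair with large such components would narrow the
  shuffling advantage.
* The marginal-mean contrasts ignore the repeated-measures dependency across
  cells, matching the stacked-OLS convention; their p-values are
  anti-conservative to that extent.
* LightGBM is not part of the model suite; the suite covers linear, lasso,
  SVR and XGBoost.
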