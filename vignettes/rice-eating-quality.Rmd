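---
title: "Objective evaluation of cooked-rice eating quality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective evaluation of cooked-rice eating quality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceval)
```

## The problem

Sensory panels score cooked rice against a reference variety on a −3..+3
scale for the integrated value of organoleptic evaluation (IVOE) and its
component traits: viscosity, appearance, taste, hardness and fragrance.
Panels are the reference method but do not scale to the hundreds of
varieties a breeding program screens. `riceval` implements the objective
pipeline that replaces the two most instrument-tractable components —
appearance by image analysis and viscosity by texture analysis — and the
statistics that validate those proxies against panels and combine them into
a predicted IVOE.

## Yellow-area appearance scoring

Cooked rice that looks poor is yellowish with weak gloss; good rice is
white and glossy. The scorer converts the RGB image to HSV (hexcone
transform, hue on the unit circle with red at 0) and classifies a pixel as
*yellow* when its hue is **strictly below 0.167** — the sector from red
through yellow, up to 60°. The appearance proxy is
`100 * n_yellow / n_total`.

Two numerical choices deserve note:

* **Achromatic pixels.** When max = min over the channels, hue is defined
  as 0, so a perfectly neutral pixel classifies as yellow under the literal
  rule. Real cooked-rice photographs contain few exactly neutral pixels,
  but glossy highlights can come close. We keep the literal rule as the
  default for fidelity to the protocol and expose an optional
  `saturation_gate` (disabled by default): with it set, a pixel must also
  have saturation at or above the gate to count as yellow. Enabling it is a
  documented configuration choice, not the default behaviour.
* **Strict inequality.** The comparison is `<`, exactly as the threshold is
  printed; a pixel with hue exactly 0.167 is not yellow. The yellow-area
  percentage is monotone non-decreasing in the threshold, which the test
  suite checks as a property.

Scoring is whole-frame by default (the imaging protocol fills the frame
with rice); a rectangular `roi` handles frames with container edges. Each
sample is photographed four times; per-image scores are averaged by
`summarise_samples()` / the CLI, not inside the scorer, so the per-image
values stay inspectable.

## TPA texture features

The texture analyzer performs two compressions with an auto-trigger of
25 gf. Segmentation uses threshold crossings with hysteresis: a cycle is
recognised when force reaches the trigger, but its window is the whole
surrounding positive-force phase (entered when force rises above 0 gf,
exited when it returns to 0), so chatter near 25 gf cannot split a cycle.
The adhesion window is the contiguous negative run between the cycles.

Features follow the standard TPA definitions: `A1`, `A2` are the positive
areas of the cycles; `A3` the negative withdrawal area, reported as a
magnitude so that adhesiveness correlates *positively* with sensory
viscosity; `A4`/`A5` split `A1` at the force peak; `T1`, `T2` are the
positive-phase durations; hardness is the cycle-1 peak; springiness
`T2/T1`, cohesiveness `A2/A1`, resilience `A5/A4`, gumminess
`cohesiveness × hardness`, chewiness `gumminess × springiness`.

Numerical choices:

* **Integration variable is time** (areas in gf s). Texture-analyzer
  exports report A-values without units; force–time integration is the
  common instrument default and is what we document on every output.
  A displacement-based variant can be derived from the optional
  displacement column by the user; durations `T1`/`T2` are time-based.
* **Zero-crossing interpolation.** Areas are trapezoidal over the window,
  extended by linear interpolation to the exact zero crossings at both
  edges. For piecewise-linear curves this is exact, which is why the
  generator round-trip recovers areas to machine precision rather than to
  a sampling-dependent tolerance.
* **Brittleness** is the largest local maximum strictly before the hardness
  peak, subject to a minimum prominence of 5% of hardness so noise ripples
  do not register. "No qualifying peak" is a first-class `NA`, never 0.
* **Baseline** is 0 gf with no drift correction; undefined ratios (zero
  denominators) are per-feature `NA`s, never errors.

Batch processing averages the four replicates per sample and, when a
control sample is designated, records each sample's feature differences
from the control — the batch-correction convention when all samples are
measured against a shared reference variety.

## Panel statistics

**ANOVA.** The panel design is balanced: every variety scored in every
year. `anova_two_way()` fits the additive decomposition
`score ~ year + variety` after averaging sensory replicates to one value
per variety-year cell (the default `replicate_policy = "mean"`), giving df
`y−1` / `v−1` / `(y−1)(v−1)` — for 322 varieties in 2 years: 1/321/321.
This no-replicate-term layout is the one under which the published panel
table's degrees of freedom reproduce, which is why it is the default; raw
replicates can instead be pooled into the error term.

Published ANOVA tables often print mean squares rounded too coarsely to
recover F (the shipped reference table prints an IVOE variety MS of 0.3
although 50.03/321 = 0.156). `anova_f_from_ss()` therefore recomputes F
directly from the sums of squares; with equal variety and error df this
reduces to `SS_variety / SS_error`, and all six variety F values of the
reference table reproduce this way within rounding.

**Heritability.** `broad_sense_h2()` uses the expected-mean-square
estimator with variety as a random effect:
`var_G = max(0, (MS_variety − MS_error)/r)`, `var_E = MS_error`,
`h² = var_G/(var_G + var_E)`. The truncation at zero keeps `h²` in [0, 1].
`r_reps` defaults to the number of years (2): in the averaged layout the
years are the replication effect entering the variety mean square. The
reference study's printed h² values (0.78 for IVOE, etc.) are shipped only
as documentation — they are not derivable from the published ANOVA table
under `r ∈ {2, 3}`, so the package asserts nothing about them and instead
validates the estimator by simulation, where it recovers the generating
`h² = 0.75` to within ±0.01 in the mean over 200 panels.

**Associations.** Pearson correlations (with t-transform p values), the
paired t test with a 95% CI for instrument-vs-panel comparisons, and a
pairwise-complete trait correlation matrix on per-variety means. No
multiple-testing correction is applied, matching the source analysis.
Degenerate inputs (zero variance) are flagged, not fatal.

## Eating-quality models

`fit_ols()` is ordinary least squares via `stats::lm` with explicit
rejection of constant and collinear predictors. `best_subset()` enumerates
all non-empty predictor subsets (bounded at p = 20) and reports the best
per size under R², adjusted R² or BIC; R² is the default criterion for
fidelity to the source analysis, with the caveat — documented and tested —
that raw R² always selects the full model, which is exactly why the
adjusted criteria are offered.

The four published IVOE models are shipped as immutable constants with
unit annotations (`adhesiveness` in gf s, `yellow_area` in percent,
sensory traits on −3..+3). The source does not state the predictor scaling
it used; annotating the constants and letting `predict_ivoe()` verify a
caller-supplied `units` declaration is our guard against silent mismatch
(e.g. a 0–1 yellow *fraction* against a model expecting percent).
`evaluate_predictions()` reports the squared Pearson correlation between
predicted and observed scores — the hold-out calibration statistic quoted
for the published models — which is affine-invariant and deliberately
distinct from the fit-time coefficient of determination; both are labelled.

## Synthetic data: what it emulates, and what it does not

The generators define the package's test conditions.

* `simulate_rice_image()` places ellipse-shaped yellow "grains" until
  exactly `round(yellow_fraction × n_pixels)` pixels carry the yellow
  label, then renders yellow pixels with hues in [0.09, 0.15] and white
  pixels with a faint cool tint (hue ≈ 0.62, saturation 0.02–0.05) —
  *not* perfectly achromatic, since neutral pixels would classify yellow
  under the literal rule. Brightness noise acts on the HSV value channel
  only, so it cannot move a pixel across the hue threshold: the
  constructed labels are exact ground truth, defined by the generator and
  never re-derived from the classifier. Default frames are 320 × 240 —
  large enough for sub-0.1-point percentage granularity while keeping a
  20-image sweep under a minute.
* `simulate_force_curve()` builds a piecewise-linear two-cycle profile
  whose closed-form features are emitted alongside, with the exact
  breakpoint times inserted into the sampling grid (default 500 Hz) so the
  sampled polyline *is* the analytic curve.
* `simulate_panel()` draws per-trait variety effects `N(0, var_G)` (default
  0.15), fixed year offsets (SD 0.1), and residuals `N(0, var_E)` (default
  0.05) — giving a generating `h² = 0.75`, the high end observed for
  eating-quality traits — around the published trait means, for 322
  varieties × 2 years. IVOE is the latent linear Model-1 combination
  (0.20, 0.35, 0.59, intercept 0.13) plus noise calibrated so the
  observation-level signal fraction is 0.87, the published fit quality.
  Scores are clipped to [−3, 3]; at the default variances the clipping
  rate is ~0 and is always reported.

What the synthetics do **not** emulate: real grain shape, gloss and
specular highlights, white-balance drift, instrument force noise and
baseline drift, panelist disagreement, genotype × year interaction beyond
additivity, and correlated component traits (traits are generated
independently except through the IVOE). Passing tests therefore certify
the *computational* pipeline — segmentation, integration, classification
and estimation are correct on data with known truth — not field
performance of the proxies; the study-scale correlations between proxies
and panels require the original field data, which is not deposited.

## Problem sizes and determinism

Test and acceptance runs use 320 × 240 images (20-image sweeps), 500 Hz
curves (50-curve sweeps), and 200 simulated panels of 322 × 2, chosen to
keep statistical error well inside the assertion tolerances (e.g. the
standard error of the 200-panel mean ĥ² is ≈ 0.004 against a ±0.05 band)
at desk-scale runtimes. Every stochastic step is seeded; generators require
a seed and are bit-reproducible given it.

## Known limitations

* The hue rule's treatment of near-neutral pixels follows the literal
  protocol; original pipelines may have differed (unstated), so absolute
  yellow-area values on glossy images can differ between implementations —
  the saturation gate is the mitigation.
* Areas are force–time; instruments that report force–displacement areas
  will differ by the (constant) test-speed factor.
* `best_subset()` is exhaustive and intentionally bounded at 20
  predictors.
* The published model constants are applied as printed; whether they were
  fitted on raw or standardized predictors, and whether adhesiveness was
  raw or control-relative, is not stated in the source and cannot be
  resolved without the original data. Predictions should be interpreted
  on the package's documented unit conventions.
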