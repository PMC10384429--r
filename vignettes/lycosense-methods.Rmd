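---
title: "Colorimetric lycopene estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric lycopene estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lycosense)
```

# The measurement problem

Lycopene is the carotenoid that turns a ripening tomato red; it is both a
consumer quality criterion and a compound of pharmaceutical interest. The
reference assay, high-performance liquid chromatography (HPLC), is accurate
but slow, expensive and destructive. Because lycopene accumulation and
epicarp color change are two faces of the same ripening process, the skin
color of an intact fruit carries enough information to estimate the
concentration non-invasively. `lycosense` implements such a colorimetric
soft sensor as a four-stage pipeline: image acquisition (a JPEG or PNG of
one fruit on a colored backdrop), background segmentation, color-feature
extraction, and regression onto lycopene in ppm (mg per kg).

# Segmentation

Segmentation happens in HSV space, where hue isolates spectral color from
brightness. Tomato hues run from green (h near 1/3) through yellow and
orange to red (h near 0), i.e. they never enter the cyan-to-magenta arc. The
default therefore treats the hue band [0.466, 0.842] (unit hue scale) as
*background* and its complement as fruit; a blue or cyan backdrop falls
inside the band while every maturity stage from green to deep red falls
outside. Saturation and value windows default to [0, 1] (no effect) but can
be narrowed, e.g. to drop near-black shadow pixels. Stray small blobs
(glints, debris) are removed by deleting connected components smaller than
400 px — components of exactly 400 px survive. Component labeling uses
8-connectivity by default (4-connectivity is available); the labeling is a
single-pass flood fill implemented in C++ for full-resolution images.

Two conventions here are deliberate interpretations rather than givens: the
hue interval is stated in the sensor literature as a pair of thresholds
without saying whether the band is kept or removed, and we remove it because
both green and red fruit must survive segmentation; and the connectivity of
the area filter is unstated, so we default to the blob-filtering standard
of 8.

# Color features

Within the fruit mask three kinds of features are computed:

* **Pixel-class areas.** Each masked pixel is classed RED, GREEN or BLUE
  when that channel exceeds both others by a margin `delta` (default 10
  intensity units), else NONE. The class counts (`area_red`, `area_green`,
  `area_blue`) are raw pixel counts; `normalizedAreas()` divides by fruit
  size.
* **L\*a\*b\* aggregates.** The masked-pixel means of L\*, a\*, b\* under
  sRGB primaries, D65 white point, 2° observer. The conversion is computed
  directly from the IEC 61966-2-1 linearization and the standard sRGB→XYZ
  matrix, with the reference white taken as the matrix's own row sums so
  that pure white maps to exactly L\* = 100 and a\* = b\* = 0; the
  implementation agrees with independent textbook evaluations to better
  than 0.01 per channel. The camera is assumed to produce sRGB — no
  profile or white-balance metadata is modeled.
* **Chromaticity ratio** a/b, the classic low-cost ripeness index.

The fuzzy model's membership functions are defined on non-standard input
domains — L in (0, 2558.3], a in (0, 1736], b in (−210, 358] — that do not
match the conventional L\* ∈ [0, 100], a\*, b\* ∈ [−128, 127] ranges, and no
mapping between the two is given anywhere. This unrecoverable ambiguity is
isolated behind one seam: a configurable affine `FeatureScaling` (per-input
gain and offset) whose default maps the conventional ranges linearly onto
the fuzzy domains. `identityScaling()` disables the mapping. The synthetic
feature generator emits values directly in fuzzy-domain units, so the
inference engine is testable independently of this choice.

# The Takagi–Sugeno estimator

The core estimator is a three-input Takagi–Sugeno fuzzy system with eight
triangular membership functions — Low/Medium/High on L, Low/Medium/High on
a, Low/High on b — and a rule base formed as the full Cartesian grid over
membership combinations: 3 × 3 × 2 = 18 rules. For input x the i-th rule
fires with strength $w_i$, the t-norm (product by default, min available)
of its antecedent degrees, and contributes an output level
$Z_i(x) = p_i \cdot x + r_i$ (first order; zero-order constants available).
The crisp output is the weighted average

$$\hat{y}(x) = \frac{\sum_i w_i Z_i(x)}{\sum_i w_i}.$$

Membership breakpoints (all configurable):

| variable | Low | Medium | High |
|---|---|---|---|
| L | 1 → 0 over [0, 1285] | triangle (10.7, 1285, 2558.3) | 0 → 1 over [1285, 2558.3] |
| a | 1 → 0 over [0, 753] | triangle (0, 753, 1736) | 0 → 1 over [753, 1736] |
| b | 1 → 0 over [210, 358] | — | 0 → 1 over [210, 358] |

Three reconstruction decisions were genuinely open:

* The printed formulas for Medium_L and High_L are typographically
  corrupted; the shapes above are the unique triangular forms consistent
  with the legible breakpoints (10.7, 1273…1285, 2558.3), the domain split
  at 1285, and the Low/Medium/High pattern that the a-variable exhibits
  cleanly. The a-variable identities Low+Medium = 1 on (0, 753] and
  Medium+High = 1 on (753, 1736] hold exactly by construction and are
  asserted to 1e-12 in the tests.
* The Low_b line (358 − b)/148 exceeds 1 below b = 210; all degrees are
  clipped to [0, 1], the standard fuzzy convention, preserving the printed
  segments on [210, 358].
* The original rule list is not available; the full-grid rule base is the
  only construction matching the stated count of 18 exactly, and makes rule
  coverage complete: every in-domain input fires at least one rule. Inputs
  outside the domains raise an explicit "outside rule coverage" error, never
  NaN.

Published descriptions of this sensor architecture count four inputs while
defining memberships for exactly three variables; the fourth is never
identified, so the model is built with three (additional variables can be
configured with user-supplied breakpoints).

## Consequent fitting

Premise memberships stay fixed at their breakpoints; only the consequent
coefficients are estimated, by the ANFIS hybrid step: with normalized firing
strengths $\bar w_{ji} = w_{ji} / \sum_k w_{jk}$, the prediction is linear
in the 18 × 4 = 72 consequent parameters, and the stacked system is solved
by least squares. We always use the minimum-norm solution via the
Moore–Penrose pseudoinverse: the full-grid design is typically
rank-deficient (corner rules fire rarely), and minimum-norm least squares
handles the overdetermined, underdetermined and rank-deficient cases
uniformly, with a warning whenever the rank is below the parameter count.
Samples firing no rule are rejected with a warning. A full ANFIS backward
pass (premise tuning) is intentionally not implemented: the breakpoints are
fixed by formula.

# Baselines

* **Linear regression (LR)** of ppm on the a/b ratio, by ordinary least
  squares; at least two distinct ratios required.
* **Feed-forward network (MNNR)**: 10 sigmoid hidden units and a linear
  output, trained full-batch by Levenberg–Marquardt on the analytic
  residual Jacobian. Inputs are z-scored internally (sigmoid training is
  unstable on raw fuzzy-domain magnitudes); weights initialize uniformly in
  [−0.5, 0.5] from the stated seed, making training bit-reproducible. The
  damping schedule is the classic Marquardt procedure: per epoch, first try
  λ/10; if that fails to improve, try λ, inflating by 10 until a strictly
  improving step is found (λ starts at 1e-3). One epoch is one accepted
  step, so the accepted-step MSE trace is non-increasing by construction;
  if no damping yields an improvement the best-so-far network is returned.
  Ten epochs is the default training budget.

# Evaluation harness

`compareModels()` fits a roster of model specifications and reports, per
model, the squared Pearson correlation between observation and prediction
(the headline "R²" in this sensor tradition), the coefficient of
determination 1 − SSE/SST alongside (the two differ for biased predictors),
and the signed mean residual mean(pred − obs). Metrics are computed on the
training set by default — the protocol that matches small HPLC-labeled
calibration studies, where no held-out split is practical with 18 fruit —
and leave-one-out cross-validation can be reported alongside (`loo = TRUE`).
Reported R² values should therefore be read as goodness of fit, not
generalization estimates.

# The synthetic study generator

Because the original 18-fruit image set with HPLC labels is not
distributable, the generator builds a structurally equivalent study:

* **Design**: 18 single-fruit images — 5 green (G), 3 turned (T), 3 pink
  (P), 2 light red (LR), 5 red (R) — at 768 × 1366 px.
* **Scene**: a centered fruit ellipse on a uniform backdrop of hue 0.65
  (blue, inside the background band), plus 3 stray specks of under 400 px
  each that the area filter must remove. The true mask is emitted with
  every image.
* **Fruit color**: each fruit pixel takes the class's red anchor color with
  probability `redFraction` (0.02 / 0.30 / 0.55 / 0.78 / 0.97 for
  G/T/P/LR/R) and the green anchor otherwise, plus Gaussian jitter
  (sd 8). This ripening-mottle model makes the red-area fraction a
  controlled, monotone correlate of maturity class.
* **Label law**: ppm = 90 · r^1.5 + N(0, 2), truncated at 0, with
  r = area_red / (area_red + area_green) measured on the generated image.
  λ_max = 90 ppm anchors the scale to the HPLC calibration ceiling of the
  original study (≈ 89 ppm); the exponent 1.5 and the 2 ppm noise are
  synthetic choices giving a smooth, monotone, mildly nonlinear surface
  with realistic label scatter. All three are configuration, not claims
  about tomatoes.

`generateFeatureTable()` bypasses imaging entirely: it samples (L, a, b)
uniformly from the fuzzy domains and labels them either with a smooth
default law or with a *planted* Takagi–Sugeno model (noiseless by choice),
which is what the parameter-recovery tests use. Planted-model labels are
not truncated at zero, so the table remains an exact realization of the
planted surface.

What the generator does **not** emulate: specular highlights, shading
gradients, camera noise correlations, the calyx and stem scar, touching or
multiple fruit, and the seven optical bandpass filters of the original
device (filter names are carried only as free-text tags). Tests passing on
synthetic scenes therefore validate the algorithmic contracts — not
field performance on real fruit, which requires a real calibration set.

# Numerical choices

* Membership evaluation is piecewise-linear with shoulder conventions
  (left foot = peak ⇒ degree 1 left of the peak, and symmetrically), and
  degrees are clipped to [0, 1]. Domains are half-open (lo, hi];
  out-of-domain degrees are exactly 0.
* The zero-coverage error (Σw = 0) is raised at predict time with the
  offending input echoed, rather than propagating NaN.
* Least-squares solutions use the SVD pseudoinverse with the default
  relative tolerance; JSON serialization writes 17 significant digits, the
  IEEE-754 double round-trip precision, so models reload bit-exactly.
* Pixel classes are decided with non-strict inequalities, so a channel
  exactly `delta` above both others counts as dominant.
* Negative model outputs are clamped to 0 ppm only at the pipeline
  boundary (`predictFromImage`); the raw value is preserved in the record.

# Problem sizes

The test suite exercises unit properties on small fixtures (32 × 32 masks,
96 × 160 synthetic images, feature tables of 30–200 rows) and runs the full
768 × 1366, 18-image study once end to end; the acceptance script
recomputes the structural counts, partition identities on 10⁴-point grids,
consequent recovery on 100 planted samples, the full-resolution study, and
the baseline contracts on 50-sample training sets.

# Limitations

* The feature-scaling seam is a documented guess; absolute predictions on
  real images are only meaningful after calibrating against reference
  measurements.
* Training-set R² on 18 samples with a 72-parameter consequent stage is
  nearly saturated by construction; use the leave-one-out option when
  comparing model families.
* Single-fruit scenes only; no illumination correction; the backdrop must
  fall inside the configured hue band.
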