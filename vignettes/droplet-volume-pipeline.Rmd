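---
title: "Measuring and modelling bioprinted droplet volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling bioprinted droplet volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropsizer)
```

## The measurement model

A small droplet resting on a flat substrate is, to good approximation, a
spherical cap: surface tension dominates gravity at microlitre volumes
(Bond number well below one for aqueous inks at millimetre scale), so the
side profile is a circular arc cut by the substrate line. Three quantities
describe the cap completely: the base diameter $D$ (the chord on the
substrate), the contact angle $\theta$ between the arc's tangent at the
contact point and the substrate, and the derived volume

$$ V = \frac{\pi D^3}{24}\,
   \frac{2 - 3\cos\theta + \cos^3\theta}{\sin^3\theta}, $$

in µL when $D$ is in mm. This closed form is algebraically identical to the
classical cap formula $V = \tfrac{\pi h}{6}(3a^2 + h^2)$ with base radius
$a = D/2$ and apex height $h = a(1-\cos\theta)/\sin\theta$; the test suite
checks the identity to $10^{-9}$ relative error across
$D \in [0.5, 5]$ mm, $\theta \in [10^\circ, 170^\circ]$. At
$\theta = 90^\circ$ it reduces exactly to the hemisphere $\pi D^3/12$.

All geometry is computed in a y-up physical frame. Image pixel rows grow
downward, so the pipeline flips rows (`y_physical = height - 1 - y_pixel`)
before any angle is computed; this fixes the branch of
$\theta = \arccos((a - c_y)/r)$ so that a sphere center above the baseline
means a hydrophobic cap ($\theta > 90^\circ$), as on silane-coated slides.
The droplet is always taken to be the cap above the baseline — sessile-drop
physics leaves no other choice.

## From photograph to cap

`measure_droplet()` composes five stages:

1. **Preprocessing** (`preprocess_droplet()`). Luminance grayscale
   conversion; a Canny-style edge map (Gaussian smoothing at
   $\sigma = 1.4$ px, Sobel gradients, four-direction non-maximum
   suppression, double-threshold hysteresis at 50/150 on the 0–255 scale);
   and Otsu binarization with the droplet dark. The analysed composite is
   the pixel-wise maximum of the inverted binary view and the edge map over
   an attenuated (weight 0.5) grayscale view: the silhouette boundary is
   reinforced for the detector while interior contrast survives for visual
   audit. The thresholds and weights are exposed in `preprocess_config()`;
   the defaults were chosen once for dark-on-light silhouettes and left
   alone.

2. **Circle detection** (`detect_circle()`). A two-stage gradient-voting
   Hough transform: each edge pixel votes along its gradient direction (both
   orientations) at every radius between 5 % and 60 % of the smaller image
   dimension; accumulator peaks are refined on a 0.5 px grid and scored by
   the fraction of circumference supported by edge pixels within 0.75 px of
   the best radius bin. The accumulator extends one radius beyond the frame
   vertically because a flat cap ($\theta < 90^\circ$) has its sphere center
   below the substrate. Selection is by support score with near-ties
   (within 0.05) resolved toward the larger radius, then the topmost
   center. Center and radius stay at 0.5 px accumulator resolution; no
   further sub-pixel refinement is applied.

3. **Baseline detection** (`detect_baseline()`). The substrate line is the
   lowest long horizontal edge run below the droplet apex. Runs are
   computed with one row of vertical tolerance (edge thinning can split a
   perfectly horizontal edge between adjacent rows), and the search region
   starts at the top of the detected circle rather than its center — for
   flat caps the center lies below the substrate, so a center-relative
   search would exclude the true baseline. The qualifying row is refined to
   sub-pixel precision by a vertical-gradient centroid across the edge,
   with a second pass that re-centers the averaging window. The cap volume
   is strongly sensitive to the baseline offset
   ($\mathrm{d}V/V \approx 3\,\mathrm{d}a/r_s$ near $60^\circ$), which is
   why the baseline — unlike the circle — is localized below one pixel. A
   known baseline row can be supplied as an override.

4. **Frame conversion and intersection.** Pixel coordinates flip to the
   physical frame and scale by the calibration factor (mm/px from a known
   length and its pixel span); `circle_baseline_geometry()` returns the
   contact points, chord and angle, with a classed error when the line
   misses the circle.

5. **Volume.** `cap_volume()` evaluates the formula above; angles are
   reported to 0.01° and lengths/volumes to four significant figures in
   the CSV writer, full precision in the returned tibbles.

`measure_batch()` maps this over files, records one row per image in input
order, and converts per-image failures into a `status` column instead of
aborting; re-running a batch is byte-identical.

## What the synthetic renders emulate — and what they do not

`render_droplet()` draws the exact cap silhouette (antialiased with a
one-pixel coverage ramp, continuum contact line on a pixel boundary, solid
dark substrate), then applies Gaussian blur ($\sigma = 1$ px by default)
and seeded additive Gaussian noise. The defaults mirror a typical
goniometer-style acquisition at 0.009728 mm/px; frames are auto-sized so
the sphere radius falls inside the detector's default radius range. On
these renders the full pipeline recovers volumes to within 2 % noiselessly
and within 5 % under noise at $\sigma = 5/255$, and it agrees with a
manual five-point circle-fit oracle within 3 %.

Real photographs differ in ways the renderer deliberately ignores: needle
shadows and reflections, meniscus brightness gradients, gravity-flattened
profiles at larger volumes, non-axisymmetric droplets, and uneven
illumination. Passing the render-and-recover suite therefore demonstrates
the correctness of the geometry and detector chain, not robustness to
every laboratory artefact; the contract is that any image in which the
silhouette boundary survives edge detection is measured consistently.

## The tabular generator

No parameter-to-volume dataset is published for this design space, so
`generate_records()` simulates one over the factorial grid of two bioink
viscosities (10.03 / 24.66 mPa·s), three nozzle inner diameters
(0.337 / 0.26 / 0.21 mm), three dispensing times (0.05 / 0.1 / 0.15 s),
two pressures (1.5 / 2 psi) and two cell concentrations (9.33×10⁵ and
1.87×10⁶ cells/mL — concentrations are stored per mL). The response
surface is a power law anchored at 6.54 µL (a realistic medium droplet)
at the grid midpoints, with exponents — time 1, nozzle 1.5, pressure 1,
viscosity −0.3, cells 0.02 — chosen once so that the per-parameter response
span is ordered *time > nozzle > pressure > viscosity > cell
concentration*, the ranking observed on real dispensing hardware. A
`"poiseuille"` preset (nozzle exponent 4) is provided as a physically
motivated stress test in which nozzle diameter dominates instead; the two
presets bracket the plausible hardware behaviours rather than guessing one.
Volumes get 2 % multiplicative Gaussian noise by default (a tight but
realistic repeatability for a well-controlled pneumatic dispenser), and the
two viscosity levels are always exactly balanced. The noiseless surface
spans about 1.8–19.3 µL over the grid, covering the 3.54 / 6.54 / 11.98 µL
droplet size groups used by the imaging fixtures.

## The modelling harness

`split_dataset()` is a seeded shuffle-and-cut (70/30 by default; 1758
records give 1230/528). `kfold_cv()` partitions the training set into ten
near-equal folds exactly once each; per-fold train/validation MAE, MSE,
RMSE and R² are recorded with wall-clock times. `grid_search()` evaluates
every hyperparameter combination by cross-validation and selects the
minimal mean validation RMSE, with exact ties resolved toward the simpler
model — the selection criterion had to be fixed somewhere, and validation
RMSE is the conventional choice for regression tuning curves.

The five engines:

* **Decision tree** — `rpart` with complexity pruning disabled
  (`cp = 0`) so `max_depth` (default 7) is the active capacity control.
* **Random forest** — `randomForest`, default 10 trees, all five features
  considered at every split (the regression-forest convention in
  scikit-learn-style harnesses; `randomForest`'s own p/3 default cripples a
  five-feature forest). `min_samples_leaf` maps to `nodesize`;
  `min_samples_split` is approximated through it, as the library exposes no
  separate split threshold.
* **Polynomial regression** — full multivariate monomial expansion up to
  the requested total degree (default 7; 792 terms in five standardized
  features) with pivoted-QR least squares. The factorial design grid has
  only 72 distinct parameter combinations, so the design matrix is heavily
  rank-deficient; aliased coefficients are treated as zero at prediction,
  which is the usual minimum-norm-flavoured resolution.
* **MLP** — two rectified hidden layers (64, 32), linear output, Adam at
  learning rate 10⁻³, batch 32, 100 epochs, He initialization,
  mean-squared-error loss. Features *and* response are standardized; the
  response scale is restored at prediction. With a smooth five-dimensional
  surface this converges comfortably within 100 epochs.
* **LSTM** — each record is a length-1 sequence of the five-feature
  vector through one 32-unit LSTM cell (zero initial state) and a linear
  head, trained like the MLP. With no published temporal ordering for
  dispensing records, the one-step framing keeps the recurrent
  architecture honest (the recurrent weights participate in the forward
  pass but receive zero gradient) without inventing a sequence dimension.

Both networks are plain seeded matrix implementations, so fits are exactly
reproducible given the spec seed. Trees use raw features (scale-invariant);
only the standardized engines are scaled. `evaluate_model()` reports
MAE, MSE, RMSE and R²; R² is left unclamped (negative for worse-than-mean
predictors) and is `NaN` with a warning when the test response is constant.
`compare_algorithms()` re-splits and re-seeds on every repeat — the more
conservative reading of "independent iterations" — and reports mean ± sd
per algorithm plus mean train/test times; only time *orderings* are
asserted anywhere, since absolute timings are hardware-bound.
`feature_importance()` normalizes the random forest's summed
variance-reduction importances to one.

## Numerical choices and degenerate inputs

* Tie-breaks: circle candidates within 0.05 score are ties → larger
  radius, then topmost center; grid-search ties → simpler model; radius
  histogram ties → larger radius.
* Degenerate inputs: zero-size images, empty batch lists, non-intersecting
  baselines, blank edge maps, constant responses and malformed CSV cells
  all raise classed, stage-named errors (or warnings where a defined
  result exists, e.g. uniform importances for a constant target).
* Determinism: every stochastic step (generation, rendering noise, splits,
  folds, weight initialization, batch order) is driven by an explicit seed
  and restores the caller's RNG state.
* Problem sizes: the test suite renders a 100-image sweep
  ($D \in [1, 3.5]$ mm, $\theta \in [60^\circ, 120^\circ]$) plus a
  30-image three-group fixture, and trains all five models on the
  1758-record synthetic dataset — the same sizes the acceptance script
  uses, chosen to exercise the full design space at interactive runtimes.

## Limitations

Single droplet per frame; horizontal substrate only; no Young–Laplace
correction for gravity-flattened caps; no reflection/meniscus handling;
the LSTM is a capacity-matched recurrent baseline, not a sequence model;
and synthetic data, however carefully constructed, cannot certify
performance on any particular laboratory's imagery — the generators bound
the algorithmic behaviour, not the acquisition physics.
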