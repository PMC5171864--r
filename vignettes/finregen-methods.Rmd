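---
title: "Quantifying caudal-fin regeneration and mineralization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying caudal-fin regeneration and mineralization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Adult zebrafish regrow an amputated caudal fin in under two weeks, and the
new bony rays (lepidotrichia) re-mineralize as the tissue grows back.
Alizarin red S (AR-S) binds calcium and fluoresces red over mineralized
bone, so a pair of micrographs per fin — bright-field for the soft tissue,
fluorescence for the mineral — captures both processes in one longitudinal
plane.  The difficulty is not imaging but *comparability*: fish stocks are
heterogeneous in size, so raw areas confound treatment effects with
specimen size, and a treatment can change the mineralized area simply by
changing how much tissue regrew.

`finregen` implements a standardized analysis chain for such image pairs:

1. **Morphometry.** From the amputation-plane annotation and the two
   images it measures REG (regenerated area, mm^2), RMA (real mineralized
   area: the AR-S-positive pixels inside REG), EMA (estimated mineralized
   area: the polygon joining the most distal mineralized tip of each ray),
   STU (stump width: the length of the amputation plane), and RAY (mean
   mineralized ray width at the first intersegment joint below the plane).
2. **Correction.** REG is normalized by STU and RMA by RAY.  These
   within-image correctors remove inter-specimen size variation without
   extra handling steps (weighing, length measurement); REG/WEI and
   REG/LEN are computed for comparison when metadata are present.
   `(RMA/RAY)/(REG/STU)` estimates the mineralized fraction of the
   regenerate.
3. **Phase model.** RMA/RAY plotted against REG/STU is flat while the
   early regenerate is still unmineralized (phase P1) and then grows
   linearly with regeneration (phase P2).  A continuous two-segment
   ("broken-stick") regression estimates the breakpoint `x0`; the linear
   P2 relation, fitted inside the 84–240 hours-post-amputation screening
   window, is the *standard curve* against which treated groups are
   compared.  A late phase (mineralization continuing after outgrowth
   stops, beyond 240 hpa) is never fitted; later records are excluded with
   a warning.
4. **Effect classification.** A treated group displaced *along* the
   standard curve has a regenerative effect (`dx`, difference in mean
   REG/STU); a group displaced *off* the curve has a mineralogenic effect
   (`dy`, difference in mean residual).  Each axis is called
   `under`/`none`/`over` by an unpaired t test at `alpha = 0.05`.
5. **Intensity analysis.** Within the mineralized mask, the luma (YUV Y)
   histogram over the 15–254 spectrum acts as a proxy for mineral density
   or hemiray thickness: denser or thicker bone binds more dye and yields
   brighter pixels.  The relative mass in the low (15–29) and high (30–44)
   intensity classes is compared between groups, which detects effects on
   the transverse plane that area-based metrics miss.

## Segmentation choices

* **Coordinates.** All pixel coordinates are R-native: 1-based
  `(row, col)` with row 1 at the top.  Areas convert to mm^2 via
  `mm_per_px^2`; `calibrate_mm_per_px()` derives the scale from a ruled
  calibrator image.
* **Amputation plane.** A straight two-point annotation.  The raster is
  partitioned by the sign of the distance to the infinite line; pixels
  exactly on the line count as distal (an arbitrary but fixed convention,
  needed so the two half-planes always partition the raster).
* **Regenerate (REG).** Tissue is darker than the clear field, so the
  default rule takes pixels below 0.9 times the background luminance,
  keeps the largest 8-connected component and fills holes.  The
  background level is the modal luminance of the *brightest decile* of
  the distal half-plane: the regenerate itself often covers most of that
  half-plane, so a global mode would land on tissue.  A manually traced
  outline always wins over the automatic rule, mirroring the manual
  workflow the method standardizes.
* **Mineral (RMA).** A conjunctive RGB band test: green and blue in
  0–30, red from a per-treatment minimum up to 255.  The red minimum is
  tuned automatically with Otsu's threshold on the red histogram of the
  distal half-plane, clamped to 20–60 — deterministic and analyst-free —
  and a manual `threshold_spec()` always takes precedence.  If no distal
  pixel reaches the search range the spec is returned flagged
  (`empty_signal`), and RMA is 0.
* **EMA.** Mineral components are grouped into rays by overlapping extent
  along the plane axis (intersegment joints split one ray into several
  components); each ray's tip is its pixel of maximal distance from the
  plane (ties broken toward the dorsal end), and the tip polygon is
  closed along the plane.  Components under 20 px are discarded as
  speckle so noise cannot contribute tips.  EMA is reported for
  comparability but never used downstream: it includes inter-ray tissue
  and systematically overestimates the mineralized area, so RMA is the
  preferred measure.
* **RAY.** For each ray proximal to the plane, the first intersegment
  joint is the gap between the two mineral segments nearest the plane,
  and the width is the across-ray extent of the plane-adjacent segment at
  the distal border of that gap.  Working with segment gaps in
  plane-aligned coordinates is equivalent to walking the medial axis for
  the quasi-straight rays in scope, and considerably more robust.  Rays
  whose stump shows no joint in the image are skipped with a warning; the
  RAY mean uses all measurable rays (configurable by supplying manual
  widths, which always win).
* **Joint/bifurcation counts.** For chronology-style summaries,
  `count_joints_bifurcations()` closes a single-ray mask with an
  anisotropic brush (bridging joint gaps along the ray without merging
  sister branches), thins it with Zhang–Suen skeletonization, and counts
  joints as skeleton runs outside the mineral and bifurcations as branch
  point clusters.  These counts are descriptive only; the package
  deliberately does not use segment counts as a mineralization measure.

## The phase model in detail

`fit_segmental()` minimizes the least-squares error of

\[ y = a + b\,x \;(x \le x_0), \qquad y = a + b\,x_0 + c\,(x - x_0) \;(x > x_0) \]

with continuity imposed at the breakpoint.  The profile SSE is evaluated
at every interior data value and midpoint and then refined numerically
inside each bracketing inter-datapoint interval, so the optimum matches an
exhaustive fine grid; SSE ties resolve toward the smaller `x0`.  Each
segment must be supported by at least three points.  Because the
one-segment line is nested in the model, the segmental SSE can never
exceed the simple-regression SSE; when it fails to improve on it the
breakpoint is flagged unidentifiable.  The first slope `b` is left free by
default (`constrain_b0 = TRUE` pins the pre-mineralization phase flat);
both options are reported identically.  `fin_reference_x0` (0.5860, from a
60-specimen fixed-stained reference time course) is provided purely as a
plot overlay.

The screening window is expressed in hours post-amputation (84–240); a
gate on `x > x0` can be used instead by filtering on the fitted phase
labels.  `build_standard_curve()` requires at least 10 control points in
the window and stores 95% prediction-band parameters, which are meant for
flagging single specimens, not for group calls.

`classify_effect()` defines `dy` as the *difference* in mean curve
residuals (treated minus control) rather than the treated mean residual
alone; the two coincide up to the control's near-zero mean residual when
the curve was fitted on the controls, and the difference form makes the
call antisymmetric under swapping the groups.

### Calibration of the group calls

With two t tests at `alpha = 0.05`, a treatment that truly affects
neither axis is called fully neutral with probability at most
`(1 - alpha)` and, for independent tests, about `(1 - alpha)^2` (~90%).
The two axes are correlated within a time point (residuals from a steep
standard curve anti-track REG/STU), which raises the joint no-call rate
to roughly 94% in the package's simulations — but a per-axis false-positive
rate of `alpha` is irreducible by design.  Screens should therefore treat
isolated borderline calls on a single axis with the usual multiple-testing
caution.

## Statistics

The group statistics are the classical ones: Pearson correlation with the
`t = r\sqrt{(n-2)/(1-r^2)}` test, fixed-effects one-way ANOVA, Tukey's HSD
with the Tukey–Kramer statistic for unequal group sizes and p-values from
the studentized-range distribution, and the pooled-variance unpaired t
test (Welch optional; the pooled form is the classical default for this
assay).  Degenerate inputs follow explicit conventions: zero variance in
both samples gives p = 1 for equal means and p = 0 otherwise (logged), and
a zero-variance ANOVA is flagged undefined rather than reported as F = 0.
Grubbs' outlier test uses the closed-form critical value
`((n-1)/sqrt(n)) sqrt(t^2/(n-2+t^2))` with the upper `alpha/(2n)` t
quantile (two-sided default), is applied once with no iterative removal,
and on tied extremes tests the first encountered.  `alpha = 0.05`
throughout.

## The synthetic-fin generator

No public reference images exist for this assay, so the package ships a
generator (`synthetic_fin_spec()`, `render_fin()`) that renders
bright-field/fluorescence pairs with exact ground truth: a fan of 16
quasi-parallel rays across a 2 mm stump at 0.005 mm/px (matching the
mm-scale of real fins), a parabolic regenerate dome, per-ray mineral
columns split by intersegment joints every ~200 µm with 20 µm gaps,
optional distal bifurcations, mineral luma drawn from N(28, 5) — centred
on the low/high intensity classes — and Gaussian channel noise.  Ground
truth is recorded from the noise-free masks, so measuring those masks
directly reproduces the recorded morphometrics exactly, and the rendered
images differ from the truth only through noise and thresholding.

`cohort_spec()`/`simulate_cohort()` generate tabular longitudinal cohorts
without rendering: by default 60 fish, four sampled at each time point
from 24–144 hpa every 12 h and then every 24 h to 240 hpa, a saturating
quadratic REG/STU trajectory reaching 1.25 mm at 240 hpa, mineralization
onset at 36 hpa (between the first and second day, when deposits first
become detectable), a P1/P2 breakpoint at `x0 = 0.586` with P2 slope 1.2,
multiplicative measurement noise (CV 0.05) and lognormal inter-specimen
size variation that scales STU strongly and RAY weakly.  The mineral
schedule follows the *control* trajectory in time, so a growth-stunted
treated fin still mineralizes on schedule — which is what makes an
under-regenerated, over-mineralized phenotype expressible.  Treatment
multipliers act on the regeneration trajectory, the mineral fraction and
the staining luma; `ra_like_effects` (0.6, 1.3, 1) and
`warf_like_effects` (1, 1, 0.7) encode the two canonical validation
phenotypes.

What the generator does *not* emulate: curved or ragged amputation
planes, pigmentation and vasculature texture, uneven illumination and
flat-field artefacts, staining-batch variation, fixation shrinkage, and
multi-fish scenes.  Passing tests on synthetic data therefore validate
the geometry, calibration and statistics of the chain — not robustness to
every acquisition artefact of real micrographs, for which the manual
override hooks (outline, widths, threshold) exist.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate on: 50 rendered
fixtures for measurement accuracy (tolerances 2% on areas, 1 px on
lengths); a 60-fin cohort with size CV 0.2 for the correction-factor
ordering; 100 simulated cohorts for breakpoint recovery (median error
well under 0.05); 10^4 null simulations for ANOVA type-I calibration;
100 simulated screens for the phenotype call rates; and 10^4-pixel luma
mixtures for intensity-class recovery (±0.02).  These sizes give stable
Monte-Carlo estimates while keeping a full run to a few minutes on one
CPU.

## Known limitations

* The amputation plane is straight; strongly curved cuts need a manual
  regenerate outline.
* Joint/bifurcation counting assumes the ray axis is within ~45° of the
  image rows (the rendering convention); arbitrary orientations would
  need a rotated brush.
* Luma is a proxy: it orders density/thickness within an acquisition
  stratum but is not densitometry, and classes from different exposure
  times are never comparable — the pipeline refuses to pool them unless
  forced.
* 16-bit inputs are rescaled to 8-bit because all published threshold
  bands are 8-bit values; native 16-bit thresholding is out of scope.
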