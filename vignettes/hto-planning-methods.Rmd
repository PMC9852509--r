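---
title: "Concentric-circle planning for medial open-wedge HTO: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentric-circle planning for medial open-wedge HTO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htoplan)
```

## The geometric model

`htoplan` works entirely in a canonical frontal plane: millimetres,
`+x` medial, `+y` distal, femoral head centre at the origin. Left
limbs are mirrored (`x -> -x`) when a landmark file is loaded, so a
single code path serves both sides; the measures and plans of a limb
and its mirror image are identical by construction, and this is
property-tested. All geometry runs on real-valued coordinates — there
is no pixel-grid snapping, so the only error sources are landmark
placement and floating point.

The planning construction treats the correction as a **rigid rotation
of the distal limb about a lateral hinge `H`**. Because all radii of
concentric circles are equal, the circle about `H` through the ankle
centre `C1` is exactly the locus of possible postoperative ankle
positions; its distal intersection `I` with the target weight-bearing
line is therefore the postoperative ankle, and the correction angle
is `θ = ∠C1·H·I`. The opening gap at the osteotomy site `S` is the
chord of `θ` at radius `|HS|`, `2·|HS|·sin(θ/2)` — an identity the
test suite checks to 1e-9 relative on a thousand random plans. The
same rotation is what `apply_osteotomy()` executes virtually, which
gives the package its central verification: for any noiseless varus
limb, plan → execute → re-measure returns the target WBL ratio to
1e-6 percentage points, because `F`, the target point `O` and `I` are
collinear by construction.

Sagittal-plane geometry (tibial slope), biplanar cut details and
implant templating are out of scope; the model is the frontal plane
that standing whole-leg radiographs capture.

## Parameters and their defaults

All interfaces exchange angles in degrees and lengths in millimetres.

| parameter | default | meaning |
|---|---|---|
| `target_ratio` | 50 % | target WBL crossing, % of plateau width from the medial edge; `"fujisawa"` = 62.5 %, the classical overcorrection target preferred in older or higher-grade arthritic knees |
| `hinge_distal_offset` | 15 mm | hinge depth below the lateral plateau edge |
| `hinge_medial_offset` | 8 mm | hinge distance medial of the lateral cortex |
| `osteotomy_radius` | 40 mm | radius of the circle about the medial plateau edge that marks the osteotomy site on the medial cortex |
| `blade_thickness` | 0.9 mm | saw-blade thickness added to the planned gap for the intraoperative tape |
| `acceptable_halfwidth` | 5 pp | half-width of the acceptable postoperative WBL band |

Two readings of the construction are genuinely open and were decided
as follows:

* **Knee centre.** The mechanical axes need a knee-side endpoint; the
  construction defines only the plateau midpoint. We use that single
  midpoint for both the femoral and the tibial axis, which keeps
  pre/post comparisons consistent and makes a collinear limb measure
  exactly mFTA 0°.
* **Direction of the 8-mm hinge offset.** "Medial to the lateral
  cortex" does not say whether the offset is horizontal or normal to
  the local cortex tangent. We apply it horizontally (parallel to the
  plateau), which matches on-screen calliper use and is exact for the
  near-vertical metaphyseal cortex.
* **WBL ratio on the infinite plateau line.** Crossings medial of the
  medial edge return negative percentages rather than errors; severe
  varus knees genuinely measure below 0 %, so clamping or erroring
  would destroy the preoperative distribution.
* **Branch selection.** Where a circle cuts a line or contour twice
  the caller selects the proximal or distal branch explicitly; the
  planner always takes the distal branch for both `S` and `I`, the
  proximal ones being anatomically meaningless. Boundary ratios
  (45.0, 55.0) classify as acceptable: the under/over definitions are
  strict exceedances of the band.
* **Valgus and neutral limbs.** A medial opening wedge only moves the
  WBL laterally, so `make_plan()` rejects limbs whose WBL is already
  lateral to the target instead of emitting a negative angle; a limb
  exactly on target yields a valid zero-angle plan flagged
  "no correction needed". Gaps above 15 mm are flagged
  `graft_recommended` (structural grafting is conventional for such
  openings); the flag is informational only.

## The synthetic-limb generator

The generator emulates the geometry of a standing whole-leg AP
radiograph with the deformity placed entirely in the proximal tibia
(an MPTA deficit), the indication for HTO: vertical femoral axis
(default 400 mm), horizontal plateau (default width 70 mm), and an
ankle deviated medially by `tibia_length * tan(varus_angle)` at the
default 400-mm tibial depth. Lengths are craniocaudal extents, so a
prescribed varus angle is recovered *exactly* by `measure_mfta()` on
a noiseless limb (`mMPTA = 90° - varus`), which the tests check to
1e-9. The default varus of 6.4° is a typical preoperative deformity
for this indication; admissible deformities span `[0°, 15°)`, the
usual inclusion ceiling for the procedure. Cortices are vertical
polylines inset 2 mm from the plateau edges, with an optional
metaphyseal flare (default off).

Landmark noise models observer digitization error: independent
isotropic Gaussian noise per point landmark, and a single rigid
Gaussian offset per cortex polyline so the contour cannot
self-intersect; the noisy contour is re-anchored at the perturbed
plateau depth so a noisy copy remains anatomically valid and
plannable. The default σ of 1.5 mm is a realistic per-coordinate
digitization error on whole-leg films. What the generator does *not*
emulate: femoral-side deformity, joint-line obliquity or convergence,
soft-tissue laxity, magnification error beyond the linear calibration,
and curved diaphyses. Passing tests therefore demonstrate the
*geometric* correctness and noise behaviour of the pipeline, not
clinical accuracy on real radiographs.

`monte_carlo_accuracy()` runs the full error chain per replicate —
plan on one noisy copy, execute on the truth, measure on a second
noisy copy — with an RNG stream derived from `(seed, replicate)`, so
results are independent of replicate ordering and exactly
reproducible. Replicates whose plan construction fails are counted
and reported, never dropped.

## The reference cohort

No individual radiographs accompany the published 54-knee series the
package's defaults are drawn from, so `demo_cohort()` reconstructs
its *summary structure* deterministically: 43 knees in the acceptable
45–55 % band (mean 49.3 %), 2 under-corrected (40.6 % and 43.0 %,
mean 41.8, sd 1.7 — also reproducing the series' postoperative
minimum of 40.6 %) and 9 over-corrected (mean 58.1 %, sd 1.8), plus
matching pre/post means and sds for WBL ratio, mFTA, mMPTA and wedge
angle. Within-column values are arcsine-spaced quantiles with the
exact target mean and sd; the arcsine shape is used because its
extremes stay within ~1.42 sd of the mean, which is the only way a
set with sd 2.6 about 49.3 fits strictly inside the (45, 55) band
(evenly spaced values would spill out medially). The pairing of pre
and post values across knees is arbitrary, so the cohort's paired t
statistics are illustrative; its classification counts, category
means and column means/sds are exact. This is a synthetic
reconstruction, clearly so named, not recovered patient data.

## Numerical choices

* Circle–line intersection solves the quadratic directly; a negative
  discriminant is a valid empty result. Intersections are returned
  proximal-first (increasing `y`).
* Angles use the `atan2(|cross|, dot)` form, stable for the tiny
  (≈ 3°) angles the planner produces.
* Polylines must be strictly increasing in depth (single-valued
  contours); segment endpoints count as hits within 1e-12 of the
  parameter range.
* `paired_t()` delegates to `stats::t.test(paired = TRUE)` and errors
  on zero-variance differences; the hand formula serves as the test
  oracle.
* `icc()` computes the two-way mean squares explicitly and assembles
  ICC(2,1) (absolute agreement, inter-rater) or ICC(3,1) (consistency,
  intra-rater) — the conventional forms when the study design is
  "two observers, repeated sessions" and no model is stated.
  Agreement categories use the customary cut-points (< 0.40 poor,
  0.40–0.75 fair to good, > 0.75 excellent), boundaries inclusive in
  the middle band. Tables with no between-subject variance are an
  error, since every ICC form is then undefined.

## Problem sizes

The shipped suite exercises: 200 noiseless limbs for the closure
check; 1000 random skeletons for the chord identity; 100 random
configurations against a dense-sampling root-finder oracle; 500 noisy
limbs for mFTA bias; and Monte-Carlo runs of 120–1000 replicates.
These sizes give binomial/mean standard errors comfortably below the
asserted tolerances while keeping the whole suite under a minute on a
single CPU.

## Known limitations

* The planner's hinge and radius defaults assume adult limb
  proportions; for k-scaled anatomy the length parameters must be
  scaled alongside (scale equivariance then holds exactly, and is
  tested).
* The postoperative "wedge angle" of a real series is measured
  radiographically around the plate; in simulation the executed
  rotation is known exactly, so the package reports it directly and
  leaves radiographic wedge-angle measurement unspecified.
* Observer noise is modelled as isotropic and independent across
  landmarks; real digitization error is anisotropic (edges are easier
  to place along the cortex than across it) and correlated between
  neighbouring landmarks.
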