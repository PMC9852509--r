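# htoplan

2D geometry and statistics for preoperative planning of **medial
open-wedge high tibial osteotomy (HTO)** from digitized standing
whole-leg AP radiographs.

Medial-compartment knee osteoarthritis in varus knees is treated by
cutting the proximal tibia above the tubercle and opening a medial
wedge, which swings the weight-bearing line (WBL) — the line from the
femoral head centre to the ankle centre — laterally across the tibial
plateau. Success hinges on hitting a target WBL crossing (typically
50 % of plateau width, or the Fujisawa point at 62.5 %) without under-
or over-correction. `htoplan` implements the concentric-circle
(Miniaci-style) planning construction on digitized landmarks, the
standard frontal-plane alignment measures, a virtual osteotomy that
verifies every plan by geometric closure, and the reporting statistics
of a pre/post cohort.

## The construction

Given the femoral head centre `F`, plateau edges, ankle centre `C1`
and the tibial cortex contours (all in mm after pixel calibration):

1. **Target line** `L1`: from `F` through the target point `O` at
   `target_ratio` % of the plateau width from the medial edge.
2. **Hinge** `H`: 15 mm distal to the lateral plateau edge, 8 mm
   medial to the lateral cortex.
3. **Osteotomy site** `S`: the distal intersection of the circle of
   radius 40 mm about the medial plateau edge `M` with the medial
   cortex.
4. **Correction angle** `θ`: the circle about `H` through `C1` cuts
   `L1` at the ankle image `I`; `θ = ∠C1·H·I`. Rotating the distal
   limb by `θ` about `H` carries the ankle exactly onto the target
   line.
5. **Correction gap**: the chord of `θ` at radius `|HS|`,
   `gap = 2·|HS|·sin(θ/2)`; the intraoperative tape length adds the
   0.9-mm saw-blade thickness.

Alignment measures: the **WBL ratio** (% of plateau width from the
medial edge, signed; severe varus knees measure below 0 %), the
**mFTA** (mechanical femorotibial angle, varus positive) and the
**mMPTA** (medial angle between plateau and tibial mechanical axis).

## Worked example

```r
library(htoplan)
limb <- load_landmarks(system.file("extdata", "worked_limb_synthetic.json",
                                   package = "htoplan"))
measure_all(limb)
#> WBL ratio 35.7%  mFTA varus 2.9°  mMPTA 87.1°

plan <- make_plan(limb)
plan
#> <hto_plan>
#>   hinge H            (-25.00, 415.00) mm
#>   osteotomy site S   (33.00, 439.95) mm
#>   correction angle   2.97 deg
#>   correction gap     3.27 mm
#>   intraoperative gap 4.17 mm (incl. 0.9 mm blade)

wbl_ratio(apply_osteotomy(limb, plan))   # virtual execution closes on target
#> [1] 50
```

The example limb has its ankle deviated 20 mm medially over a 400-mm
tibia (2.9° varus), so the WBL crosses at 35.7 % of the plateau; the
plan opens a 3.27-mm wedge hinged at (−25, 415) and the virtual
osteotomy confirms the postoperative WBL lands exactly on the 50 %
target.

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/htoplan.R", package="htoplan"))')" \
    plan landmarks.json --target-ratio 50 --svg overlay.svg --json report.json
```

Subcommands: `measure`, `plan`, `generate` (synthetic limbs),
`simulate` (Monte-Carlo landmark-noise studies), `cohort`, `icc`.

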