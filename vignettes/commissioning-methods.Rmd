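---
title: "Commissioning a dual-layer MLC model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Commissioning a dual-layer MLC model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmlc)
```

## The problem

Ring-gantry linacs with a stacked-and-staggered dual-layer MLC ship with a
vendor-locked beam model. Commissioning an independent treatment planning
system for such a machine means estimating the handful of parameters that
describe how the MLC shapes fluence — above all the leaf-end behaviour —
from a set of isolating measurements, and then validating the resulting
model with modulated plans. `dualmlc` implements that whole loop at desk
scale: a parametric leaf-end/fluence/dose model, a virtual laboratory that
stands in for the physical machine, the estimation pipeline, and the QA
statistics used to judge the result. Because the "machine" is a hidden
ground-truth parameter set, parameter recovery is an objective test of the
pipeline in a way physical commissioning can never quite be.

## The leaf-end model

Each MLC bank's modeled tip position is an affine-quadratic map of the
nominal position $X_{nom}$ (cm at isocenter, positive to the right in
beam's eye view for both banks):

$$X_{Lt} = X_{nom} - \mathrm{Offset} + \mathrm{Gain}\,X_{nom}
  - \mathrm{Curvature}\,X_{nom}^2$$
$$X_{Rt} = X_{nom} + \mathrm{Offset} + \mathrm{Gain}\,X_{nom}
  + \mathrm{Curvature}\,X_{nom}^2$$

Two derived quantities organize the estimation. For an opposed pair planned
at the same $X_{nom}$, the *dosimetric offset*
$\Delta X_D = (X_{Rt} - X_{Lt})/2 = \mathrm{Offset} +
\mathrm{Curvature}\,X_{nom}^2$ measures how far the dosimetric edge sits
beyond the nominal one, and the *midpoint shift*
$\Delta X_{MP} = (X_{Lt}+X_{Rt})/2 - X_{nom} = \mathrm{Gain}\,X_{nom}$
measures the displacement of the pair's center. Offset and Curvature move
only $\Delta X_D$; Gain moves only $\Delta X_{MP}$. That separation is what
lets the pipeline fix parameters one experiment at a time. The off-axis
term is taken to be the *signed* nominal position itself: that is the only
reading under which the separation above is exact, which is why the package
adopts it. (An absolute-value reading would make the midpoint shift kink at
the axis and leak Offset into it.)

Parameters (units, defaults):

| parameter | unit | default | role |
|---|---|---|---|
| offset | cm | 0 | retracts both tips outward; widens every gap by `2*offset` |
| gain | – | 0 | proportional position error; moves pair midpoints |
| curvature | 1/cm | 0 | quadratic off-axis widening |
| tip_width | cm | 0 | half-attenuation zone inboard of the tip |
| layer_transmission | – | 0.0047 | per-layer transmission of a blocking leaf |
| tng_width | cm | 0.05 | tongue-and-groove half-thickness strips |
| dynamic_min_gap | cm | 0.06 | smallest allowed moving gap |

The machine geometry carries the fixed constants: SAD 100 cm, layer planes
at 38.9 and 47.9 cm from the source (bottom-of-leaf distances; the engine
blurs with the source projected from their midpoint), 28 × 28 cm² maximum
field, 1 cm physical / 0.5 cm effective leaf width (the distal rows sit
half a leaf width off the proximal rows), primary source sigmas 0.075 cm
(X) and 0.090 cm (Y), d_max 1.3 cm, 5 cm/s leaf speed, 12 deg/s gantry
speed, 0.1 MU/deg minimum, 800 MU/min dose rate.

## Fluence and dose

Leaves are infinitely thin attenuators. A blocked region transmits $T$ per
layer; a strip of width `tip_width` on the leaf side of the modeled tip,
and tongue-and-groove strips of width `tng_width` along leaf sides facing
open neighbor rows, transmit $\sqrt T$ — the attenuation exponent of half
a leaf height. Where a tip zone and a T&G strip overlap, the smaller
transmission wins (a choice; the blend is not otherwise constrained).

Rasterization is by exact area-weighted pixel averages of the piecewise
leaf geometry, so sub-grid leaf motion changes the map continuously. One
detail matters more than it looks: the two layers must be multiplied *as
piecewise functions within each half-leaf-width band* and averaged once
(`dual_layer_fluence()`). Multiplying two already-pixelized layer maps
(`combined_fluence()`, kept for map-level work) corrupts coincident layer
edges — the product of two 57%-coverage pixels is 32%, not 57% — which
would shift every shared dosimetric edge inward by a few hundredths of a
centimeter, the very scale the commissioning resolves.

Dynamic deliveries interpolate leaf positions linearly between control
points, with MU-weighted midpoint sub-sampling no coarser than 1 mm of
leaf travel. A uniform sweep is therefore the box average of the static
gap map over the travel window; the sweep generator exploits that identity
(one static map instead of hundreds) and the tests verify it against the
literal control-point accumulation.

The dose engine is deliberately simple, because every quantity the
pipeline fits is relative: dose = depth-dose factor × source-blurred,
magnified fluence. The depth-dose is linear to d_max and exponential
beyond, pinned to 0.63 at 10 cm; an optional mild output-factor curve on
the equivalent square (`2ab/(a+b)`) is available but cancels out of all
fits. Field edges of the FFF beam are located at the penumbra inflection:
the extremum of the centered first difference, refined by quadratic
interpolation of the three points around it. Profiles whose derivative is
constant (ramps) or has tied, non-adjacent extrema are rejected as
ambiguous rather than silently resolved.

## The virtual laboratory

`ground_truth()` hides a true parameter set behind the session generators;
every session is a pure function of (truth, arguments, seed), so identical
seeds reproduce readings bit for bit. The default truth mirrors a
commissioned machine of this class: offset +0.007 cm, gain 0, curvature 0,
flat tip, 0.47% per-layer transmission, 0.05 cm T&G width. Detector models
are Gaussian kernels (Edge diode 0.08 cm, CC13 0.6 cm) and a 2.3 cm line
average along Y for the Farmer chamber; noise is multiplicative lognormal,
0.5% by default — typical chamber repeatability — one independent draw per
record.

The sessions:

* **Sweeping gaps** (`gen_sweep_session`): 2–20 mm gaps crossing a ±5 cm
  window around each chamber position (X = 0, ±3, 5, 10, 12, 13 cm;
  10 cm depth, 90 cm SSD), plus a closed-field leakage record per position
  and one static 10 × 10 cm² cross-calibration record. The window is
  clamped into the ±14 cm leaf travel independently of the gap; at 12–13
  cm the large gaps consequently cannot pass the chamber completely, and
  the per-position DLG is visibly distorted there — the same thing a
  physical chamber at the travel limit sees. The pipeline reports those
  values rather than hiding them and bases its initial offset on the RMS
  method instead.
* **Abutting fields** (`gen_abutting_session`): two 2 × 4 cm² fields
  scanned across their junction with the Edge diode, each normalized to
  its own center, summed, three runs averaged. A +0.01 cm offset produces
  an overlap peak, −0.01 cm a gap dip — the most sensitive static probe of
  the leaf end.
* **Complementary bars** (`gen_bar_session`): alternate open/blocked
  leaves of one layer and the inverse pattern, scanned along Y; the sum is
  flat except for T&G dips at the leaf borders (1 cm period per layer; the
  staggered distal layer dips half a leaf width away from the proximal
  ones).
* **Strip edges** (`gen_edge_session`): 1 cm strips at off-axis centers;
  both inflection edges per strip yield measured $\Delta X_{MP}$ and
  $\Delta X_D$ versus position.
* **Modulated plans** (`gen_plan_suite`): seeded random VMAT,
  sliding-window VMAT (all leaves sweeping one direction) and 9-field
  sliding-window IMRT plans within the kinematic limits, each with a
  high-dose chamber at the isocenter and a second chamber at a low-
  gradient point whose noise-free dose ratio lies in 0.4–0.8, plus
  581–1009 diode samples of a helical cylindrical array at 10.5 cm radius
  over the irradiated band. Gantry angles enter kinematic validation only;
  dose is computed in the fixed measurement plane, which is faithful for
  the homogeneous phantoms this workflow uses.

What the generator does *not* emulate: beam-energy/PDD structure beyond
the simple depth factor, off-axis spectral softening, interleaf leakage
beyond the T&G strips, detector field-size corrections, portal images and
trajectory logs. Passing recovery tests therefore demonstrates that the
estimation logic inverts the forward model it assumes — not that the
forward model captures every property of a physical beam.

## The estimation pipeline

`run_commissioning()` fixes the easily isolated parameters first and hones
the rest:

1. **Transmission** from closed-field records (stacked reading ≈
   $T^2 \times$ depth factor); the standard 0.47% is kept when confirmed
   within 20%.
2. **T&G width** by RMS agreement between measured and calculated bar
   sums over a 0–0.1 cm grid.
3. **Gain** by OLS of measured midpoint shifts on $X_{nom}$ with a
   two-sided slope t-test: the slope is adopted only at p < 0.05,
   otherwise gain = 0. At the 0.005 cm positional repeatability of the
   edge measurements this test has its nominal ~5% false-trigger rate.
4. **Initial offset** from the sweeping gaps, two ways: the classic DLG
   (negative x-intercept of reading-minus-leakage vs gap; DLG/2 is the
   flat-tip offset equivalent) and the RMS method (cross-calibrated
   absolute doses, leakage not subtracted, model recomputed per candidate
   offset, parabolic refinement of the three best candidates). The RMS
   value seeds the next step. On a flat-tip truth the two agree; a tip
   zone inflates the DLG by $2\,t_w(T - T^2)$ of fluence integral while
   the RMS method stays put — with the stacked layers that disagreement
   is a few thousandths of a centimeter, consistent with how weakly this
   class of MLC constrains the tip parameter.
5. **Final offset** from the modulated-plan scan: mean local percent
   difference (calculated − measured)/measured over all chamber points,
   per candidate offset; the x-intercept of the straight-line fit is the
   answer. This value overrides the static/dynamic initializers.
6. **Curvature** stays 0 unless the quadratic term of $\Delta X_D$ versus
   off-axis position exceeds 3× its standard error — a concrete stand-in
   for the judgment call that a strong quadratic would inject spurious
   off-axis offsets.

All fits are ordinary least squares with standard parametric uncertainty;
every `fit_result` records its estimate, SE, diagnostics, the decision and
the rule that produced it.

## Evaluation

`gamma_index()` implements the gamma test with global or local dose
normalization: the reference is bilinearly resampled at DTA/10 steps
(never coarser than 0.02 cm, so loosening the DTA cannot degrade the
search grid), the search radius is 3×DTA, and points receiving less than
the threshold (default 10%) of the reference maximum are excluded. The
passing count uses γ ≤ 1 with a 1e-9 guard against floating-point
boundary artifacts. Against an exhaustive brute-force search the
implementation agrees to better than 1e-6 on random grids — a standing
test, not a one-off check. Local-normalization passing rates are never
above global ones, and loosening either tolerance never lowers a passing
rate.

`confidence_limit()` gives the TG-119-style 95% limits: mean ± 1.96·SD for
error distributions, mean − 1.96·SD (upper end 100) for passing rates.
Both raw values and the reporting convention (rounded toward zero at one
decimal, so mean 0.0%, SD 1.1% reads ±2.1%) are returned, because the
truncating convention is what commissioning summaries conventionally
print.

## Numerical choices and degenerate inputs

* Grids are pixel-centered; default spacing 0.1 cm, 0.05 cm for
  diode-scanned sessions. Tip/T&G structure below the pixel size is
  represented by area weighting; a note is recorded when spacing exceeds
  0.1 cm with strips present.
* Sweep sub-sampling at ≤1 mm of travel makes the accumulated sweep
  fluence exact to ~1e-9 relative (midpoint-rule error is suppressed
  exponentially by the source blur).
* Closed pairs with crossed modeled tips (negative offset) are treated as
  fully blocked; their facing tip zones are not modeled.
* `field_edge_inflection()` raises errors, never guesses: no extremum,
  window-boundary extrema and tied extrema are all explicit failures.
* Replicate studies of the final offset scan re-draw only the measured
  chamber doses against cached calculated doses: the calculated values do
  not depend on the noise, so re-simulating them per replicate would only
  burn time. The noise-robustness statement ("offset within ±0.003 cm in
  at least 95% of replicates at 0.5% noise") is therefore a property of
  the honing step, evaluated at 100 replicates.
* Problem sizes in the shipped tests: 2 plans per technique (12 chamber
  points), seven sweep gaps at seven positions, 10 edge strips, 20 × 20
  gamma grids. These sizes keep the full recovery demonstrably sharp
  (noise-free offset error < 0.002 cm) at desk scale.

## Known limitations

* The dose engine is a relative-dosimetry kernel model; absolute output,
  heterogeneity and spectral effects are out of scope.
* One parameter set serves both layers and all leaf rows (uniform-leaf
  machine); per-row offsets are not modeled.
* Off-axis DLG at 12–13 cm is distorted by the travel limit (see above);
  this is reported, not corrected.
* The cylindrical array is compared at detector coordinates against the
  calculated plane; measurement-guided interpolation of the reference is
  not implemented.
* Real DICOM RT Plan I/O is a documented extension point: plans serialize
  to the package's JSON schema, and a converter would slot in at
  `read_plan_json()`/`write_plan_json()` without touching the engine.
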