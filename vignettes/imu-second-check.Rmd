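---
title: "Independent monitor-unit second checks for MR-Linac adaptive plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Independent monitor-unit second checks for MR-Linac adaptive plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imucheck)
```

## The problem

Online adaptive radiotherapy on a high-field MR-Linac creates a new plan at
every fraction, while the patient is on the table. Each of those plans needs
an independent verification of its monitor units (MU) and dose before
delivery, and it needs it within minutes. The practical route is a second
dose calculation in a conventional treatment planning system (TPS) — but two
obstacles stand in the way:

1. **Dialect.** The MR-Linac's planning system describes beams in its own
   DICOM conventions: a source-to-axis distance (SAD) of 143.5 cm, a fixed
   collimator angle of 0°, MLC leaf positions stored under the tag `MLCY`,
   and a fixed 22 cm jaw opening in the superior–inferior direction with no
   Y jaw entries in the file at all. A conventional TPS expects a 100 cm
   SAD, `MLCX`, and explicit X jaws.
2. **Physics.** The 1.5 T magnetic field bends secondary-electron
   trajectories, which a conventional dose algorithm does not model. The net
   effect on a transverse profile is, to good approximation, a rigid lateral
   shift of about 2 mm. The posterior radiofrequency (RF) receive coil under
   the patient additionally attenuates posterior beams by about 2.2%, and is
   invisible to the second system because it is not part of the exported
   structures.

`imucheck` implements the whole second-check chain as a file-based pipeline:
plan dialect conversion, per-beam extraction of a beam's-eye-view (BEV)
comparison plane from two 3D dose grids, the lateral-shift and coil
corrections, and a 2D gamma analysis restricted to the beam's complete
irradiated area outline (CIAO). Because the two commercial dose engines
cannot ship with a package, a deterministic toy dose engine generates
matched and deliberately mismatched synthetic cases so every stage — and the
pipeline end to end — is testable offline.

## Plan conversion

Three rules map a Monaco-dialect plan to the conventional dialect, applied
per beam by `convert_plan()`:

1. **Rescale and retain the source distance.** All collimation (leaf
   positions, leaf boundaries, jaw openings) is defined at the 143.5 cm
   plane and is rescaled to the 100 cm plane by similar triangles — a factor
   of $100/143.5$, i.e. division by 1.435 — so the projected aperture in the
   original BEV is unchanged. The beam switches from SAD technique to
   extended-SSD technique: its nominal SAD becomes 100 cm but the geometric
   source-to-isocenter distance stays 143.5 cm, so the source position in
   the patient frame is untouched. The fixed ±11 cm physical limit projects
   to ±7.67 cm.
2. **Relabel the energy** (7MV-FFF → 6MV-FFF), a nominal bookkeeping step.
3. **Swap the in-plane axes.** The MLC tag changes `MLCY` → `MLCX` and the
   collimator angle 0° → 90°; the rotation exactly undoes the relabeling, so
   the aperture in the patient frame is identical (the suite rasterizes both
   sides to verify this to 10⁻⁶ cm). New X jaws are derived from the
   open-leaf envelope plus a 5 mm margin, clipped to ±7.67 cm; a fixed
   ±7.67 cm mode is available and differs negligibly inside the CIAO (a
   gamma comparison of the two modes on the toy engine scores ≳99.5%).

Decisions worth recording, where the rules leave room:

* *Open pairs only.* The jaw envelope ignores leaf pairs whose tip gap is at
  or below 0.05 cm at the 100 cm plane; parked closed pairs would otherwise
  force the jaws wide open. The same closure tolerance defines the CIAO.
* *Margin plane.* The 5 mm jaw margin is interpreted at the 100 cm plane,
  since the rule operates on already-rescaled positions.
* *Static jaws per beam.* The target dialect expects one jaw setting per
  beam, so the derived jaws are the envelope over all control points.
* *Write precision.* Positions are written to DICOM at 0.01 cm, matching the
  printed precision of the projected jaw constant. In-memory conversion is
  exact; quantization happens only at the file boundary.

MU are never modified: the second system recalculates dose with fixed MU.

## The comparison plane and its corrections

For each beam the comparison happens on the BEV-parallel plane through the
plan reference point (usually the isocenter), perpendicular to the beam
axis. The plane frame is chosen so that its second in-plane axis,
`axis_v`, is perpendicular to both the beam axis and the B-field axis
(patient superior–inferior) — this is the direction along which the
magnetic-field shift acts, and for coplanar beams it coincides with the
leaf-travel direction. `axis_u` completes the right-handed frame and is the
leaf-stacking direction. The default lattice is 1 mm, covering the CIAO
bounding box plus a 2 cm margin — finer than either distance-to-agreement
criterion.

Both 3D grids are resampled on this lattice by trilinear interpolation
(`sample_plane()`). Samples outside a grid are marked invalid and excluded
from the region of interest rather than zero-filled; zero-fill would
fabricate gamma failures at plane edges.

Two corrections are applied before scoring:

* **Lateral shift.** The reference (B-field-aware) plane is translated by
  2 mm along `axis_v` (`shift_plane()`). The shift exists only inside the
  comparison — stored doses are never modified. The sign convention needs
  care: the emulated Lorentz deflection displaces the delivered pattern
  towards `+v`, so the *corrective* shift applied to the reference moves it
  by `shift_sign × bfield_shift_mm` with `shift_sign = -1` by default,
  overlaying it on the no-B-field calculation. Both magnitude and sign are
  configuration values (`correction_config()`), because the right sign
  depends on how the second system's beam model was commissioned.
* **Posterior coil.** Beams with gantry angles in the closed interval
  [100°, 260°] (configurable; the boundary convention is closed on both
  ends) traverse the posterior RF coil, so the evaluated dose is multiplied
  by 0.978 — the 2.2% attenuation the second calculation cannot see. The
  0.4% anterior coil is ignored. The correction is a single scalar on the
  whole beam dose; it commutes with plane extraction and with the shift,
  which the suite checks. The couch, by contrast, is *not* corrected here:
  its contours travel with the structure set and both calculations model
  it, which the toy engine mirrors by placing its couch slab in both sides.

## Gamma analysis on the CIAO

The score is the standard gamma index with global normalization: for each
reference pixel $r$,

$$\gamma(r) = \min_e \sqrt{ \frac{|e - r|^2}{\delta_{\mathrm{DTA}}^2} +
 \frac{(D_e(e) - D_r(r))^2}{(p \cdot D_{\max}/100)^2} }$$

with $D_{\max}$ the reference maximum over the region of interest, $p$ the
dose criterion in percent, and the minimum taken over evaluated positions
$e$. Two criteria sets are configured by default — 3%/3 mm (primary,
verdict-driving) and 3%/2 mm (informational) — with a per-beam passing
threshold of 95%.

The region of interest is the CIAO: the union over control points of the
open MLC aperture intersected with the jaws, projected to the analysis
plane by the divergence factor and rasterized with a pixel-center test
(centers exactly on an edge count inside, for determinism). No low-dose
cutoff is applied inside the CIAO, though an optional exclusion contour can
remove, say, an air cavity (`subtract_roi()`).

Numerical choices:

* The evaluated dose is bilinearly interpolated on a sub-lattice of the
  plane spacing with target step $\delta_{\mathrm{DTA}}/10$, quantized to an
  integer divisor of the spacing so candidate offsets align exactly with
  lattice nodes.
* The search is restricted to a radius of $3\,\delta_{\mathrm{DTA}}$ and
  gamma is capped at the radius bound (3.0): beyond it the spatial term
  alone exceeds any plausible minimum, and a capped value already means
  "far beyond failing".
* Candidates are visited in shells of increasing distance, and a pixel is
  finalized as soon as the spatial term alone exceeds its current best
  value. This is an exact optimization, not an approximation — the result
  equals the exhaustive minimum over the same candidate set, which the
  suite verifies against `gamma_brute_force()` (plain nested loops over the
  full sub-lattice, no radius restriction, refusing planes over 64×64) to
  10⁻⁶ on random smooth plane pairs.
* The pass condition is $\gamma \le 1 + 10^{-9}$, so exact-boundary cases
  (an edge translated by exactly the DTA) pass deterministically.
* Reference pixels with less than half of their search neighborhood valid
  on the evaluated side are dropped from the ROI with a warning.
* `gamma_brute_force()` takes a `refine` argument that densifies its
  sub-lattice. Refinement can only lower gamma; where the dose term
  dominates, the discrete minimum moves at the dose-gradient scale
  (~0.1 for these fields), which is why oracle equivalence is stated on a
  shared lattice and lattice-refinement stability is a separate, looser
  check.

Useful invariants, all in the suite: $\gamma(D, D) = 0$; gamma is pointwise
non-increasing as either criterion loosens (hence pass rates order as
3%/3 mm ≥ 3%/2 mm); gamma is invariant under a common rescaling of both
planes (global %-of-max normalization); and a smooth edge translated by
exactly the DTA scores $\gamma \approx 1$ and passes.

## The toy dose engine and what the synthetic studies mean

The engine (`toy_dose_engine()`) computes, per beam,

$$D(p) = \mathrm{MU} \times k \times
  \left(\tfrac{\mathrm{SAD}}{d(p)}\right)^2 e^{-\mu\, z(p)}
  \, F(p) \, \mathrm{OAR}(p) \times T_{\mathrm{slabs}}$$

an inverse-square divergent beam with effective attenuation
$\mu = 0.05\ \mathrm{cm}^{-1}$, a fluence $F$ built from the
control-point-weighted aperture gates convolved with a 3 mm Gaussian
penumbra, a linear FFF off-axis falloff of 1.5%/cm, and Beer–Lambert-style
slab transmissions for the couch (0.97) and posterior coil (0.978). The
calibration constant $k$ fixes 1 cGy/MU on the central axis at 5 cm depth
and 138.5 cm SSD. The B-field emulation displaces the fluence pattern 2 mm
towards `+v`. These engine parameters are fixture conventions chosen at
realistic scales, not claims about any machine.

A synthetic case pairs a "reference" calculation (B-field emulation on,
coil present — the role of the B-field-aware primary TPS) with an
"evaluated" one (neither — the role of the conventional second engine),
over a 24 cm water-equivalent cube. Both sides share the engine, so a
matched case passes gamma near 100% *by construction*, and the pipeline's
corrections are the only discriminators. That is the point: the synthetic
studies validate the pipeline's bookkeeping and corrections, not any dose
algorithm. What they cannot show: electron-return-effect hot spots at
tissue–air interfaces (explicitly beyond the rigid-shift approximation),
heterogeneity, MLC transmission/leakage and the dosimetric leaf gap,
scatter-kernel differences between real algorithms — all reasons real
clinical pass rates sit near 98% rather than 100%.

Study conditions, chosen once:

* **Sensitivity suite** (`run_sensitivity_suite()`): 94 beams, 18
  mismatched, mirroring a commissioning design at desk scale. Mismatch
  magnitudes are MU errors of 5–10% and leaf-bank shifts of 4–6 mm — at or
  above the 5%/3 mm detectability floor. A leaf-bank translation equal to
  the 3 mm DTA is mathematically undetectable by a 3 mm gamma criterion
  (the spatial search absorbs it exactly), so the shifts used start at
  4 mm. Engine noise is off, its default. At the 95% threshold the suite
  separates perfectly; the verdict-vs-truth contingency coefficient then
  attains its 2×2 maximum $\sqrt{1/2} \approx 0.707$.
* **Shift-efficacy study**: 10 beams with 1% engine noise, scored at
  3%/2 mm. Both choices are forced by the metric, not tuned: a rigid 2 mm
  offset between otherwise identical planes can never fail a 3 mm DTA
  (gamma tops out at 2/3), and with zero noise the unshifted comparison
  still passes everywhere. The 1% noise supplies the error floor every real
  engine pair has, and at 3%/2 mm the 2 mm residual sits exactly at the
  DTA limit; there the corrective shift improves every beam, by ~7–15
  percentage points.
* **Problem sizes**: engine grids at 4 mm over the 24 cm phantom, analysis
  planes at 1 mm. A full 15-beam case (generation, DICOM round trip,
  conversion, planes, CIAO, gamma at both criteria, report) completes in
  well under a minute, comfortably inside the few-minute turnaround online
  adaptation demands.

## Degenerate inputs and edge behavior

* A fully closed control point contributes nothing to the CIAO; an
  all-closed beam has no ROI and is an error. Jaw derivation for a fully
  closed segment collapses to the closed-leaf position ± margin, with a
  warning.
* Converting an Eclipse-dialect plan raises — double rescaling is
  impossible by construction.
* Dialect detection trusts the MLC tag name and requires the SAD to
  confirm it; disagreement, or any unknown combination, is an error rather
  than a guess.
* Shifting a plane by more than its extent is an error; integer-lattice
  shifts are exact rolls (source indices are snapped at 10⁻⁹ to keep them
  so).
* `validate_plan()` never raises; it reports each violated invariant with
  beam and control-point indices, and both writers refuse plans whose
  dialect triple is inconsistent.

## DICOM handling

No R DICOM package was available to build on, so the package carries a
minimal Part-10 codec (explicit VR little endian, nested sequences) that
covers the RT Plan and RT Dose subset it needs. Dose grids are stored as
32-bit integers with a `DoseGridScaling` chosen so quantization error stays
below `5e-10` of the grid maximum. Files carry content-derived UIDs and no
timestamps, so identical inputs produce byte-identical files — which is
what makes the generators' determinism testable. The suite cross-reads
generated files with an independent DICOM implementation (pydicom) to guard
against a self-consistent but malformed encoding. The beam technique
(SAD vs extended SSD) and the retained physical source distance ride in the
beam description field, as the plan attribute set has no standard slot for
them.

## Known limitations

* 2D gamma only; a 3D extension is a natural next step but changes the
  runtime envelope.
* The lateral-shift approximation is depth-independent and rigid; it does
  not attempt the electron return effect at interfaces.
* The posterior-coil correction is a single scalar per beam, applied
  uniformly, and the posterior gantry interval is a configuration choice —
  the physical transition is gradual.
* Exclusion contours are 2D polygons in the plane frame; projecting a 3D
  structure onto the plane is the caller's job.
* The toy engine is a fixture: no transport, no heterogeneity beyond
  slabs, no leaf transmission. Conclusions from synthetic studies are about
  the pipeline, not about dose algorithms.
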