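---
title: "Cohort-averaged AAA anatomy models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-averaged AAA anatomy models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselphantom)
library(dplyr)
```

## The problem

Vascular flow phantoms for ultrasound, CT and MRI studies come in three
flavors: simplified tubes, patient-specific replicas, and generalized
(averaged) anatomies. Averaged models built from a handful of scalar
landmarks (mean diameter, mean angulation) discard the curvature and
tortuosity that shape the flow. `vesselphantom` implements an averaging
approach that works on the full geometry instead: every patient contributes a
center lumen line (CLL) per vessel segment and a per-point lumen diameter,
and the cohort average is taken index-wise after all centerlines are
normalized to a common number of points. The result preserves realistic
angulation and curvature while representing a cohort, here an abdominal
aortic aneurysm (AAA) population with its aortoiliac branches, and can be
turned into a watertight, thin-walled, 3D-printable surface. The package
also implements the mathematics needed to characterize a printed phantom
acoustically (two-thickness attenuation, substitution-method speed of sound)
and to compare volumetric flow extracted from planar velocity measurements
against a flow sensor.

## The averaging model

Each patient supplies a triangulated lumen surface (STL) and labeled CLLs
(`aorta`, `common_iliac_L/R`, `external_iliac_L/R`, `internal_iliac_L/R`,
`renal_L/R`). The pipeline is:

1. **Resampling.** Every CLL is resampled to a fixed per-segment point count
   at equal arc length (defaults: 200 aorta, 100 common iliacs, 150 external
   iliacs, 75 internal iliacs and renals — set by typical segment lengths).
   This normalizes length differences so that point *k* of one patient
   corresponds anatomically to point *k* of another. The resampler iterates
   the equal-arc-length placement to its fixed point, which makes it exactly
   idempotent (a property the test-suite checks at 1e-9 mm) and makes
   `arc_step * (n - 1)` exactly the resampled polyline length. Interpolation
   is chordal/linear rather than spline: the exported CLLs are already
   smoothed, and linear interpolation keeps the arc-length parameterization
   monotone and reproducible.
2. **Cross-sections.** At every resampled point a plane perpendicular to the
   local tangent (central differences) is sampled from the patient's
   voxelized lumen by trilinear interpolation at 0.5 occupancy threshold.
   Connected components are labeled with 8-connectivity; the component at
   (or within 3 mm of) the plane center is the lumen. The lumen area gives
   the circular-equivalent diameter `2 sqrt(A / pi)`.
3. **Exclusions.** No meaningful diameter exists where the plane runs
   through a bifurcation. A section is dropped (flagged invalid, never
   averaged) when (a) no component lies within 3 mm of the center, (b) the
   lumen component touches the sampling-window border, (c) the plane sits on
   an end face of the truncated lumen (detected by empty occupancy one voxel
   fore or aft of the center), or (d) another segment's centerline crosses
   the plane inside the lumen component — the signature of a merged
   cross-section near a bifurcation. The pipeline logs per-segment exclusion
   counts.
4. **Registration and averaging.** All patients are translated so their
   aortic bifurcation (the distal endpoint of the aorta CLL) coincides;
   "rigid alignment" is read as translation-only because no rotation
   criterion is available from landmarks alone, and an optional rotation
   stage was deliberately left out. Coordinates (per axis) and diameters are
   then averaged index-wise over the patients valid at that index, with the
   contributing count recorded. Spread is the sample standard deviation
   (n-1; the cohort is a sample of the AAA population), and the single
   "3D" coordinate SD reported per point is the Euclidean norm
   `sqrt(sd_x^2 + sd_y^2 + sd_z^2)` — one documented convention among
   several possible ones.

## Surface reconstruction

The averaged anatomy is turned back into a surface by placing a ring of the
average diameter at every valid mean CLL point, perpendicular to the local
tangent. Ring frames are propagated with rotation-minimizing
(double-reflection) transport so rings do not twist against each other in
tortuous segments; 32 points per ring keep the chordal radius error below
0.5 percent. Segments can be lofted individually into open tubes
(`loft_segment()`), but the full model is assembled implicitly: each segment
becomes a capsule-chain signed-distance field (distance to the polyline
minus the linearly interpolated radius — exact for cylinders, with an error
second order in the per-step radius change at the ~0.5 mm ring spacing
used), the fields are united with a polynomial smooth-minimum, and the zero
level set is extracted by marching tetrahedra on a regular grid. The blend
radius of the smooth union (default 3 mm) plays the role of the manual
fillet a CAD operator would apply at the bifurcations; at 0 it degenerates
exactly to the sharp plain union.

Because cross-sections are excluded inside bifurcations, the averaged
segments do not quite touch. Child chains are therefore extended to their
parent — common iliacs to the aorta's distal ring, external/internal iliacs
to their common iliac, and renals to the nearest aorta centerline point — at
their most proximal radius, which is the same rule the renal connection
needs (no diameters exist over the covered CLL stretch, so the most proximal
measured diameter is carried across).

Inlets and outlets are cut flat at the terminal ring planes and capped, so
the default output is closed and voxelizes directly for Dice comparisons;
`open_ends = TRUE` removes the caps afterwards for printing. Marching
tetrahedra was chosen over table-driven marching cubes: it needs no
4096-entry case tables, handles every sign configuration with four
runtime-orientable cases, and produces watertight surfaces; its only cost is
a higher triangle count. Isosurfaces of *binary* volumes are extracted after
a narrow separable tent filter softens the 0/1 field (two passes, support
one voxel per side) — this removes the voxel staircase (which would inflate
surface areas by ~25 percent) without moving the 0.5 level away from the
voxel boundary; the raw field is kept automatically for features so small
the filter would erase them.

Global smoothing maps the familiar "smoothing factor" in [0, 1] to Taubin's
two-step lambda/mu scheme (`lambda = 0.6 * factor`,
`mu = -lambda - 0.01`, 10 iterations). This is a convention, not a
reproduction of any proprietary smoother; Taubin was picked because it does
not shrink the model (volume change stays below 2 percent in the tests).
The thin wall (default 1.5 mm, in line with reported human AAA wall
thickness) displaces vertices along area-weighted outward vertex normals;
inner and outer surfaces are stitched at open boundary loops, and a
self-intersection check reports vertices that fold closer than 80 percent of
the wall thickness.

## Quality assessment

Model fidelity is quantified exactly as a phantom study would:

* **Sorensen-Dice similarity** `SDSC(X, Y) = 2|X n Y| / (|X| + |Y|)` on
  binary volumes resampled to a common grid (the "elements" are voxels, so
  the value depends on the chosen resolution — 0.5 mm by default).
  Junction neighborhoods can be masked out (`mask_spheres()`) since the
  bifurcation surface is interpolated rather than measured.
* **Closest-point distance maps**, one-directional from every generated-mesh
  vertex to the reference surface (point-to-triangle via an AABB tree),
  stored as per-vertex scalars for color-coded PLY export. A symmetric
  Hausdorff value is available by running the map in both directions.
* **Landmark translation registration** as the mean of matched landmark
  differences (the least-squares optimal translation).
* **Axisymmetric flow integration** `Q = int_0^R v(r) 2 pi r dr`
  (trapezoidal), with `fold_radial_profile()` to collapse a planar
  diametral velocity profile about the centerline first. Velocities in cm/s
  with radii in mm integrate to ml/s exactly (factor 0.01).

## Acoustic characterization

Through-transmission characterization of a printable resin:

* **Water reference.** The speed of sound in pure water follows the
  published fifth-order polynomial in temperature (valid 0-95 degC);
  at 21.8 degC it evaluates to 1488 m/s.
* **Attenuation** from the amplitude ratio between a thin (1 mm) and thick
  (2 mm) sample, `alpha(f) = 20 log10(A_thin/A_thick) / (d_thick - d_thin)`
  dB/mm, which cancels the front/back interface losses common to both. The
  amplitude metric is the magnitude of the discrete Fourier component at the
  transmit frequency over a steady-state window (cycles 5-25 of the
  30-cycle burst), robust to transient edges; a peak-to-peak metric is
  available as an alternative since the field uses both.
* **Speed of sound** from the arrival-time shift against the water path:
  `c = d / (d/c_w - dt)` with `dt` found at the cross-correlation peak and
  refined by parabolic sub-sample interpolation — at a 4 ns sample interval
  one whole sample is worth ~7 m/s through a 2 mm sample, so sub-sample
  refinement is not optional. The sign convention is advance-positive:
  positive `dt` means the sample waveform arrives earlier than the
  reference, hence `c > c_w`.
* **Uncertainty** propagated to first order through the SoS formula with
  analytic partials (`dc/ddt = c^2/d`, `dc/dc_w = c^2/c_w^2`,
  `dc/dd = -dt c^2/d^2`), cross-checked against Monte Carlo in the tests.
  The exact formulas used by any specific lab workbook may differ; this is
  the package's documented choice.
* **Spectral smoothing** with a Gaussian-weighted moving average (window 16
  data points = 0.32 MHz at the 0.02 MHz sweep step, sigma = window/4,
  edge-aware renormalization), and an ordinary least-squares line through
  the 3-7 MHz band for slope (dB/mm/MHz) and extrapolation to an imaging
  center frequency — the band below where thick-sample signal-to-noise
  degrades.

## The synthetic cohort: what it emulates and what it does not

No patient CTAs ship with the package, so every stage is validated against
a synthetic generator with known ground truth:

* `synth_vessel_tree()` builds an analytic aortoiliac tree — an aorta with
  sinusoidal in-plane tortuosity and a Gaussian diameter bulge for the
  aneurysm sac, two common iliacs leaving the bifurcation at symmetric
  angles, optional renals — and reconstructs its watertight surface through
  the package's own implicit-union machinery. Defaults are sized like an
  EVAR-candidate anatomy: 120 mm aorta, 20 mm base flow lumen, bulge
  peaking at 35 mm, 12 mm iliacs, 6 mm renals.
* `synth_cohort()` jitters patient size parameters uniformly (5 percent by
  default) and adds smooth zero-mean Gaussian noise to centerline control
  points and diameters. Noise lives at 5 control points per segment
  (roughly 30 mm apart) and is interpolated between them: inter-patient
  anatomical variation is a segment-scale phenomenon, and pointwise noise
  at the resampling resolution would be tortuosity, not anatomy.
  `coord_sigma_mm` is the SD of the *total* 3D control-point displacement
  (isotropic, sigma/sqrt(3) per axis). Because all noise is zero-mean, the
  cohort ground-truth mean is the base anatomy, and the averaging pipeline
  must recover it at the central-limit rate — the recovery tests and the
  acceptance checks run under exactly these conditions (n = 30, 2 mm
  coordinate noise, 1 mm diameter noise, no size jitter, common frame).
* `synth_pulse_pair()` produces Hann-windowed tone bursts with an exactly
  imposed fractional-sample delay (evaluated analytically at shifted time)
  and amplitude ratio, so the SoS and attenuation estimators can be tested
  by forward-model inversion.

The generator is deliberately idealized: the aneurysm is a smooth Gaussian
bulge, not a lobulated sac; cross-sections are circular, so the known
limitation of circular-equivalent averaging (sac cross-sections in patients
are elliptic or irregular, which is where the largest model deviations
occur) is *not* exercised; there is no imaging physics, no segmentation
noise, no thrombus. Passing tests therefore demonstrate the correctness of
the algorithms under their stated assumptions, not the clinical accuracy of
any particular phantom.

## Numerical choices and degenerate inputs

* Voxel membership is the voxel-center ray-parity test; a sub-voxel jitter
  (~1e-7 voxel) on the ray origin resolves ties on grid-aligned geometry,
  so an axis-aligned 10 mm box at 1 mm spacing voxelizes to exactly 1000
  voxels. Unpaired crossings (numerically grazed creases) are dropped
  conservatively.
* Default grid spacing is 0.5 mm — half a typical abdominal CTA pixel
  (0.7-0.8 mm), fine enough to resolve lumen boundaries; the binary-volume
  resolution used by any given study is a config choice, and Dice values
  depend on it.
* Problem sizes in the tests and acceptance runs (0.7-0.8 mm grids, 40-200
  points per segment, single-patient end-to-end checks) were chosen so the
  full suite exercises every stage of the pipeline at desk scale; the
  algorithms are resolution-independent and the defaults above apply to
  real cohorts.
* Zero-area faces are dropped at mesh construction (only exactly zero:
  sliver triangles from isosurfacing must survive or pinholes open).
  Meshes that fail the watertightness test get small boundary loops (up to
  25 edges) fan-filled before voxelization; larger holes raise an error
  that reports the open-edge count.
* The lumen-selection tie-break in cross-sections (component containing the
  center, else nearest within 3 mm), the deterministic in-plane axis rule
  (projection of global +x, fallback +y), and the advance-positive delay
  sign are all fixed conventions so repeated runs are bit-identical.
* Tiny satellite components (< 2 percent of faces) of the implicit-union
  surface are extraction artifacts at grid tangencies and are removed; a
  *substantial* second component aborts with the junction gap, since it
  means the blend radius cannot reach across a gap in the anatomy.

## Limitations

* Translation-only registration; cohorts whose anatomies differ by large
  rotations about the bifurcation will average wider than they should.
* Circular-equivalent diameters flatten non-circular sacs; the averaged sac
  is rounder than a patient sac.
* The bifurcation surface is a modeling construct (anchored chains +
  smooth union), not a measurement; Dice comparisons should mask junction
  neighborhoods when judging the measured part of the model.
* The acoustic module assumes plane-wave through-transmission with
  negligible diffraction; no diffraction correction is applied.
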