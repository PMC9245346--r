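---
title: "Modeling TTFields dose enhancement by skull-remodeling burr holes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TTFields dose enhancement by skull-remodeling burr holes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tumor treating fields (TTFields) are ~200 kHz alternating electric fields
delivered to glioblastoma patients through transducer arrays glued to the
scalp. The therapeutic "dose" at a point is the field intensity — the
Euclidean norm of the electric field vector, in V/m. The skull is by far the
most resistive layer in the current path, so drilling small burr holes
(skull-remodeling surgery, SR-surgery) over the tumor opens low-resistance
corridors that locally raise the dose in the tissue beneath. `ttdose`
simulates this situation end to end on a synthetic head phantom: it builds
the anatomy, places the surgical burr holes and the transducer arrays,
solves the conduction problem, and quantifies dose, enhancement and
parameter uncertainty.

At 200 kHz, capacitive effects in tissue are negligible for this purpose and
the field is treated quasi-statically: the potential obeys
$\nabla\cdot(\sigma\nabla\varphi) = 0$ with insulating boundaries on the head
surface except at the electrodes, and $E = -\nabla\varphi$.

## The phantom

The anatomy is a set of nested concentric ellipsoids: scalp (6 mm), skull
(7 mm), CSF (3 mm), cortical gray matter (4 mm), and white matter filling the
interior, with outer semi-axes 85 x 105 x 95 mm — representative adult head
dimensions. A real post-operative anatomy differs in shell thickness,
curvature, gyrification, and the presence of muscle, blood and eyes; the
phantom deliberately trades those for a fully parametric, reproducible
geometry, because the placement principles under study are geometric rather
than patient-specific. Consequences of this choice are discussed under
*Limitations*.

The pathology emulates a resected superficial lesion: a 25 mm spherical
resection cavity buried 2 mm below the cortical surface, a 25 mm spherical
residual tumor tangent to the cavity directly beneath it, and an 8 mm
cylindrical surgical funnel from the cavity to the inner skull table. The
lesion axis points at the scalp point 50 mm above the axial mid-plane at 60
degrees of azimuth, so the standard circumferential array sweep passes
directly over it.

SR-surgery is a quincunx of five 15 mm holes — one central, four at the
corners of a 45 mm square — drilled along the local skull normal and filled
with CSF-conductivity material. Variants place the quincunx directly over the
lesion, 30 mm superior / posterior / both (measured as geodesic distance
along the skull surface, matching how a surgeon would mark the scalp), or far
away in the occipito-parietal region; `none` is the intact-skull control.
The far position is 110 mm posterior and 20 mm inferior to the over-tumor
position: an early 80 mm placement turned out to sit directly under the
135–150 degree arrays, which reproduces "holes under the array" rather than a
genuinely distant configuration.

All solids are defined in world coordinates (RAS, mm) and rasterized by a
center-of-voxel inclusion test. Volumes round-trip through NIfTI-1 with a
JSON label sidecar.

## Conductivities

Isotropic tissue conductivities (S/m): scalp 0.25, skull 0.010 (spongy and
compact bone merged; a two-layer option with 0.025/0.008 exists), CSF 1.654,
gray matter 0.276, white matter 0.126, residual tumor 0.24, necrotic cavity
fluid 1.0. The funnel track and the burr holes are fluid-filled and default
to the CSF value. The burr-hole fill is the least certain of these — it is
granulation tissue somewhere between skin and CSF — which motivates the
uncertainty analysis below.

## Electrodes and layouts

One array is a 3 x 3 grid of 20 mm discs at 45 x 22 mm center-to-center
pitch, laid out by geodesic walks on the scalp so the pitches are preserved
as surface distances. Two opposed arrays form a pair driven at 0.9 A
(baseline-to-peak). Three layout families parameterize placement:

* **circumferential** — the pair rotates about the craniocaudal axis in 15
  degree steps on the ring 50 mm above the axial mid-plane; 0 degrees is the
  anterior–posterior configuration and 60 degrees puts the ipsilateral array
  over the lesion;
* **normal rotation** — the ipsilateral array of the 60 degree layout spins
  about its own surface normal while the contralateral array stays fixed;
* **vertex translation** — starting 30 mm inferior to the 60 degree
  positions, both arrays travel (20–150 mm, 10 mm steps) along their
  meridians toward the vertex. On this phantom the meridian arc to the pole
  is ~121 mm, so each array center clamps 12 mm short of the pole; at large
  travels the footprints overlap and the configuration becomes a deliberate
  scalp short.

Each disc is realized as the set of scalp voxels within the disc radius and
within a fixed 4 mm layer under the surface; those voxels receive the cap
conductivity (500 S/m, configurable) and are tied to a common ideal terminal
per array. Keeping the contact depth fixed in millimetres (rather than in
voxels) makes the electrode geometry independent of grid resolution. The
paper-facing quantity is the total pair current, so the solve uses unit
terminal potentials and rescales the potential to the requested current
afterwards — exact by linearity. Where the two arrays' footprints physically
overlap (vertex-translation extremes), the contested voxels are dropped from
both terminals; the remaining adjacent source/sink patches reproduce the
near-total scalp shunting such a montage would cause in reality.

## Discretization and solver

The conduction equation is discretized cell-centered finite-volume on the
voxel lattice with a 7-point stencil. Face conductances are harmonic means of
the adjacent voxel conductivities times face area over spacing — exact for
series resistors, conservative by construction, and zero across faces to
background, which implements the insulating boundary without any surface
meshing. The resulting system is symmetric positive definite and is solved
with conjugate gradients preconditioned by symmetric Gauss–Seidel, to a
relative residual of 1e-8 by default (161 iterations for the default 3 mm
phantom, ~131k conductive unknowns). The solver is deterministic; repeated
runs are bit-identical. Charge conservation (source vs. sink terminal
current) holds to the solve tolerance; tests that assert 1e-6 balance solve
at 1e-10.

Field vectors are recovered by central differences of the potential (one-
sided at domain boundaries), and the dose is the voxelwise Euclidean norm.

Numerical behavior worth knowing: the dominant discretization error is the
stair-step rasterization of the thin resistive skull, so scalar summaries
converge between first and second order in the voxel size. On a layered
sphere the WM median changes by ~28% from 4 mm to 2 mm and ~9% from 2 mm to
1 mm (error contraction ~0.3 per halving). Absolute field levels at 3 mm
should therefore be read as ~10% accurate, while *comparisons* between
layouts and variants — the object of the study — are far more stable because
the discretization bias is shared. One caveat: layouts whose tumor medians
differ by less than ~2% can exchange ranks between resolutions.

## Dose statistics, enhancement, uncertainty

Per region (white matter, gray matter, residual tumor, a peritumoral shell,
and the cavity), the report gives the voxelwise median, the peak defined as
the 99th percentile (linear interpolation between order statistics,
`quantile` type 7, the numpy convention), and the cumulative exposure curve
(fraction of the region above each threshold, 0–400 V/m in 2 V/m steps).
Voxels are equally weighted — the lattice is regular, unlike the
volume-weighted tetrahedra a FEM pipeline would use. The peritumoral shell is
not defined in the clinical literature; here it is brain tissue within a
configurable 10 mm margin of the cavity or tumor, excluding the pathology
itself.

Enhancement compares a with-holes solution against the control solved with
the *identical* array geometry: voxelwise difference maps, and percent maps
floored at 1 V/m of control intensity (voxels below the floor are flagged
undefined rather than reported as huge ratios). Region summaries use the
difference of medians and its ratio to the control median, which needs no
floor. The summary form (difference of medians, not median of differences)
is a choice; both are computable from the maps.

The burr-hole conductivity uncertainty is propagated by seeded Monte Carlo:
draws uniform on [0.465, 1.654] S/m, one solve per draw (warm-started from
the previous draw's potential), accumulating voxelwise mean and sample SD. A
regression-surrogate method (polynomial chaos) would be more
sample-efficient, but with a single uncertain scalar, 64 draws at 3 mm are
cheap and trivially verifiable — the mocked-solver test recovers the
closed-form uniform SD, and the real-physics result (relative SD ~2% under
the holes, well under 10%) is insensitive to the draw count.

## Study sizes used by the packaged checks

The shipped tests and the acceptance script run the full experiment matrix at
3 mm (five SR variants plus control, twelve circumferential layouts,
fourteen vertex travels, twelve normal rotations, 64 Monte-Carlo draws), with
the grid-comparison check repeated at 2 mm; unit tests use a reduced phantom
at 4 mm. These sizes were chosen so the whole suite runs on a laptop-class
machine in minutes while keeping every qualitative contrast (enhancement
direction, localization, shunting, rotation tolerance) far from its decision
threshold.

## Limitations

* The phantom is smooth and ellipsoidal: no gyri, no ventricles, no muscle,
  blood or eyes, and uniform shell thicknesses. Absolute medians here run
  higher than in MRI-derived models (smaller conducting cross-section);
  conclusions should be read as contrasts, not absolute doses.
* Isotropic, purely ohmic conduction; no capacitive effects, no DTI-derived
  anisotropy.
* The craniotome track and titanium fixation hardware of a real SR-surgery
  are not modeled.
* Only a single active array pair is simulated; clinical therapy alternates
  two orthogonal pairs.
* Voxelized electrodes cannot represent the 1 mm physical cap height; the
  contact-patch contract above is the intended interpretation at these
  resolutions.
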