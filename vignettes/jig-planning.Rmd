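---
title: "Geometry and validation of jig-based cochlear-implant access planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and validation of jig-based cochlear-implant access planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jigplan)
```

## The planning problem

Minimally invasive cochlear implantation replaces the open mastoidectomy
with a single straight drill channel from the skull surface to the round
window. The channel must thread the facial recess, the bony corridor
bounded by the facial-nerve canal (FN) on one side and the chorda tympani
(CT) on the other, while staying clear of the posterior wall of the
external auditory canal (EAC). In the jig-based workflow the plan is
physically realized by a through-hole in a patient-specific positioning
jig mounted on a bone-anchored frame, so the computational chain is:
localize the frame's X-ray marker in the scan, plan the path in image
coordinates, transfer it to frame coordinates as a hole pose, and verify
the manufactured hole.

This vignette documents the models, parameter choices and numerical
decisions behind each stage, and what the synthetic-phantom validation
does and does not demonstrate.

## Clearance model

Risk structures are modelled as capsules: all points within a fixed radius
of a centerline polyline. Nerve canals are tubes at the millimetre scale,
and a capsule is the coarsest shape that still makes the planning quantity
exact. The quantity reported per structure is the shortest distance
`d_S` from the drill-path **centerline** to the structure **surface**.
This convention, rather than centerline-to-centerline, is what makes the
margin arithmetic a drill-radius comparison:

* margin at diameter D: `m_S(D) = d_S − D/2`,
* effective recess width: `w = d_FN + d_CT`,
* diameter D fits when `min(d_FN, d_CT) ≥ D/2`.

The width `w` sums two distances that need not be collinear; it is
reported because it is the figure surgeons quote, not because it is a
Euclidean gap. Negative `d_S` values are returned unclamped so a caller
can distinguish a path that touches a canal from one that penetrates it.

Two boundary conventions deserve note. Feasibility is **inclusive**
(`≥`): a drill surface exactly grazing the bony boundary still "fits";
a strict variant (`feasible_strict`, "passes freely") is reported
alongside, because an intraoperative pass/fail call at zero margin is
genuinely ambiguous. The 0.3 mm FN margin is a **soft** rule: anatomy
(typically the EAC wall) can force a smaller margin, so
`check_fn_constraint()` emits a warning note for margins in `[0, 0.3)` mm
rather than rejecting the plan — reflecting clinical practice, where such
a case was accepted at 0.29 mm.

The distance primitive is the standard clamped closest-point
parameterization for segment-segment distance; parallel ties are resolved
by clamping the first parameter to zero, which cannot change the distance
value. It is verified against a purely sampling-based oracle (coarse
parameter grid plus two dense refinement rounds, accurate to ~1e-8 mm,
sharing no code with the closed form) on 200 random scenes.

### EAC distance convention

Whether a published "distance to the EAC wall" refers to the path axis or
to the drill surface is ambiguous, so `check_shaft_eac()` takes an
explicit `convention` argument and reports both the axis distance and the
convention-specific value. The pipeline default is
`drill_surface_to_wall`: under the axis reading, a 3 mm guidance shaft
would be declared "touching" for every wall closer than 1.5 mm to the
axis, yet clinically such paths (walls 0.6–1.9 mm from the axis) were
executed without shaft contact — the axis reading is therefore not usable
as a hard gate. The choice is the package's own and is configurable.

## Marker registration

The frame's marker carries titanium balls at known positions. The default
model is a five-ball, non-symmetric layout spanning ~35 mm whose ten
inter-ball distances are pairwise distinct, so no rigid motion can map the
layout onto itself; the clinical layout is unpublished and the model is
user-replaceable (`marker_model()`, JSON schema on `read_marker_model()`).

Detection thresholds the volume (default: Otsu restricted to the top 1%
intensity tail — titanium is the brightest material, so modelling the full
histogram is unnecessary), labels 26-connected components, filters them by
equivalent-sphere radius, and returns intensity-weighted sub-voxel
centroids sorted lexicographically — determinism matters more here than
the last hundredth of a voxel. Matching is an exhaustive search over
injective model-to-detection assignments scored by how many model
inter-ball distances are reproduced within tolerance (ties broken by total
residual); exhaustive search is exact and cheap for ≤ 10 balls. The rigid
fit is the SVD/Kabsch solution with a determinant guard that forbids
reflections.

Validation: on a noiseless rasterized marker at 0.3 mm voxels the
recovered pose is within 0.05 mm / 0.05° of ground truth with FRE below
0.01 mm; the Monte-Carlo mean FRE at σ = 0.05 mm per-axis fiducial noise
(N = 6, 500 draws) matches the closed-form expectation
`sqrt(⟨FRE²⟩) = σ·sqrt(3(1 − 2/N))` within a few percent; and with 0.1
voxel centroid noise the target registration error 50 mm from the marker
stays below 0.5 mm in at least 95% of 500 draws.

## Jig through-hole and deviation

The hole pose anchors the path where it crosses the jig reference plane
(the jig's datum is a configuration choice — the clinical jig's datum is
unpublished — as are the 5 mm boundary-disc radius and 30° tilt limit of
the default envelope). A registration is only accepted below an FRE gate
(default 0.3 mm): transferring a plan through a bad registration is the
one error the geometry cannot detect downstream.

Manufacturing deviation is the lateral offset between nominal and measured
hole axes at the nominal target depth,
`‖(p_m + L·a_m) − (p_n + L·a_n)‖`. An axial offset does not displace the
drill axis, so it is deliberately excluded. For a pure axis tilt θ the
exact value is the chord `2L·sin(θ/2)`, which equals the familiar
small-angle `L·tan θ` to within ~1e-7 at the sub-degree errors relevant
here; tests pin the exact form at 1e-9 and the small-angle agreement at
its true magnitude. The QC tolerance defaults to 0.3 mm so that a passing
jig cannot by itself consume the planned FN margin.

## Entry optimization

`optimize_entry()` maximizes the smaller of the two nerve margins over a
disc of candidate entry points (the jig-reachable region), subject to the
EAC shaft check, with the FN rule reported softly. The search is a regular
grid (0.25 mm pitch — half the typical planning deviation budget) followed
by two local refinement rounds at pitch/10 and pitch/100; ties are broken
by distance to the disc center, then lexicographically, so results are
deterministic. A grid is preferred over gradient methods because the
objective is piecewise-smooth (a min of distances) and the domain is tiny.

## The synthetic phantom

No imaging data accompany the clinical work, so validation uses a phantom
whose geometry is placed in closed form: the target sits at the origin,
the canonical path runs along −z, and each nerve is a straight capsule
crossing the corridor perpendicular to the axis with its closest
centerline point offset laterally by exactly `d + r`. Straight canals are
a deliberate simplification — over the 3–4 mm extent of the facial recess
the canals' curvature is negligible for a shortest-distance computation.
The EAC lumen is an air capsule parallel to the path, and a bone slab of
configurable thickness backed by a 2 mm air-cell layer occupies the
screw-site corner of the volume, kept clear of the nerve corridor so the
structures remain topologically separate after rasterization.

Defaults were fixed once from the clinically observed ranges: nerve
clearances d_FN = 1.1 / d_CT = 1.45 mm (observed 1.04–1.33 and
0.95–2.28 mm), EAC axis distance 1.1 mm (0.6–1.9 mm), slab 5.6 mm
(observed mean 5.62 mm, range 3.7–6.9 mm), 0.3 mm isotropic voxels (the
intraoperative scanner's resolution), Gaussian noise at 2% of the titanium
intensity. Canal radii (FN 0.7 mm, CT 0.3 mm) follow typical temporal-bone
anatomy; they affect only where the surface sits, not the planning
arithmetic. Material intensities (air −1000, soft tissue 0, bone 1000,
titanium 3000) are CT-like arbitrary units; only their ordering matters.

Rasterization uses linear partial-volume blending over a one-voxel band at
each surface and is fully determined by the spec's seed. The
rasterized-route check re-measures clearances **from the voxels**: a
soft-tissue intensity window segments canal voxels, connected components
are attributed to FN or CT by centroid proximity to the known centerlines,
and the axis-to-surface distance is the minimum axis-to-voxel-center
distance. Component voxels are additionally restricted to the attributed
canal's vicinity (radius + 2 voxels) because the air–bone partial-volume
shell of the EAC lumen also falls in the soft-tissue window and must not
be counted as nerve. Voxel-center quantization limits this route to about
one voxel of accuracy; the end-to-end tolerance is 1.5 voxels (0.45 mm).

### What the phantom does and does not show

Passing these tests shows the *planning arithmetic* is exact (analytic
route, ~1e-16 mm), and that detection, registration and clearance
measurement survive rasterization and noise at scanner resolution. The
phantom does not emulate beam hardening or metal artifacts, anatomical
segmentation (segmentations are inputs here, as in the clinical system),
curved canals, or soft-tissue deformation — so it says nothing about
segmentation accuracy on real scans, which the clinical workflow addresses
by surgeon review. Nor can planned distances predict intraoperative
pass/fail at a given diameter: the bundled trial table itself shows three
of six cases failing at 1.8 mm despite planned clearances that would admit
0.9 mm radii, which is why the outcome tallies are taken from the recorded
outcome rows rather than recomputed from geometry.

## Problem sizes used in the test suite

Suite and acceptance-script sizes were chosen as the smallest that
exercise each claim convincingly: 200 random scenes for each sampling
oracle, 500 Monte-Carlo draws for FRE and TRE statistics, 25 noisy marker
phantoms for detection RMS, 100 random analytic phantoms for ground-truth
recovery, and all six trial cases rasterized at full 0.3 mm resolution.
The complete suite runs in well under a minute on one CPU.
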