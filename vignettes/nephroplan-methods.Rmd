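---
title: "Predicting urinary-tract opening in partial nephrectomy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting urinary-tract opening in partial nephrectomy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nephroplan` turns a delay-phase contrast CT of a kidney into a
preoperative prediction: at each candidate surgical margin, would resecting
the tumor open the urinary tract, and where? This vignette explains the
models behind each stage, the parameters that matter, what the synthetic
phantom does and does not emulate, and the numerical choices and
limitations a careful user should know about.

## The clinical quantity being computed

A partial nephrectomy removes the tumor plus a protective rim of healthy
parenchyma. We model the *removed region* at margin $m$ as

$$R_m = \{\, v \in K \cup T : d(v, T) \le m \,\},$$

where $K$ and $T$ are the kidney and tumor masks and $d(\cdot, T)$ is the
Euclidean distance (in mm, spacing-aware) to the nearest tumor voxel
center. The urinary tract $U$ is *open* at margin $m$ exactly when
$R_m \cap U \neq \emptyset$ — transection, the event that requires
suturing of the collecting system — not mere proximity. Because the sets
$R_m$ are nested in $m$ (closed balls around the same tumor), the open
status is monotone along the margin schedule, and the *minimum opening
margin* is well defined: the smallest scheduled margin at which the tract
is entered. The complementary answer is the sentinel
"Not open with 5 mm margin" (the largest scheduled margin).

Alongside the discrete schedule answer the report always carries
`min_tract_distance_mm`, the minimum of the tumor distance field over
tract voxels. Margins on a 1 mm schedule are coarse; the continuous value
shows how close a call is. This matters because margins measured at
surgery are themselves position-dependent (smallest at the tumor's deepest
point), so a 1 mm discrepancy between a predicted and an observed opening
margin is expected behaviour, not an error mode.

### The voxel-center metric and its bias

Distances are computed voxel-center-to-voxel-center: well defined,
exactly testable against brute force, and independent of any surface
reconstruction. The cost is a one-sided bias: voxel centers lie strictly
inside their shapes, so the measured tumor-tract distance can exceed the
true surface-to-surface gap by up to roughly one voxel diagonal
($\sqrt{3}\,s$ for spacing $s$; in practice 0.1–0.9 mm at $s = 0.5$ mm in
our phantom studies, never negative). Consequences:

- predictions err toward "not open" by at most one schedule step, the
  cautious side for operative planning;
- the built-in validation (`margin_recovery_study()`) reports both strict
  agreement with the analytic answer and agreement after accounting for
  this voxelization tolerance (a one-step-high prediction with the gap
  within one voxel diagonal of the margin boundary);
- sub-millimetre reconstruction matters. The randomized study phantoms
  use 0.5 mm isotropic grids ($128^3$) precisely because the margin
  schedule is in 1 mm steps and the metric's resolution is a fraction of
  the spacing.

The default clinical-scale phantom (0.8 mm spacing) places the tumor with
a 0.3 mm sub-voxel offset: the lattice phase of the tumor-tract pair
determines where inside the $[g, g + \sqrt{3}s]$ band the measured
distance falls, and a grid-symmetric placement happens to sit at the top
of that band (3.2 mm for the 2.5 mm design gap), where the 3 mm bin is
missed purely through discretization. The offset placement sits on a wide
plateau (2.88 mm) representative of general positions; the scan over
lattice phases is part of the package's development record, and the
phantom geometry is fixed once here, not a tunable.

## Segmentation models

### Kidney: scribble-constrained graph cut

The user marks a few foreground voxels inside the kidney and background
voxels outside. The segmentation minimises

$$E(x) = \sum_v D_v(x_v) \;+\; \lambda \sum_{(u,v) \in N}
\frac{\exp\!\big(-(I_u - I_v)^2 / 2\sigma^2\big)}{1 + \lVert u - v
\rVert_{mm}} \, [x_u \neq x_v]$$

over binary labelings $x$, where $D_v(\ell) = -\log p_\ell(I_v)$ with
$p_\ell$ a Gaussian kernel density estimate (Silverman bandwidth, guarded
for tiny or constant scribble samples) of the intensities of class
$\ell$'s scribbles, and the scribbles themselves are hard constraints
(terminal capacities exceeding the total finite energy). Defaults:
$\lambda = 1$; $\sigma$ estimated as the median absolute intensity step
between neighbouring voxels (floored at $10^{-6}$ for noise-free data,
where a vanishing $\sigma$ correctly makes any true intensity edge free
to cut); 6-neighbourhood (26 available). Full-3D neighbourhoods are used
rather than slice-wise 2D ones.

The minimiser is found exactly by max-flow/min-cut. The solver is a Dinic
blocking-flow implementation in C++: the generic solver available to R
(`igraph::max_flow`) is exact but impractically slow on voxel graphs
(two minutes at $40^3$; the Dinic solver does the same instance in
0.3 s and a $10^6$-voxel kidney volume in about 10 s). The test suite
validates the solver against `igraph` on hundreds of random s-t graphs
(flow value = cut value = reference flow), and validates the segmentation
energy against an independently written evaluator, including exhaustive
enumeration of boundary-band relabelings on tiny grids. Minimum cuts need
not be unique; tests therefore assert energy values and hard constraints,
never a particular labeling, except where intensities make the optimum
unique.

One practical note reflected in the annotation generator: the kidney
*region* is the whole organ, which contains the tumor and the
contrast-bright collecting system. Foreground scribbles must sample all
of those intensity populations (as a user naturally does when marking
inside points across several cross-sections); scribbles confined to
parenchyma let the cut carve out the bright tract as "background", and
the planner's removed region — defined on kidney ∪ tumor — then cannot
reach it.

### Urinary tract: seeded region growing

Delay-phase contrast makes the collecting system far brighter than
parenchyma. Growth from user seeds is restricted to voxels with CT value
strictly greater than a per-patient threshold $r$ (clinically chosen in
$[350, 420]$); the result is exactly the union over seeds of the
supra-threshold connected components containing them, and is therefore
idempotent and monotone non-increasing in $r$ — properties the suite
asserts against an independent flood-fill oracle. The comparison is
strict (`>`), matching the definition of the threshold as an exclusion
bound. Default connectivity is 6: face-connectivity prevents diagonal
leakage through thin tract walls; 26 is available. A seed whose own value
is $\le r$ is reported by position — it signals a mis-placed seed or a
wrong threshold, and silently dropping it would hide exactly the
per-patient tuning step the method requires.

### Tumor: implicit surface through planar contours

Tumors often lack a high-contrast boundary, so they are delineated by a
few closed contours on cross-sectional planes. A signed field is fitted
as a radial-basis expansion with the triharmonic kernel
$\varphi(r) = r^3$ plus a linear polynomial, constrained to zero at every
contour vertex and to $\pm h$ at points offset by one in-plane voxel
spacing $h$ along the in-plane contour normals (outside positive). The
zero level set then passes through all contours and interpolates smoothly
between planes; the mask is the set of voxel centers with negative field.

Numerical choices: the biharmonic kernel $\varphi(r) = r$ was evaluated
and rejected (its flatter extrapolation overshoots the end caps roughly
twice as far on a three-contour sphere fixture); interpolation is exact
by default (`smoothness = 0`), with an optional ridge term for noisy
contours; the dense symmetric system is solved directly and an
ill-conditioned system (e.g. duplicated contour points) is reported with
a reciprocal-condition estimate rather than silently regularised;
evaluation is restricted to a padded bounding box of the contours, both
for cost and because far-field RBF extrapolation is meaningless. The
surface between and slightly beyond the contoured planes is genuinely
interpolated, and end caps beyond the outermost planes are the least
constrained part of the fit: on the sphere fixture the caps account for
nearly all of the ~5% volume excess. Contours should bracket the tumor's
axial extent reasonably well.

`tol_fit` (0.25 mm, a quarter of typical in-plane spacing) documents the
guaranteed vertex-to-surface fidelity; with exact interpolation vertices
lie on the surface to machine precision.

## Mesh geometry

- **Distance fields**: exact squared-Euclidean separable transform
  (Felzenszwalb–Huttenlocher lower envelopes) generalised to anisotropic
  spacing, computed per axis in mm. Tested to $10^{-9}$ mm against
  all-pairs brute force, including anisotropic cases.
- **Surface extraction**: marching tetrahedra on the Freudenthal
  six-tetrahedron cube decomposition at iso-level 0.5 of the 0/1 mask.
  The decomposition is translation-consistent, so shared cube faces are
  triangulated identically and the surface of a closed mask is watertight
  (every edge on exactly two faces — asserted, not assumed). Vertices sit
  at grid-edge midpoints and are welded by edge identity; triangles are
  oriented outward so divergence-theorem volumes are consistent. Masks
  touching the grid border are padded with one zero layer first, because
  kidneys cropped at the volume edge are common and an open capsule would
  poison every downstream volume.
- **Volumes and areas**: enclosed volume via the signed tetrahedron sum
  (orientation-independent absolute value; watertightness is a
  precondition and is checked). A digitized 10 mm sphere at 0.5 mm
  spacing meshes to within 0.1% of its analytic volume. Surface *area* of
  a raw voxelized iso-surface, in contrast, carries a staircase excess
  (about +26% on a sphere); a few volume-preserving Laplacian smoothing
  passes recover the geometric area to within a few percent. Smoothing
  is off by default so geometric tests are exact; when on, enclosed
  volume drift beyond 2% is corrected by uniform rescaling about the
  centroid.
- **CT on the surface**: per-vertex trilinear interpolation of the CT
  volume at vertex positions, the package's stand-in for texture-mapping
  CT slices onto the resection surface. Out-of-volume vertices are
  clamped (with a warning in user-facing paths).

## The resection planner

One tumor distance field is computed per case and thresholded at every
scheduled margin (default 1–5 mm every 1 mm, strictly increasing), which
guarantees the nesting invariant by construction; per-margin removed
regions are bit-identical to independently recomputed ones. The margin
comparison is $\le$ (closed ball): a tract exactly at margin distance
counts as open, the cautious side. The removed-region domain is
kidney ∪ tumor, so a segmentation disagreement at the tumor rim can never
exclude tumor tissue. Tract voxels inside the tumor mask (segmentation
overlap) are treated as distance zero with a warning.

The *resection surface* is the interface the surgeon cuts: faces of the
removed-region mesh whose centroids lie strictly inside the kidney.
Interface faces sit deep in parenchyma where the trilinear kidney
occupancy is ~1, capsule faces sit on the kidney's own iso-surface where
it is ~0.5; the classifier keeps faces with occupancy > 0.75, cleanly
between the two populations. An entirely exophytic removal yields an
empty surface with a warning. The opening is reported as voxel count,
centroid, and exact maximum pairwise extent (computed directly up to
5000 voxels; beyond that the candidate set is first reduced to boundary
voxels, where the diameter of a voxel set is attained, keeping the
computation exact).

How the removed region is constructed from the masks — a voxel-domain
closed-ball expansion of the tumor within the kidney — is this package's
interpretation of "a kidney deformed to a given margin from the tumor";
mesh-offsetting formulations would differ at sub-voxel scale.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds a delay-phase-like scene: mid-intensity
parenchyma (150 CT units) in an ellipsoidal kidney, a darker tumor sphere
(60), and a bright tract tube (500, above the entire clinical threshold
range) along a polyline centerline (three segments by default, minimally
mimicking calyx-pelvis branching; straight tube in the randomized
studies for closed-form geometry), plus i.i.d. Gaussian noise
(default sd 15) under an explicit seed — identical seeds give bitwise
identical volumes. Masks are voxelized center-inside; the analytic
tumor-tract surface gap is computed in closed form from the shapes and
cross-checked in the suite by numeric minimisation and dense surface
sampling.

Default geometry: 136×92×80 voxels at 0.8 mm; kidney semi-axes
(50, 30, 25) mm; tumor radius 12 mm; tube radius 2 mm with a 2.5 mm
surface gap, so the expected minimum opening margin on the default
schedule is 3 mm. The randomized study phantoms are compact
($128^3$ at 0.5 mm, near-spherical kidney) with tumor radius 6–8.5 mm,
tube radius 1.2–1.8 mm, and a prescribed gap realised exactly as a
perpendicular offset.

What passing on phantoms does **not** show about real data: real CT has
partial-volume boundaries, scanner texture and artifacts rather than
i.i.d. noise and 4-level piecewise-constant intensities; real collecting
systems are thin, branched, and sometimes incompletely contrast-filled
(acquisition-timing dependent); real tumors are not spheres and their
contrast to parenchyma varies; and real annotation placement is a human
choice, not stratified sampling from ground truth. The phantom validates
the geometry and the algorithmic contracts, not clinical accuracy — the
per-patient threshold $r$, scribble placement and contour quality remain
the operator-dependent steps they are in practice.

## Reproducibility and problem sizes

All randomness (phantom noise, annotation sampling, study geometry) flows
from explicit integer seeds; pipeline runs with identical configuration
and seed produce byte-identical reports, and every run writes a
provenance record (configuration echo, package version, input checksums).
The validation study sizes used by the test suite and
`scripts/acceptance.R` — 50 randomized $128^3$ phantoms for margin
recovery, 20 random masks up to $25^3$ for the brute-force distance
check, $28^3$ noisy volumes for graph-cut quality, $64^3$ half-millimetre
grids for the contour fixtures — were chosen as the smallest scales at
which each property is cleanly separated from its failure mode.

## Known limitations

- The opening prediction inherits the one-sided voxel-center bias
  discussed above: at 1 mm schedule steps, predictions can be one step
  conservative when the true gap is within a voxel diagonal of a margin
  boundary.
- `min_tract_distance_mm` is the minimum over *all* tract voxels, while
  the opening test intersects the tract with kidney ∪ tumor; for a tract
  segmented partly outside the kidney mask the two can disagree. Keeping
  the kidney mask organ-complete (see the scribble note) avoids this.
- Graph-cut unaries are intensity-only; structures with overlapping
  intensity distributions rely entirely on the boundary term and
  scribble placement.
- The planner does not model tissue deformation, vessel anatomy, or the
  intraoperative pose; it answers a geometric question on the
  preoperative CT.
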