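---
title: "Methods: anatomical localization of intracranial electrodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomical localization of intracranial electrodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegloc)
```

This vignette is the package's account of its models and of the design
choices that were genuinely open: what each stage computes, why the
defaults are what they are, what the synthetic phantom does and does not
emulate, and the numerical conventions that matter when results are
compared across implementations.

## Coordinate model

Everything happens in one working frame: world RAS millimetres in the
native space of the pre-operative volume. Voxel indices are 0-based and the
4×4 affine maps an index to the world position of that voxel's *center*;
round trips `world_to_voxel(voxel_to_world(i)) = i` are then exact. Surface
meshes reconstructed by FreeSurfer-style tools live in a "surface RAS"
frame offset from scanner RAS by the world position of the volume center;
`read_surface(path, volume = vol)` applies that offset at read time, and
every container carries a `frame` tag (`scanner_ras` / `surface_ras`) so
that mixing the two frames — the classic silent failure of this kind of
pipeline — is detectable rather than invisible. Contact picks are treated
as scanner RAS; if a picking tool emits surface RAS instead, the tag (not a
guess) is the mechanism for catching it.

Label volumes are sampled by nearest voxel center, with half-way points
rounded away from zero componentwise (R's `round()` is banker's rounding
and would make `.5` cases parity-dependent); intensity volumes are sampled
trilinearly. Interpolating label ids is meaningless, hence the split.

## Probabilistic labelling (expanding-cylinder sampling)

For a contact at position $c$ with local shaft direction $u$ (central
difference of neighbour contacts; one-sided at the ends; undefined for a
single contact, which switches to spherical sampling), the algorithm lays a
cubic lattice of sample points with pitch $s$ over the cylinder of radius
$r_{\max}$ and half-length $h$ around $c$ along $u$. For each radius in the
schedule $r_k = k\,r_{\max}/K$, $f_L(r_k)$ is the fraction of lattice
points within radius $r_k$ (and axial distance $\le h$) whose parcellation
label is $L$, and

$$P(L) = \frac{1}{K}\sum_{k=1}^{K} f_L(r_k), \qquad \sum_L P(L) = 1 .$$

Parameters (all exposed in `ela_params()`):

* `r_max = 3` mm, `n_radii = 6`: the cylinder grows past a typical contact
  radius out to the few millimetres of pick/registration uncertainty;
  radii are weighted uniformly for transparency. Small radii dominate
  locality, large radii context — the mean over the schedule is a simple,
  monotone compromise.
* `half_length`: half the local inter-contact spacing by default (1 mm for
  isolated contacts), so adjacent cylinders tile the shaft without
  overlapping; a bipolar pair uses its midpoint, its own axis and half its
  separation.
* `sample_spacing = 0.5` mm: ~2200 lattice points per contact at the
  defaults, enough that the largest-radius fraction is stable to ~1%.

Two deliberate choices:

* **Half-offset lattice.** Samples sit at $(k+\tfrac12)s$ offsets from the
  contact on each axis, never on the contact itself. A contact-centred
  lattice would place an entire lattice *plane* exactly on any label
  boundary passing through the contact, and the rounding tie-break would
  hand that whole plane to one side — a ~0.09 bias in the
  boundary-straddling case. The half-offset lattice is symmetric about the
  contact and keeps that case at 0.5/0.5 up to lattice asymmetry < 0.05.
* **Volumetric membership.** Region membership of a sample point is read
  from the label volume rather than from reconstructed per-region
  surfaces. This makes the probabilistic and volumetric routes share one
  geometry primitive and makes the phantom's analytic truth exactly
  applicable; a surface-proximity flavour is recoverable from the
  enclosing volumes if needed.

Assignment takes the argmax over labels whose category is cortical or
subcortical grey. Exact ties break to the lower label id and are flagged;
if every grey probability is zero the overall argmax is returned with a
fallback flag, so white-matter or outside-brain contacts are reported as
such instead of being silently forced into the nearest grey region.
Background (outside-brain) mass is retained in the normalization so
probabilities are comparable across contacts.

## Volumetric labelling (enclosing volumes)

Each labellable region (cortical grey, subcortical grey, white) gets a
watertight boundary mesh:

* `voxelized` (default): the exact boundary of the union of voxel cubes
  carrying the label — the 0.5 isosurface of the binary mask. Every voxel
  center with the label is strictly inside, so membership agrees with the
  mask by construction away from the boundary. Where two labelled cubes
  touch only along an edge the raw quad surface is non-manifold; vertex
  fans are split there (faces generated by the same cube stay paired) so
  every edge is shared by exactly two faces.
* `alpha_complex`: the alpha complex over the voxel-center point cloud.
  On a regular lattice the Delaunay complex decomposes lattice cubes and
  every simplex in a cube has circumradius $\le \frac{\sqrt3}{2}\,v$
  (voxel size $v$), so for the default $\alpha = 2v$ the alpha complex is
  exactly the union of fully-occupied $2^3$ voxel-center cubes; its
  boundary is extracted the same way. This reproduces alpha-shape
  behaviour (thin single-voxel sheets are eroded) while remaining exact
  for the lattice case.

Membership is a ray-parity test against the watertight boundary (compiled;
a few fixed skew ray directions with retry on degenerate edge hits), with
points within $10^{-8}$ mm of the surface counting as inside so boundary
contacts are members. Classification precedence is total and fixed:
subcortical → cortical grey → white → inside-pial-hull (`pial_surface`,
surface-array contacts in sulci; the pial mesh itself, not its convex
hull) → `outside`. The precedence order is a package decision — the
volumes of adjacent structures share boundaries after voxelization, and
deep grey nuclei are the structures for which volumetric labelling is the
reference method, so they win ties.

## Brain-shift correction

Surface arrays displace with the brain between imaging and implantation.
The snapper minimizes

$$E(x) = \sum_i \lVert x_i - x_i^0\rVert^2 +
\lambda \sum_{(i,j)\in\mathcal E} \left(\lVert x_i - x_j\rVert -
d^0_{ij}\right)^2$$

subject to every contact lying on the target surface, with
$\mathcal E$ the 4-neighbourhood of the grid (chain for strips) and
$d^0$ the original neighbour distances. The target is the pial surface
smoothed by 20 Taubin iterations ($\lambda = 0.5$, $\mu = -0.53$ —
shrink-compensated, so a sphere keeps its radius within 1%), which fills
sulci so the array lands on the crowns as a physical sheet would.

The solver is deterministic by construction: it starts from the naive
per-contact nearest-point projection, then alternates one damped
Gauss–Seidel sweep (fixed order = contact order; each contact moves toward
the local stationary point of the unconstrained energy) with immediate
re-projection to the continuous nearest surface point. A sweep that fails
to decrease $E$ is rolled back and retried at half damping; the iteration
stops when no improvement above `tol = 1e-6` is possible or at
`max_iter = 200`. Consequences, by construction rather than by luck: the
per-sweep energy trace is non-increasing, the final energy is never worse
than naive projection, every output contact lies exactly on the surface,
and reruns are bit-identical. `lambda_deform = 1` weights a millimetre of
displacement like a millimetre of spacing distortion; it is exposed
because the right trade-off depends on how much the picks are trusted.
Depth electrodes are rejected — snapping is a surface-array correction.

## Measurements

Grey/white distances are *nearest-vertex* distances from each bipolar
midpoint to the pial and white meshes, matching the conventional
operationalization ("distance to the nearest reconstructed vertex"); exact
point-to-triangle distance is available via `project_to_surface()` but is
not the default. The discretization consequence is worth stating: with
mesh subdivision 4 the nearest vertex can sit up to ~2.8 mm of arc away,
so the vertex distance overestimates the true surface distance by
$\sqrt{d^2 + rR\alpha^2} - d$, which is negligible mid-shell (< 0.5 mm at
$d \approx 5$ mm) but dominates as $d \to 0$. Distance validation on the
phantom therefore anchors at mid-shell bipolar midpoints.

The "cortical axis" at a point is the area-weighted vertex normal at the
nearest pial vertex — a rigorous definition of a cortical-column direction
is an open question in the field, and a surface normal is the assumption
made here; the shaft angle is folded into [0°, 90°] since a
shaft has no preferred sign. On the spherical phantom, normals are radial
up to the same ~2.2° vertex-offset bound, which sets the test tolerances.

## The synthetic phantom

`make_head()` builds a deterministic labelled head: pial sphere
$R_p = 60$ mm and white sphere $R_w = 50$ mm (human-scale hemisphere
radii), 8 azimuthal cortical wedges between them (DKT-scale region count
along one angular coordinate), two spherical subcortical blobs of radius
8 mm at $(\pm 20, 0, 0)$ (hippocampus/amygdala-scale deep grey), 1 mm
isotropic voxels (standard T1 resolution), icosphere meshes at subdivision
4 (2562 vertices, ~4 mm edges — coarser than a real reconstruction but
analytically checkable). The analytic `truth()` function is the oracle;
the voxelized parcellation agrees with it everywhere except within one
voxel of an analytic boundary, which is why oracle comparisons exclude a
1 mm boundary band.

What the phantom does *not* emulate — and what passing tests therefore do
not show about clinical data: cortical folding (no sulci, so snapping onto
a smoothed sphere is easier than onto a real pial surface), partial-volume
and topology defects of real segmentations, CT metal artefact and pick
error, non-rigid brain shift, and anisotropic voxels. The phantom
validates the *computational* contracts: sampling, membership,
optimization, measurement and I/O.

Synthetic implants: depth electrodes are exactly colinear at exact spacing
(default 5 mm, the clinical median); grids are planar, tangent to the pial
sphere, at 10 mm pitch, with optional outward lift and Gaussian jitter
emulating brain shift (seeded; the caller's RNG state is preserved).

## Problem sizes and numerical conventions

The test suite and the acceptance script run on: the default phantom
(121³ voxels); a 240-contact interior-cortical battery (8 wedges × 15
directions × 2 contacts at radii 52.5/57.5 mm, all ≥ 2 mm inside their
wedge); 1000 interior random points for the volumetric oracle; a 4×4 grid
at 10 mm pitch lifted 3 mm with 0.5 mm jitter for snapping; 100 random
queries for the exhaustive nearest-vertex check. These sizes make every
quantitative property decidable in seconds while keeping the geometry
non-trivial.

Conventions that affect reproducibility: 0-based voxel indices with
half-away-from-zero rounding; half-offset sampling lattice; fixed
Gauss–Seidel sweep order; ties in argmaxes break to the lowest label id /
vertex index; STL is written in 32-bit floats (1e-4 mm round-trip
tolerance); probability CSVs carry 9 significant digits so re-read rows
still sum to 1 within 1e-6; BIDS TSVs use `n/a` for unknown values.

## Known limitations

* The probabilistic route reports the nearest grey structure even when its
  probability is small (the fallback flag fires only when *all* grey mass
  is zero); users comparing routes should expect white/grey disagreements
  for contacts a few millimetres from deep grey, as the worked example in
  the README shows.
* Vertex-based distances inherit the mesh resolution (see above); for
  sub-millimetre distance work use `project_to_surface()`.
* The snapper optimizes a local quadratic model with projection; it finds
  the physically sensible local minimum near the naive projection, not a
  certified global one.
* Reslicing names panels (coronal/sagittal/axial) from the affine's
  dominant axes and falls back to index-plane names with a warning for
  oblique volumes.
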