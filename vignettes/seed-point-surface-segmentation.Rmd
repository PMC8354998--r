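---
title: "Seed-point surface segmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-point surface segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what the segmentation model assumes, which knobs matter, how the synthetic
phantoms are built, and where the genuinely open design choices were
decided.

## The segmentation model

The object being partitioned is a triangle surface mesh in world
millimetres, typically produced by global Hounsfield-unit thresholding of a
CT volume followed by iso-surface triangulation. On such a surface,
adjacent bone segments (vertebrae touching at facet joints) are joined
through small contact zones where the surface folds sharply, while each
segment's own surface is locally smooth. The model exploits exactly that
contrast:

* each vertex carries a unit normal, the area-weighted mean of its incident
  face normals;
* two neighbouring vertices are *connected at threshold θ* when their
  normals differ by at most θ degrees;
* a region grows from labelled seed vertices by breadth-first traversal,
  claiming every unlabelled connected neighbour.

Growth therefore floods smooth areas and halts at creases whose normal jump
exceeds θ. The working assumption is scale separation: intra-segment
normal variation per edge stays well below the crease angle between
segments. On marching-cubes output this holds when the mesh resolution is
fine relative to the anatomy's curvature; it degrades with heavy surface
noise, which is why the threshold is adapted iteratively instead of fixed.

### The iterative schedule

One pass at a low θ labels only the smoothest terrain. The schedule then
raises θ by a fixed step and re-grows from the current region boundaries
(labelled vertices that still have unlabelled neighbours), repeating until
every segmentable vertex is labelled or the ceiling θ_max would be
exceeded. Parameters, all in degrees:

| parameter    | default | role |
|--------------|---------|------|
| `theta_init` | 5       | first-pass connectivity threshold; low so early growth cannot leak |
| `theta_step` | 5       | increment between passes; smaller steps give finer control, more passes |
| `theta_max`  | 60      | ceiling; must stay below the crease angle separating segments |

The defaults start at 5° and raise by 5° per pass. The ceiling is the one
parameter a user must reason about: everything below it is eventually
flooded, everything at or above it is a permanent barrier.

### Queue discipline and tie-breaking

The traversal is strict FIFO (true breadth-first): the frontier is enqueued
sorted by vertex index, a dequeued vertex labels its unlabelled connected
neighbours in ascending index order, and labelled vertices are never
relabelled. Two regions racing for the same vertex within a pass are
therefore resolved by arrival order, which the sorted initialisation makes
machine-independent — identical inputs give bit-identical label arrays. A
LIFO queue would instead grow depth-first along one branch at a time; the
ring-wise "oil film" behaviour that makes the method predictable requires
FIFO, and that is what the package implements.

The connectivity test is *local* — the angle between the dequeued vertex
and its neighbour, not between the neighbour and the seed. This makes
growth transitive along smooth gradients (a gently curving segment is
flooded even though its far side's normal differs greatly from the seed's),
which is the intended behaviour; the flip side is that a noise path of
many small steps can in principle sneak around a crease, which the low
initial threshold and the undo facility mitigate.

### Undo semantics

Every pass appends a log entry `(θ, newly labelled vertices, seeds added
just before the pass)`. `undo_last_pass()` reverts the entry's grown
vertices *and* its seeds — the entry is the unit of user intent, and this
keeps the invariant that replaying the log always reproduces the current
labels exactly (`replay_log()`). The one consequence worth knowing: undoing
the very first pass also removes the initial seeds, so an interactive hook
that undoes pass 1 must re-seed (the segmentation tests exercise exactly
this flow).

Vertices with no incident face have no meaningful normal; they are flagged
unsegmentable, excluded from the termination criterion, and never labelled.

## The evaluation suite

Surface agreement is measured from every vertex of the test mesh to the
nearest point (face interior, edge or vertex — computed exactly) of the
reference mesh, and vice versa, pooled. Vertex sampling matches the density
of marching-cubes output and keeps the metric deterministic; an
area-uniform sampling mode was considered and rejected as a default because
it would make reports depend on a random draw. From the pooled samples:

* **ASSD** — mean unsigned distance;
* **AASD** — mean *signed* distance; the sign convention is positive when
  the test point lies outside the reference surface (in front of the
  outward normal at its nearest point), so protrusions are positive and
  missing parts negative. Signed distances are pooled over both directions
  into a single mean — the only reading under which one signed number can
  summarise a both-ways comparison;
* **RMS**, **maximum**, **95th percentile** (linear interpolation between
  order statistics, `stats::quantile` type 7 — the same rule feeds the
  cumulative error curve, so curve(95) equals the report's p95 by
  construction);
* **% below tolerance** — strictly below, default 0.2 mm, vertex-counted.

`partition_by_plane()` reproduces substructure analyses (e.g. an
anterior/posterior split at a vertical plane through the pedicles);
vertices exactly on the plane go to the positive side so the two masks
always partition. Inter-observer agreement uses ICC(2,1) — two-way
random-effects, absolute agreement, single measure — computed from the
ANOVA mean squares; its correctness is tested against an independent
`stats::aov` recomputation.

The nearest-point search is exact. The default engine bins triangles into a
uniform grid and scans outward shell by shell, stopping once no unvisited
cell can beat the best distance; an exhaustive all-triangle scan is kept as
`method = "exhaustive"` and the test suite asserts bit-level agreement
between the two, plus agreement with a scalar reference implementation.

## The synthetic phantom generator

No clinical volumes are distributed, so the package generates its own study
material: chains of convex lobes stacked along *z*, fused at small contact
patches, with ground-truth labels, suggested seed layouts, optional surface
noise and optional holes at the contacts.

**Geometry.** Round lobes are surfaces of revolution. The radial profile is
`r(z) = c + A·f(sin(π z/h))` with the saturation `f(u) = u/((1−b) + b·u)`
(`b = 0` for the smooth "superellipsoid" lobe, `b = 0.65` for the
flatter-sided rounded box); `c` is the contact radius and the amplitude
`A = h·tan(γ/2)(1−b)/π` is chosen so the profile meets the contact circle
at exactly half the requested crease angle γ. End lobes close with a
hemispherical cap attached at the profile's zero-slope point, so the pole
is smooth. Consecutive lobes are joined across a 0.005 mm band of triangles
at the contact circle: the band's area is negligible, so the area-weighted
vertex normals on its two rims stay those of their own lobes and the
normal jump across the weld equals γ within mesh resolution (the generator
achieves it to about a degree at the default 1.2 mm resolution). Cube lobes
are the minimal worked example: their interior edges are fixed 90° creases
and the contact crease is effectively 180°, so `crease_angle` is ignored
for them.

**Ground truth and seeds.** Every vertex is labelled by its lobe of origin
(rim rings belong to their own lobe; contact ties would go to the lower
index). Two seed layouts per lobe mimic clinical placement logic: a 5-seed
layout (one body-centre vertex plus four near-contact vertices) and a
12-seed layout (four body vertices plus eight near-contact vertices). The
12-seed near-contact set extends the 5-seed set at every contact, mirroring
how an operator adds articular seeds rather than moving them.

**Noise and holes.** `perturb_mesh()` displaces vertices along their
normals by zero-mean Gaussian noise (seeded); `hole_fraction` deletes that
fraction of weld-band faces, reproducing the open facet-joint holes real
thresholded meshes show. All randomness flows through the single
`random_seed`, so every fixture is a pure function of its spec.

**What the phantoms do and do not emulate.** They reproduce the features
the algorithm's success depends on — smooth segment interiors, sharp small
contact creases, CT-like noise, contact holes — so passing tests show the
method separates touching convex segments under those conditions. They are
not anatomically shaped vertebrae: no inner cortical surface, no processes
or foramina, no beam hardening or kernel-specific CT texture. Results on
phantoms therefore validate the algorithmic machinery, not clinical
performance.

**Volumes.** `generate_phantom_volume()` rasterises the same solid at a
given spacing (recording its interior voxel count, which the thresholding
test checks), and `extract_surface()` triangulates an iso-surface with
marching tetrahedra — each cell split into six tetrahedra around its main
diagonal with linear interpolation along crossing edges. The decomposition
is conforming across cells, so supra-threshold regions away from the array
border give watertight surfaces; triangle winding is fixed at emission so
normals point away from the supra-threshold side, and closed components
enclose positive volume. Marching tetrahedra was chosen over classic
marching cubes because it needs no disambiguation tables to be
topologically consistent; it emits somewhat more (and thinner) triangles,
which the vertex-welding cleanup tolerates.

## Numerical choices

* Duplicate vertices weld at 1e-6 mm via spatial hashing; exact duplicates
  (per-facet STL storage, shared marching-tetrahedra edge points) always
  merge. Zero-area faces are dropped after welding.
* Vertex indices are 1-based throughout the R API; all deterministic
  tie-breaks ("lowest index wins") are stated in the function contracts.
* Seeds snap to the nearest vertex; exact ties go to the lowest index, and
  two seeds may not claim one vertex with different labels.
* Non-manifold edges (marching cubes can emit them) are tolerated
  everywhere and reported by the boundary-loop detector rather than raised.
* Mesh files are written at full double precision (`%.17g`), which is what
  makes repeated pipeline runs byte-identical.

## Test and experiment sizes

The suite keeps problem sizes small enough for a single CPU while staying
in the regime each property needs: oracle-equivalence checks use random
fixtures of at most 500 vertices (50 of them) and 1000 query points against
a ~220-triangle mesh; the exact-recovery fixture is the default-resolution
3-lobe chain (~2400 vertices); the half-normal noise check uses a
~10,000-vertex single lobe at σ = 0.05 mm. For that check the closed form
σ·√(2/π) is asserted on the mean distance from the *displaced* vertices to
the original surface — that is the quantity the derivation describes. The
reverse direction measures the distance from smooth vertices to the rough
perturbed interpolant, which is systematically smaller (the nearest point
on a plane tilted by neighbouring displacements is closer than the vertex's
own displacement), so the pooled two-way mean sits a few percent below the
closed form and is not asserted against it.

The seed-count experiment runs 20 fixtures at 0.4 mm noise with 30% contact
holes — the regime where occasional label races and starved pockets occur,
so comparing layouts has content; at lower noise both layouts recover every
fixture exactly and the comparison degenerates to a tie. The inter-observer
experiment scores two jittered seed placements (1.5 mm hand error) on 20
cases of graded noise against the noise-free reference geometry, per lobe,
so every rating carries its case's noise floor the way an
algorithm-versus-manual comparison would.

## Known limitations

* The signed distance takes its sign from the face normal of the nearest
  triangle; for a query point equidistant from faces of opposing
  orientation (deep inside a thin slab) the sign can flip with the
  tie-break. Unsigned statistics are unaffected.
* Crease control in the generator assumes the weld band stays negligible in
  area; at very coarse resolutions (edge length approaching the lobe size)
  the realised crease drifts from the requested angle.
* Growth cannot cross holes: a region cut off from its seeds by missing
  faces stays unlabelled until the ceiling, then is reported, not guessed.
* No mesh repair of any kind (hole filling, remeshing, smoothing) — the
  exported segments are exactly what the traversal labelled.
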