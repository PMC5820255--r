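---
title: "Curvature-map shape comparison of infant skulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-map shape comparison of infant skulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why this package exists

Open cranial vault reconstruction for craniosynostosis divides the
cranial vault into osseous panels that are relocated to restore a normal
head shape. Which panels to cut and where to move them is, in current
practice, decided interactively by the surgical team, so the plan
depends on the team's experience and taste. `cranioshape` implements an
objective alternative: it quantifies local skull shape by Gaussian
curvature maps and finds, for a chosen reference area on an
age-appropriate average skull, the region of the patient's skull whose
shape corresponds best. Every step is deterministic and user-independent
once the four skull-base landmarks are supplied.

The pipeline has five stages, each its own module:

1. **Volume pipeline** — CT volume to bone surface mesh.
2. **Registration** — landmark-based canonical pose.
3. **Sampling** — hemi-icosphere raycast resampling.
4. **Averaging** — per-ray mean reference skulls.
5. **Curvature + comparison** — quadric-fit curvature fields, ring
   curvature maps, L1 matching.

## From CT volume to mesh

Bone is segmented by thresholding at **167 HU** (`segment_bone`), a
value that separates infant cranial bone from soft tissue. Speckle
components below `min_component_voxels` (default 50) are removed and the
binary indicator is smoothed with a Gaussian of `smoothing_sigma_mm`
(default 0.5 mm, converted to voxels per axis) and re-thresholded at 0.5
(`denoise`). The threshold is configurable per run but treated as fixed
in routine use.

`extract_surface` triangulates the 0.5 iso-level by **marching
tetrahedra**: each grid cell is split into six tetrahedra and the linear
interpolant is contoured per tetrahedron. Compared with table-based
marching cubes this has no ambiguous cases, so closed voxel solids
always yield watertight, consistently outward-oriented meshes — a
property the downstream raycasting relies on. Vertex placement is the
same linear interpolation along grid edges. Because a raw 0/1 indicator
puts every crossing at an edge midpoint (a staircase surface whose area
overestimates a smooth surface by tens of percent), the indicator is
pre-smoothed with a small voxel-space Gaussian (`presmooth_sigma_vox`,
default 0.8 voxel) before contouring; with it, the surface area of a
voxelized ball of radius 20 mm is reproduced to well under 5%. The
sigma is specified in voxels, not millimetres, so mesh geometry scales
exactly linearly with voxel spacing.

DICOM input is read by a deliberately small part-10 reader (explicit VR
little endian, uncompressed 16-bit slices, one slice per file), which
covers CT exports and the package's own synthetic series writer;
compressed or multi-frame files are out of scope.

## Canonical registration

Four anatomical landmarks fix the patient-independent frame: the centre
of the **sella turcica** maps to the origin, the **sella–nasion** line
to the +y axis, and both **anterior clinoid processes** are placed as
close to the x,y-plane as possible. Four landmarks over-determine a
rigid frame, so the two exact constraints (sella, nasion) are imposed
first and the remaining rotation about y is chosen in closed form to
minimise the summed squared z-coordinates of the two clinoids — a
least-squares flattening that stays well-defined for imperfect anatomy.
Handedness is fixed by mapping the right clinoid to x > 0 (+z
superior). The transform is strictly rigid: no scaling, no surface ICP.

## Hemi-icosphere resampling

Registered skulls are resampled by casting one ray per direction of a
fixed direction set: the vertices of an icosphere (icosahedron with
4-to-1 triangle subdivision and re-projection, `10 * 4^L + 2` vertices
at level `L`), cut to the superior hemisphere `z >= -eps` with `eps`
half the minimal vertex spacing so that equatorial directions survive
rounding. The default level 6 gives 20481 directions over the cranial
vault. Ray–mesh intersections use the Möller–Trumbore algorithm; per
ray, the nearest hit is the **inner** table radius and the farthest the
**outer** one, duplicate hits closer than 1e-9 mm (shared triangle
edges) collapse to one. The ray origin defaults to the coordinate
origin, i.e. the sella centre. Rays that miss (fontanelles, sutures,
foramina) are marked invalid and filled by harmonic (Laplacian)
interpolation of neighbouring radii over the sampling graph, iterated
to a 1e-6 mm tolerance (`fill_missing`); the discrete maximum principle
guarantees filled values stay within the range of their boundary.

Because every skull is sampled on the *same* directions, per-ray radii
are directly comparable: an age-group reference skull is simply the
per-ray arithmetic mean over the cohort (`average_sampled`), and a
surgeon-specific overcorrection is a single multiplicative scale on the
reference radii (default 1.0; the appropriate degree of overcorrection
is a clinical choice the package does not make).

## Curvature at a metric scale

Gaussian curvature is estimated per vertex by implicit quadric fitting:
the face centroids within `radius_mm` of the vertex (restricted to its
connected component), weighted by face area, determine the unit-norm
coefficient vector of `F(x) = x'Ax + b'x + c` minimising the weighted
squared residuals — the smallest eigenvector of the 10x10 monomial
scatter matrix. Curvature then follows the implicit-surface formula

    kappa_G = grad(F) adj(H) grad(F)' / |grad(F)|^4,   H = 2A,

evaluated at the vertex. Degenerate patches are handled explicitly:
planar data make the small-eigenvalue subspace multi-dimensional, in
which case the representative with the smallest quadratic part (the
plane itself) is chosen; if even that is non-unique (collinear data) the
fit aborts with an ambiguity error. Vertices with fewer than 6 patch
faces inherit the values of their nearest supported neighbour.

Two numerical choices deserve mention:

* **Patch radius versus element size.** The fit is unbiased only when
  the patch spans several mesh elements; empirically (on iso-surfaced
  spheres) the estimate is within ~1% once the patch radius exceeds
  ~3.5 grid steps and degrades to 20%+ below ~2 steps. The default
  radius of **15 mm** is appropriate for infant reference skulls and
  gives the best detail discrimination there; a radius sweep (10–35 mm)
  is exposed for exploration. For the 50 mm test object a 5 mm patch is
  used so the smallest 4 mm bulge stays resolved. Larger patches damp
  noise at the price of spatial detail — curvature of discrete meshes is
  only defined at a non-zero scale, and the choice of that scale is part
  of the method.
* **Orientation sign.** `1/sqrt(kappa_G)` alone cannot tell a bulge
  from an equally curved hole. Each vertex therefore carries a sign
  taken from the implicit mean curvature relative to the outward
  normal: +1 where the surface bends away from the normal (convex), -1
  towards it (concave). The signed radius `R_s = sign/sqrt(|kappa_G|)`
  (with `|kappa_G|` floored at 1e-8 mm^-2 so flat points stay bounded)
  is log-compressed as `sign(R_s) log(1 + |R_s|)`, which tames the
  dynamic range for display and comparison.

## Ring curvature maps and L1 matching

The shape descriptor of a vertex is its **ring curvature map**:
breadth-first rings 0..8 by edge-graph distance, entry `k` the
area-weighted mean Gaussian curvature over ring `k` (vertex weight = a
third of its incident face areas, i.e. the ring's surface), log-scaled
with the ring's area-weighted majority orientation sign. Ring 0 (the
centre vertex) is included, which sharpens locality. Two maps are
compared by their **L1 distance**; `find_matches` ranks every target
vertex and, when secondary matches are requested, suppresses vertices
within `exclusion_rings` of any better-ranked match so that the second
match is spatially distinct. Maps with more than 30% partial rings
(hemisphere rim) are excluded from the search. Ties break to the lower
vertex index, so results are fully deterministic. Only the outer layer
is compared: the inner table is irrelevant for the visible head shape.

Because rings and curvature are intrinsic, matching is equivariant
under rigid motion of either surface, and because curvature is *not*
scale invariant, bulges of different size do not match each other — a
feature, since panels must be matched at their true size.

## The synthetic fixtures

No patient data ships with the package; everything is generated:

* `make_test_object()` — a 50 mm sphere with five bulges of radii 4, 6,
  8, 10, 12 mm, a torus bulge (ring 10 mm, tube 3 mm) and a spherical
  hole whose 10 mm radius equals the second-largest bulge, all centred
  on the base surface, composed as a signed-distance union/difference
  and iso-surfaced. Feature directions are fixed at >= 40 degrees
  separation so features do not overlap. The default grid step
  (~1.35 mm, ~75k vertices) keeps 5 mm quadric patches unbiased at the
  smallest bulge (see the patch/step ratio above).
* `make_phantom_volume()` — an ellipsoidal bone shell (semi-axes
  60x75x55 mm, 4 mm thick, 1000 HU on 0 HU background) with labelled,
  bilaterally symmetric landmarks, standing in for a cranial CT.
* `make_symmetric_skull_mesh()` — the registered outer surface of the
  phantom with two mirrored temple bulges; the right apex is the
  reference of the within-skull symmetry experiment and its mirror is
  the expected second match.

All fixtures are deterministic given their spec. They emulate the
geometry and intensity contrast of cranial CT but none of its noise,
beam hardening, fontanelle topology or anatomical detail, so passing
tests demonstrate correctness of the geometry processing, not clinical
performance on real scans.

## Problem sizes and runtime

The shipped experiments run on one CPU in a few minutes: the rotation
experiment uses the default test object (~75k vertices) with 5 mm
patches and 8-ring maps; sampling oracles use hemisphere level 3 (337
rays) against level-5 icospheres; the averaging checks use 12-member
synthetic cohorts at level 3. These sizes were chosen so each check is
sharp (features span many elements) while the whole suite stays fast.

## Known limitations

* The comparison is purely geometric: no suture or vessel avoidance, no
  osteotomy-panel optimisation, no stability constraints — identifying a
  best-matching region is the input to planning, not a surgical plan.
* Landmarks are manual inputs; no auto-detection is attempted.
* The DICOM reader intentionally covers only uncompressed explicit-VR
  little-endian series.
* Curvature maps are scale variant by design; skulls of different ages
  need age-matched references and possibly different patch radii.
* Hemisphere resampling assumes the vault is star-shaped about the
  sella; pathologies violating that would need a different origin.
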