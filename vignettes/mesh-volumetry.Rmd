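---
title: "Closing partial food-scan meshes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing partial food-scan meshes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealvol)
```

## The problem

Handheld depth-sensor scans of plated food produce triangular surface
meshes with systematic defects: the sensor never sees the underside of an
item, the seam where food meets the plate (or another item) is occluded,
and segmentation of the plate away from the food opens a large boundary.
An enclosed volume is only defined for a watertight surface, so the
pipeline's job is to (1) find every hole, (2) close it without disturbing
the measured geometry away from the hole, (3) compute the volume, and
(4) convert leftover volume into consumed nutrients against what the
kitchen reports having served.

## Hole detection

After welding duplicate vertices (`clean_mesh()`, tolerance 1e-6 cm —
scanner exports routinely duplicate corner vertices, and boundary
detection is meaningless on unwelded topology), a *boundary edge* is an
edge used by exactly one face. Chaining boundary half-edges in the
direction induced by their adjacent faces yields closed loops, one per
hole (`find_holes()`).

Each loop vertex $v_i$ carries its *front angle* $\theta_i$: the interior
angle between the two boundary edges $(e_{i-1,i}, e_{i+1,i})$, opened
toward the hole. The angle between two 3D edge vectors is ambiguous for
reflex vertices ($\theta > 180^\circ$), and disambiguating against the
normals of adjacent mesh faces fails on exactly the case we care most
about — a box missing its top, where the side-face normals average to
zero. We therefore disambiguate against the Newell (area-vector) normal
of the loop polygon itself: for any traversal direction the Newell normal
flips consistently, so interior angles are well defined even for
non-planar loops. Degenerate (near-zero-area) fronts fall back to the
initial loop normal.

## Advancing-front filling

`afm_fill()` iteratively selects the front vertex with the smallest
$\theta_i$ and applies one of three rules:

* $\theta_i \le 75^\circ$ — connect $(v_{i-1}, v_i, v_{i+1})$ directly;
* $75^\circ < \theta_i \le 135^\circ$ — add one vertex on the angle
  bisector, in the plane spanned by the two boundary edges, at their
  mean length;
* $\theta_i > 135^\circ$ — add two vertices on the trisectors, same
  plane, mean edge length.

A candidate vertex closer than $\varepsilon$ to an existing front vertex
is replaced by that vertex; among several candidates the one whose
triangle is closest to equilateral (by the normalized ratio
$4\sqrt{3}A/\sum l^2$) wins. Such merges prevent cluttered, overlapping
patches but can make the front visit a vertex twice; the front is then
split at the duplicate and each simple sub-front processed in turn — a
two-vertex remnant is a healed seam and needs no triangles.

Design choices where the procedure is underdetermined:

* **Selection order.** Each iteration re-selects the global minimum
  $\theta$ over the whole front (rather than walking to an adjacent
  vertex), the standard advancing-front variant; exact ties break toward
  the lowest vertex index, so the fill is deterministic.
* **Default $\varepsilon$.** Half the mean boundary-edge length of the
  loop, exposed as `epsilon_factor` in `fill_config()`. No canonical
  value exists; larger values coarsen the patch (patch vertex count is
  non-increasing in $\varepsilon$, which the suite checks).
* **Trisector insertion order.** The new vertex adjacent to $v_{i-1}$ on
  the updated front is the one at $2\theta/3$ from the $v_{i+1}$ edge.
  Swapping the pair inverts the middle triangle — the patch still closes
  but double-covers a sliver, which the planar area-recovery check
  ($\pm 0.5\%$) catches.
* **Termination.** The front must close within `10 * loop_size`
  iterations; exceeding the bound raises an error rather than looping
  (an over-large $\varepsilon$ can collapse the front unproductively).
* **Near-collinear edges.** Above ${\sim}179^\circ$ the two edge vectors
  no longer span a plane; the in-plane frame is stabilized with the
  front normal.

## Harmonic refinement

Patch-interior vertices are repositioned by minimizing the discrete
Dirichlet energy: solve, per coordinate,

$$\sum_{v_j \in N_i} \omega_{ij}\,(f(v_j) - f(v_i)) = 0,
\qquad \omega_{ij} = \cot\alpha_{ij} + \cot\beta_{ij},$$

with $N_i$ the 1-ring of $v_i$, $(\alpha_{ij}, \beta_{ij})$ the angles
opposite edge $(i,j)$ in its two incident triangles, and every original
mesh or boundary vertex fixed (`harmonic_refine()`, sparse Cholesky via
Matrix). Only the harmonic step is performed — no normal estimation,
triangle rotation, or Poisson reconstruction — because food holes are
predominantly planar (items lie flat on the plate), and for planar holes
the harmonic solution is exact. Two consequences worth knowing:

* The cotangent Laplacian reproduces linear functions, so a patch over a
  planar hole stays in the hole's plane (checked to 1e-8 cm), and the
  weights are computed once from the advancing-front geometry — the
  solve is a single linear system, not an iteration.
* Over strongly curved holes the membrane solution is *depressed*
  relative to the missing cap (the maximum principle keeps it inside
  the boundary's bounding box, which the suite asserts). This
  under-estimates volume for dome-like blind spots; it is a documented
  limitation, not corrected.

Numerical guards: corner angles are clamped to $[10^{-4}, \pi - 10^{-4}]$
rad and cotangents to $\pm 10^6$ (`cot_clamp`) so skinny patch triangles
cannot poison the system; an all-degenerate 1-ring raises an error naming
the vertex.

## Volume

`signed_volume()` sums signed tetrahedra against the origin,
$V = \left|\sum_T \det(a, b, c)/6\right|$ — exact for polyhedra, so the
generated 7 cm cube yields 343 cm³ to the last bit. Non-watertight input
is refused (with the boundary-edge count); inconsistently wound input
(advancing-front patches can flip winding locally) is repaired by
flood-filling face adjacency and orienting each component to positive
volume, and flagged. `voxel_volume_oracle()` is the independent
cross-check: a vertical ray-parity count of voxel centers at a given
pitch, with the grid offset by irrational fractions of the pitch so rays
never graze axis-aligned edges. The suite requires agreement within 2%
at 0.05 cm pitch.

## Plate segmentation and item splitting

The original workflow segmented plate and items by hand in an
interactive mesh tool; here both steps are deterministic so the pipeline
is scriptable. `segment_plate()` runs RANSAC (500 seeded 3-point
hypotheses, 0.3 cm inlier band, least-squares refinement): faces whose
three vertices lie in the band are plate, the rest split into connected
components as item candidates. A plane must explain at least 20% of the
vertices, otherwise "no plate found" — note that strongly flattened
items can legitimately present such a band, so plate removal is opt-in.
`split_items()` replaces interactive item selection with one 3D seed
point per item: faces go to the nearest seed by geodesic flood fill over
the face-adjacency graph, with flood boundaries at concave creases whose
dihedral exceeds 50° — the valley where touching items meet. Faces
unreachable by any flood fall back to the Euclidean nearest seed.

## The synthetic-scan generator

Desk-scale validation needs scans with known ground truth.
`simulate_scan()` builds a closed solid (cube; fan cone; or a blob — a
seeded, smoothly perturbed sphere shaped into an apple, croissant or
mound), records its exact volume, perturbs vertices with Gaussian noise
along vertex normals (the desk-scale proxy for depth error along the
view ray), and punches blind-spot holes by removing faces near a point.
`scan_suite()` fixes the study conditions used throughout: twelve
scenarios (cubes with edges 5–10 cm, cones with radii 2–4 cm and heights
4–8 cm), one puncture each kept under 15% of the surface area, noise
cycling 0–0.05 cm. All randomness flows from a single integer seed
through a local Lehmer generator, so no global RNG state is touched and
every scenario is bit-reproducible.

What the generator does *not* emulate: view-dependent occlusion and
registration drift of a real structured-light sensor, texture-dependent
depth bias, ragged (non-circular) hole boundaries, and utensils or other
clutter. Passing the suite therefore demonstrates the geometry pipeline
is correct and stable under idealized damage; it does not certify
accuracy on physical captures, whose published per-model errors
(apple, pepper, scanned cube) are deliberately out of scope here.

## Nutrition accounting

With density $D$ (g/cm³) and per-gram nutrient content
$ND_g(i)$ for component $i$ (calories, carbohydrate, protein, sugar,
fat): $W = V \cdot D$, $CN(i) = W \cdot ND_g(i)$, and consumed
$CoN(i) = RN(i) - CN(i)$ against the kitchen-reported $RN$. Leftover
nutrients are summed across items per component before the subtraction
(per-meal, not per-item, accounting). $CoN + CN = RN$ holds exactly;
$CN(i) > RN(i)$ is retained but flagged. The shipped density table is a
clearly labeled synthetic fixture with plausible values — proprietary
nutrition-database content is not redistributed, and any CSV in the same
format plugs in.

## Study statistics

`method_stats()` reduces the packaged 13-trial fixture to the summary a
dietary study reports: total absolute error over trials with data,
percent of total actual grams, and the *population* standard deviation
of per-trial absolute errors — the only definition consistent with the
published summary rows (verified by hand before implementation). The
24-h-recall summary printed alongside the original table cannot be
reproduced from its own rows by any single summation rule, so it is
carried as metadata and never recomputed.

## Problem sizes

The test suite and acceptance script run at deliberately modest sizes:
blobs at 24×32 sphere resolution (~1.5k faces), cones at 48–64 segments,
the voxel oracle at 0.05 cm pitch on single items, and the twelve-scenario
suite described above. These sizes keep every geometric property tight
(watertightness, 2% oracle agreement, 0.5% planar area recovery) while
the full suite completes in well under a minute.
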