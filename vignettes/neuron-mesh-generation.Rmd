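---
title: "From morphological tracings to watertight neuron meshes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From morphological tracings to watertight neuron meshes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotess)
```

This vignette is the package's own account of the science: what is modelled,
which parameters matter, what the numerical choices are, and what the tests
do and do not establish.

## Input model: the tracing

The only input is a morphological tracing: a rooted tree of points, each
with a position (micrometres), a radius and a type code, serialized as SWC.
Neurites are polylines with per-point thickness; the soma is usually
under-described. Two soma dialects are handled: a single type-1 point
(centre + average radius, used directly) and a multi-point type-1
ring/contour, for which the centre is the centroid of the type-1 points and
the mean radius the average centroid distance. Which dialect fired is
recorded on the soma descriptor. Consecutive points with bit-identical
positions are collapsed at read time (with a warning) because the
orientation-vector computation needs non-zero segment directions.
Coordinates are taken as-is (right-handed, micrometres, no unit scaling).

## Soma: static linear FEM on a tetrahedral icosphere

The soma surface is unknown, so it is *reconstructed* by deforming a sphere
toward the first-order neurites. The domain is a subdivided icosahedron
projected to the soma sphere and filled with tetrahedra: at subdivision
level $L$ the interior holds $L$ radially scaled copies of the surface, the
prisms between consecutive shells are cut into three tetrahedra using a
sorted-column diagonal rule (which makes the cuts agree across shared prism
faces, so the mesh is conforming), and the innermost shell fans to the
centre vertex. The default level is 2 (162 surface vertices, 160 surface
quads after pairing), a surface density comparable to the coarse somata this
approach targets; standard icosphere subdivision only offers 42/162/642
surface vertices, so finer control is not meaningful here.

Surface triangles are merged pairwise into quads because the sweep and
refinement stages operate on quads. Pairing is a perfect matching on the
triangle adjacency graph, chosen greedily by coplanarity of the merged quad
(dot product of the two face normals, ties broken by lowest triangle index)
with full backtracking; a perfect matching always exists for these closed
cubic dual graphs, so the search terminates. One consequence worth noting:
the matching is deterministic but not equivariant under the icosahedron's
symmetries, so scene-level mirror symmetry holds only up to quad selection;
the FEM stage itself is exactly mirror-equivariant, and that is what the
symmetry test verifies (on an explicitly mirrored domain).

Each first-order neurite claims one surface quad — jointly, by minimising
the total angular distance between quad-centroid directions and insertion
directions, with quads required to be pairwise vertex-disjoint so their
boundary conditions cannot conflict. The assignment is solved by
branch-and-bound, exact on each anchor's cheapest `max(12, 4·n)` candidate
quads (widened to all quads if that restriction is infeasible; at least $n$
candidates per anchor guarantee a feasible vertex-disjoint solution exists
on these meshes).

The four vertices of an assigned quad are *prescribed*: they are placed on a
planar square centred at the neurite insertion point, normal to the
insertion direction, with corner-to-centre distance equal to the neurite
start radius — so the tube cross-section is continuous at the junction. The
square's in-plane rotation is fitted to the quad's current corners (circular
mean of corner angles) to avoid twisting the membrane. All other vertices
solve static equilibrium of isotropic linear elasticity on linear
tetrahedral elements, assembled from the closed-form stiffness
$K_{ai,bj} = V(\lambda\,\partial_i N_a \partial_j N_b + \mu\,\partial_j N_a
\partial_i N_b + \mu\,\delta_{ij}\nabla N_a\!\cdot\!\nabla N_b)$ and solved
with a sparse direct factorisation (Matrix). Constraints are pure
displacements, so the solution is independent of the Young modulus — the
modulus is kept only as a nominal parameter — and the Poisson ratio
$\nu \in (-1, 0.5)$ is the single shape control: lower $\nu$ lets the pulled
membrane swell, raising soma volume; the sweep helper (`poisson_sweep()`)
exposes this monotone trend. The direction of the trend presumes the
anchors' net effect is outward pull (the physical setup: dendrites attract
the sphere toward insertion points outside it); when constraints are
dominated by shrinking a large quad onto a small anchor square, the
near-incompressible limit can instead push volume outward and the trend
reverses — the sweep fixtures therefore place insertion points well outside
the sphere. The default is
$\nu = 0.3$, the midpoint of the range in which the deformations stay
well-behaved on our fixtures. Strong pulls can invert interior tetrahedra;
this is diagnosed with a count (warning) but does not affect the extracted
surface, which is what the pipeline consumes.

"Pulling" is implemented as Dirichlet constraints rather than applied
forces because the target quad geometry (position, orientation, size) is
known exactly; a force formulation would need an arbitrary stiffness-to-load
calibration to hit the same configuration.

## Neurites: quad-tube sweep with bifurcation stitching

At every tracing point a planar section-quad is placed: centred at the
point, normal to its orientation vector, with corner-to-centre distance
equal to the radius (the quad is inscribed in the cross-section circle, so
the refined surface at the section rings is exactly consistent with the
corner attributes). Orientation vectors: standard point — normalized sum of
the unit directions from parent and to child; bifurcation — normalized sum
of the two child directions (independent of the parent segment); ending —
the incoming direction; exact hairpins fall back to a deterministic unit
vector orthogonal to the incoming direction.

The in-plane rotation of each section-quad is not fixed by the orientation
vector, so rings are parallel-transported: the previous ring's first corner
direction is projected into the new section plane to seed the frame, and the
handedness is matched to the previous ring. This rotation-minimising choice
prevents tube twist; it is seeded at the soma by the anchor quad's own
corners.

Consecutive rings are joined by four lateral quads with outward
counter-clockwise winding. At a bifurcation the extra vertex
$v' = t + r\,\mathbf{o}$ is added and the section-quad is split along the
diagonal whose endpoints lie nearer the plane through the bifurcation point
and its two children; the two resulting rings (three quad corners plus
$v'$ each) seed the child tubes, and each child takes the ring whose Newell
normal best aligns with its direction. Points with three or more children
(legal SWC, though rare) are handled by recursive binary splitting in
child-id order and logged. Endings are closed by a single cap quad over the
last ring. In this construction the split quads are tube start *rings*, not
surface faces, so the final surface consists only of soma quads, lateral
quads and caps — and is closed, 2-manifold and of sphere topology for any
tree morphology, which the topology suite verifies over seeded synthetic
morphologies.

Every vertex carries its tracing point's position, radius and orientation
vector, plus its own radial direction; every lateral quad records its
segment $(t_0, t_1)$ with corners $v_0, v_1$ on the $t_0$ ring and
$v_2, v_3$ on the $t_1$ ring. These attributes, not the coarse geometry, are
what refinement evaluates — which is why traced positions and radii survive
bit-exactly into the output.

## Refinement: crack-free adaptive tessellation on the CPU

The refinement emulates the three user-visible substages of hardware
tessellation.

**Levels.** Importance is a scalar $\ge 1$ per tracing point — uniform, or
decreasing linearly with camera distance between a `near` and `far` radius —
and transfers to vertices through their tracing points. The outer level of a
patch edge is the weighted sum of its two vertex importances (default
weights ½/½, applied in canonical vertex order), rounded half-up and clamped
to $[1, \texttt{max\_level}]$; the inner level is the weighted sum of the
four corner importances (default ¼ each). Because an edge's level depends
only on the edge itself, the two patches sharing it always agree — this is
the whole crack-freeness argument, made bit-exact below. The weights and
rounding rule are configuration because no canonical values exist; uniform
weights are the symmetric default.

**Subdivision.** Each lateral quad becomes a parametric tessellation of the
unit square: a regular interior $(m{-}1)\times(m{-}1)$ point grid (inner
level $m$), boundary edges carrying $\text{outer}[e]+1$ vertices, and the
annulus between them stitched by parameter-merged triangle strips. Two
special cases: all levels 1 returns the original quad as two triangles (the
identity — uniform importance 1 reproduces the triangulated coarse mesh
vertex-for-vertex), and inner level 1 with any outer level above 1 is
promoted to an effective inner level 2 (one centre vertex) so the stitching
is well defined. The exact GPU primitive-generator pattern is not
reproduced; only the levels and the $(x, y)$ coordinates matter downstream.

**Evaluation.** A new vertex at $(x, y)$ on the patch over segment
$(t_0, t_1)$ is placed at $v = r\,\mathbf{n} + c$: $c$ from the cubic
Hermite centerline with tangents $\tilde{o}_i = s\,|t_1 - t_0|\,\mathbf{o}_i$
(adaptive magnitude, default scale $s = 1$), $r = (1{-}y) r_0 + y r_1$, and
$\mathbf{n}$ the normalized bilinear interpolation of the four corner
normals (with a slerp-free fallback to the $t_0$-edge pair in the measure-
zero case of cancelling normals). Scaling tangents by segment length
suppresses the loops a fixed tangent module produces on short segments: for
orientation vectors generated by the bisector rules the longitudinal speed
$|dc/dy|$ never vanishes, which the regression test checks against a fixed-
module control. Soma quads and caps are not Hermite-evaluated (they have no
two-point segment); they pass through at base resolution but absorb any
subdivided boundary rows of neighbouring lateral patches, fan-triangulated
around a centre vertex when extra boundary points exist, so no T-junctions
remain.

**Bit-exact welding.** Shared-edge vertices are generated once through
canonical edge routines whose arguments are integers (edge index along the
canonical direction, level) and canonical endpoint order; both adjacent
patches map their local indices to the same canonical call, so the two
sides produce bit-identical positions and the weld uses exact keys, not
float hashing. The crack audit re-derives both sides independently and
compares them bitwise.

## Validation metrics

`is_closed_manifold()` reports vertex/edge/face counts, Euler
characteristic, closedness (every edge in exactly two faces), orientation
consistency, component count and — when closed — the divergence-theorem
volume (fan triangulation about each face's first vertex; merged soma quads
are ordered so this fan reproduces their two source triangles, keeping the
coarse volume exactly the triangle-mesh volume). `hausdorff_summary()`
estimates the symmetric surface distance by area-weighted random sampling on
each mesh against exact point-triangle distances to the other, summarised as
mean/maximum/minimum; the estimator (sample count, seed) is reported with
the result, and distances below machine precision relative to the scene
scale are reported as zero. Sampling density is the accuracy control: on
concentric spheres the maximum converges to the radial gap as samples grow.

## Synthetic morphologies

No laboratory tracings ship with the package, so tests run on a synthetic
generator that emulates deposited tracings: a single soma point (default
radius 8 µm), first-order neurites starting just outside the soma surface,
tortuous growth (Gaussian bending, sd 0.25 rad per step), mean inter-point
spacing 5 µm, geometric radius taper 0.9 per point from 1.5 µm, and
bifurcations with probability 0.3 per section up to depth 3 — values chosen
once as typical of cortical dendrite tracings at NeuroMorpho-like sampling.
Each branch draws from its own counter-derived RNG stream, so adding a
neurite never perturbs existing geometry, and a forced first bifurcation
guarantees branching cases appear whenever they are possible. The generator
does not emulate neurite-type statistics, spines, boutons, self-avoidance or
tracing noise artefacts (duplicate points, gaps); conclusions from the test
suite therefore concern the meshing pipeline's correctness on well-formed
trees, not robustness to every artefact of real acquisitions — though the
reader validates zero-length segments and structural defects explicitly.

## Numerical choices and degenerate inputs

* Levels round half-up (`floor(x + 0.5)`), away from the banker's rounding
  of base R, so equal-weight midpoints resolve deterministically upward.
* Hairpin bisectors and degenerate bifurcation planes (children collinear
  with the parent point) fall back to deterministic orthogonal vectors /
  the first diagonal, with warnings where the input is suspect.
* The FEM solve uses one sparse LU/Cholesky factorisation; no iterative
  tolerance is involved. The linear patch test bounds discretisation error
  at machine precision, and modulus invariance holds to the factorisation's
  accuracy (observed ~1e-14).
* Problem sizes in the test and acceptance suites — soma level 2 (487
  FEM vertices, 2240 tetrahedra), 100 seeded morphologies, 1000 random
  importance fields on an ~80-patch fixture, $10^5$ random Hermite
  segments — were chosen as the smallest sizes at which the properties are
  exercised across all code paths (bifurcations, caps, soma boundaries,
  mixed levels).

## Known limitations

* Tubes are always four-sided before refinement; very thick, closely spaced
  neurites can interpenetrate the soma or each other (the guarantees are
  topological, not collision-aware).
* The soma surface resolution is fixed by the initial icosphere; only
  neurite patches refine adaptively.
* The orientation-vector frame transport fails gracefully but not
  beautifully on >90° kinks between consecutive segments (rings may shear).
* Dendritic spines and 2D soma contours as deformation targets are out of
  scope.
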