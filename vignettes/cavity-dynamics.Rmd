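---
title: "Detecting and tracing molecular cavities with cavitrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracing molecular cavities with cavitrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavitrace)
```

## The model

Internal cavities and channels of a molecule are regions of empty space in
which a spherical probe — typically water-sized, radius $r_p = 1.4$ Å —
fits without touching any atom. cavitrace models the molecule as a set of
van der Waals spheres with centers $p_i$ and radii $r_i$ and works with the
*additively weighted Voronoi diagram* of those spheres, i.e. the partition
of space by the signed distance to the sphere surfaces,

$$ d_i(p) \;=\; \lVert p - p_i \rVert - r_i . $$

The region of atom $i$ is
$V_i = \{\,p \mid d_i(p) \le d_j(p)\ \forall j \ne i\,\}$. The vertices of
this diagram are centers of *empty spheres* tangent to four atoms; its
edges are loci of points equidistant (in the weighted sense) to three
atoms. Together the vertices and edges carry the complete topological
skeleton of the distance function — all local maxima of the clearance to
the van der Waals surface, all index-2 saddles, and the separatrices
connecting them. Every locally-widest path through the molecule therefore
runs along this vertex–edge graph, which is why cavitrace computes only
the graph and not the full diagram.

Per trajectory frame the pipeline is:

1. **Perturbation.** Atom centers are displaced by independent random
   vectors of length at most $\varepsilon = 10^{-6}$ Å so that no five
   spheres are tangent to one common empty sphere (a degenerate diagram).
   The displacement is orders of magnitude below atomic coordinate
   precision and irrelevant for the analysis; it exists purely to put the
   spheres in general position.
2. **Voronoi graph.** All vertices inside the frame's bounding box
   (expanded by a margin, default 5 Å) are found; edges are sampled as
   clearance-annotated polylines.
3. **Filtering.** An ambient-occlusion pass removes vertices lying outside
   the molecular domain; a probe pass removes everything with clearance
   below $r_p$.
4. **Path components and cavities.** The surviving graph splits into
   connected components; each component's cavity is approximated by the
   union of the empty tangent spheres at its vertices and along its edges.
5. **Volumes.** Cavity volumes and pairwise intersection volumes are
   estimated on a regular cube grid with side $a = 0.2$ Å.

Across frames, cavities of consecutive frames are connected into a *time
graph* whenever a probe can pass from one into the other; identities,
split/merge events, dynamic paths and residence-probability grids are
derived from that graph.

## Computing the graph

A Voronoi vertex satisfies $\lVert p - p_i\rVert = r_i + c$ for its four
generators, where $c$ is the clearance (the empty sphere's radius).
Subtracting these tangency equations pairwise gives three linear equations
in $(p, c)$; substituting the resulting affine family $p(c)$ back into one
tangency equation leaves a quadratic in $c$, so each 4-subset of spheres
contributes at most two candidate vertices, each accepted only if no other
sphere is weighted-closer than $c$ (the empty-sphere property). cavitrace
enumerates 4-subsets directly (in compiled code, pruned by the necessary
condition that two generators of a vertex with clearance $\le c_{\max}$
lie within $r_i + r_j + 2c_{\max}$ of each other). Direct enumeration
scales worse than edge tracing but is robust, exactly testable against
brute force, and entirely adequate for the structure sizes this package
targets (hundreds of atoms per frame; a 150-atom frame takes a few
seconds on one CPU).

Edges are conic arcs. For each generator triple shared by two vertices,
the connecting arc is sampled by recursive midpoint projection: the chord
midpoint is projected onto the equidistance locus by Gauss–Newton
iteration on the two constraints $d_1 = d_2$, $d_1 = d_3$, and refinement
continues until the chord sag falls below 0.05 Å and segments are at most
0.3 Å long (so clearance dips interior to an edge are resolved). Samples
must keep the empty-sphere property; arcs whose samples lose it are
discarded (the locus leaves the diagram there). Unbounded edges are traced
outward along the locus tangent and clipped at the expanded bounding box.

Numerical tolerances: the tangency system is solved exactly (Cramer's
rule plus the quadratic); vertices closer than $10^{-9}$ Å with equal
clearance are merged (adjacent 4-subsets of a nearly cospherical 5-tuple
produce the same empty sphere twice); true degeneracy — a fifth tangent
sphere within $10^{-12}$ — raises an error directing the user to
`perturb_positions()`. Incidental near-tangencies at the $10^{-7}$–
$10^{-10}$ scale are *generic* on structured inputs (millions of candidate
5-tuples make tiny minima inevitable) and are deliberately not treated as
degeneracies.

## Filtering

**Ambient occlusion.** Whether a vertex lies "inside" the molecule is
decided operationally: from the vertex, `n_rays` (default 256) directions
from a seeded, randomly rotated Fibonacci sphere lattice are cast, and the
escaping-ray fraction is the vertex's ambient light. Vertices receiving
more light than the threshold (default 0.15) are removed with their
incident edges. Buried vertices (clearance $\le 0$) receive no light by
definition. For *unbounded* edges the free, box-clipped end is also
occlusion-tested — such rays leave the molecular domain through the box
and would otherwise survive via their buried interior endpoint and
produce spurious exterior components. The threshold is exposed as a
parameter because any occlusion measure is only defined together with its
normalization; ours is the escaping-ray fraction under the fixed
direction set, which is deterministic for a given seed.

**Probe pass.** Vertices with clearance below $r_p$ are removed, and edge
polylines are truncated to maximal runs of samples with clearance
$\ge r_p$. A truncated arc end receives a terminal *pseudo-vertex* at the
interpolated crossing point, carrying clearance exactly $r_p$;
pseudo-vertices are flagged, excluded from occlusion testing, and serve
only as graph nodes. With $r_p = 0$ the pass is a no-op. Because the
clearance along an edge attains its interior minima at saddles, an edge
interior never exceeds the clearance of both endpoints, so truncation can
only shorten arcs, never disconnect a region of clearance above $r_p$
from its bounding vertices.

Components are numbered in descending order of clearance-weighted arc
length (ties by smallest vertex id) so cavity ids are reproducible
run-to-run.

## Cavities and the probe-continuity criterion

A cavity is approximated by the union of empty spheres at the component's
vertices plus spheres along its arcs. Sphere placement along an arc obeys
the *probe-continuity criterion*: for each pair of consecutive spheres,
the largest circle inscribed in their intersection must have radius at
least $r_p$, which guarantees the probe can roll from sphere to sphere
without leaving the union. Additional spheres are inserted at locus
midpoints (clearance recomputed from the generators, not interpolated —
this keeps every cavity sphere an exact empty tangent sphere) up to 12
levels.

The inscribed-circle primitive has three regimes for spheres at center
distance $d$:

* $d \ge r_1 + r_2$: disjoint, no circle;
* $d \le \sqrt{\lvert r_1^2 - r_2^2 \rvert}$: the smaller sphere's great
  disc fits inside the larger ball, radius $\min(r_1, r_2)$ — note this
  regime extends beyond strict containment $d \le \lvert r_1 - r_2\rvert$;
* otherwise the circle lies in the radical plane at offset
  $x = (d^2 + r_1^2 - r_2^2)/(2d)$ with radius $\sqrt{r_1^2 - x^2}$.

The middle regime matters: near arc-truncation points the spheres have
radii approaching $r_p$, and only the great-disc regime makes the
criterion attainable there. Even so, where the clearance dips to *exactly*
$r_p$ with vanishing slope the probe touches the cavity boundary
tangentially and no finite sphere set satisfies the exact criterion; the
criterion is therefore applied with a slack of $10^{-6}$ Å, which bounds
the probe's maximal protrusion from the sphere union.

## Volumes on the cube grid

Exact volumes of sphere unions are notoriously delicate; cavitrace uses
the simple, convergent estimate: a grid of cubes with side $a$ spans the
cavity's bounding box (centers at $\mathrm{origin} + (i + \tfrac12)a$),
and the volume is $a^3$ times the number of cube centers strictly inside
at least one sphere. "Strictly inside" makes ties measure-zero after
perturbation. The intersection volume of two cavities counts cube centers
inside at least one sphere of *each* cavity, on a grid restricted to and
anchored at the intersection of the two bounding boxes; the shared anchor
makes the result exactly symmetric and identical to the computation over
the full combined box (verified bitwise in the tests). Counting is
column-parallel in compiled code; counts are integers, so the result is
independent of summation order. At $a = 0.05$ Å the unit-sphere error is
below 1%; the default $a = 0.2$ Å balances accuracy against grid size for
routine volume tracking. The helper `water_capacity()` converts a volume
to a water count via the 30 Å³-per-molecule approximation.

## Tracing over time

Two cavities of consecutive frames *correspond* when some empty sphere of
one intersects some empty sphere of the other with an inscribed circle
strictly greater than $r_{ic}$ (default: equal to $r_p$) — exactly the
condition that the probe can cross between them without leaving their
intersection. Correspondence edges carry the maximal circle radius and
the grid intersection volume of the two cavities.

Identities propagate by greedy volume-sorted matching: per frame pair the
edges are sorted by intersection volume, largest first (ties broken by
ascending identity at $t$, then cavity id at $t+1$, a deterministic
completion of an otherwise ambiguous ordering); an edge whose endpoints
are both unmatched matches them, the matched cavity inherits its
partner's identity, and every unmatched cavity of $t+1$ receives a fresh
number — so identities are unique within a frame. First-frame cavities
are numbered consecutively in cavity order.

Optional passes: *dead-end removal* deletes cavities with no continuation
to the next frame and propagates the deletion backwards until a node with
another forward edge (a split) or the range start is reached; cavities
alive through the final frame are kept, since no later frame exists to
demand a continuation. *Forbid-splits* keeps only greedily matched
cavities (plus genuinely new, edge-less cavities, which start their own
chains), leaving one simple path per identity. Dynamic paths between
user-selected (frame, cavity) nodes are found by depth-first search
moving forward in time, preferring larger intersection volumes among
branches; the preference rule is a deterministic choice where several
modifications of plain DFS would be defensible.

## Timelines and residence probability

`split_merge_timeline()` exports one polyline per identity (per-frame row
index assigned top-to-bottom by identity — no crossing minimization is
attempted — and cavity volume as thickness) plus an explicit event table;
an event is recorded at the *later* frame of its transition, so a
schedule whose constriction first drops below $r_p$ at frame $k$ yields a
split at frame $k$. `evolution_profile()` projects each cavity onto a
user axis (for membrane proteins, the membrane normal) as the interval
$[\min_i(c_i \cdot u - r_i),\ \max_i(c_i \cdot u + r_i)]$ over the cavity
spheres. `residence_probability()` samples the union bounding box of all
frames on the same cube-center convention as the volume grids — so a
single-frame residence grid equals the occupancy grid exactly — and
stores, per cube, the fraction of frames whose cavity covers the cube
center; values are exact multiples of $1/T$. Grids are exported as
plain-text OpenDX for PyMOL/VMD/Chimera; rendering (isosurfaces, maximum
intensity projection) is left to those viewers, and
`stable_core_count()` reports the size of the largest 6-connected block
of cubes above a chosen threshold.

## The synthetic fixtures

Because every quantitative claim must be testable without external data,
the package generates toy systems whose ground truth follows from their
construction parameters, never from the algorithms under test:

* `make_tetra_cage(L, r)` — four spheres at tetrahedron vertices; the one
  interior Voronoi vertex sits at the centroid with clearance
  $L\sqrt{3/8} - r$ in closed form.
* `make_shell_pocket()` — a Fibonacci-lattice shell (default radius 6 Å,
  atom radius 1.5 Å, 120 atoms) with an optional circular mouth; the
  closed version is the cage on which the occlusion measure must return
  exactly zero, and its interior volume is approximately
  $\tfrac43\pi(R - r)^3$.
* `make_channel_tube()` — a staggered-ring tube (default length 14 Å)
  whose on-axis clearance equals the nominal bottleneck radius; it
  drifts laterally per frame to exercise tracing.
* `make_splitting_dumbbell()` — a closed capsule cage with a central
  constriction ring whose free radius follows a per-frame schedule; the
  scripted split (or, reversed, merge) frame is the first frame whose
  constriction is below the probe radius. The default schedule crosses
  $r_p = 1.4$ Å between frames 4 and 5.

All fixtures are deterministic (the Fibonacci lattice needs no RNG) and
regenerate bit-identically. They emulate the *geometry* of pockets,
channels and constrictions with a single atom radius per fixture; they do
not emulate realistic protein packing, element-dependent radii, thermal
noise, or any force field. Tests passing on them demonstrate geometric
and algorithmic correctness, not biological validity on real trajectories.

## Problem sizes and determinism

The shipped tests and the acceptance script run fixtures of 100–160 atoms
over up to 10 frames, random frames of 20 spheres for vertex
verification, and brute-force cross-checks at 6–8 spheres — sizes chosen
so the full suite completes in minutes on a single CPU while still
exercising every code path at meaningful scale. The dumbbell and channel
runs bound the generator search at the geometrically justified clearance
maximum of their cages (no interior empty sphere can exceed the cage
radius) and use a reduced bounding margin, which prunes exterior
candidates without affecting any interior result.

Determinism is end-to-end: perturbation seeds derive from the run seed
and the frame's time index, occlusion directions from the run seed, all
orderings are explicitly tied-broken, and two identically-seeded pipeline
runs produce byte-identical outputs (asserted in the tests).

## Known limitations

* Vertex enumeration is $O(n^4)$ (pruned); frames beyond a few hundred
  atoms call for the edge-tracing algorithm, which this package does not
  implement.
* The ambient-occlusion normalization is this package's own operational
  definition; thresholds tuned for other implementations need not
  transfer.
* Edge arcs whose locus leaves and re-enters the diagram between two
  vertices are truncated rather than split around the excluded span; on
  the fixture geometries this changes nothing that the validity checks
  would catch, but exotic configurations may lose sub-arcs.
* Cavity volumes inherit the $O(a)$ bias of cube counting near surfaces;
  halve $a$ when comparing cavities whose volumes differ by a few
  percent.
* The time graph connects only *consecutive* frames; a cavity vanishing
  for one frame and reappearing is two identities.
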