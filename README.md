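# cavitrace

Internal cavities and channels of proteins are dynamic: they open, close,
split, merge, and occasionally connect into transient channels, and these
changes are coupled to the conformational motions that make transporters
and pumps work. `cavitrace` detects such cavities per trajectory frame
from exact geometry — the additively weighted Voronoi diagram of the van
der Waals spheres — and traces them through time, producing volumes,
split/merge timelines, dynamic paths, and residence-probability grids.
It is aimed at structural bioinformaticians who want a scriptable,
deterministic cavity-dynamics analysis with quantitative guarantees,
on moderate structure sizes (hundreds of atoms per frame).

## Method in brief

For atoms with centers $p_i$ and van der Waals radii $r_i$, space is
partitioned by the weighted distance $d_i(p) = \lVert p - p_i\rVert - r_i$.
The vertices of the resulting Voronoi diagram of spheres are centers of
empty spheres tangent to four atoms; the edges are loci equidistant to
three. This vertex–edge graph contains every locally-widest path through
the molecule (all maxima, index-2 saddles and separatrices of the
clearance function). Per frame, `cavitrace`:

1. perturbs atom positions by ≤ 1e-6 Å to break degeneracies;
2. computes the Voronoi vertex–edge graph (compiled 4-subset enumeration
   with exact tangency algebra);
3. filters it — an ambient-occlusion pass removes vertices outside the
   molecular domain (escaping-ray fraction above a threshold, default
   15%), a probe pass removes everything with clearance below the probe
   radius $r_p$ (default 1.4 Å, a water-sized probe);
4. splits the survivors into path components and approximates each
   component's cavity as a union of empty tangent spheres, placed so a
   probe can roll along every path (consecutive spheres intersect with an
   inscribed circle ≥ $r_p$);
5. measures cavity volumes on a cube grid (side $a$ = 0.2 Å by default;
   the count of cube centers inside the union times $a^3$).

Across frames, cavities are connected whenever spheres of consecutive
frames intersect with an inscribed circle larger than $r_{ic}$ (default
$= r_p$); identities propagate by greedy matching sorted by intersection
volume; dead ends and splits can be pruned; and residence probability —
the fraction of frames in which a point lies inside the cavity — is
exported as an OpenDX grid.

## Worked example

A closed spherical cage of 120 atoms (shell radius 6 Å, atom radius
1.5 Å) encloses a single cavity of interior radius 4.5 Å:

```r
library(cavitrace)

fr <- make_shell_pocket(6, 1.5, 120, mouth_angle = 0)
pf <- perturb_positions(fr, 1e-6, seed = 7)
g  <- compute_voronoi_graph(pf, max_clearance = 6)
g
#> <cav_voronoi_graph> frame 0: 326 vertices, 771 edges

ambient_light_fraction(c(0, 0, 0), pf)   # cage center is fully dark
#> [1] 0

fg    <- filter_graph(g, pf, filter_params(probe_radius = 1.4,
                                           occlusion_threshold = 0.15))
comps <- connected_components(fg)
cavs  <- build_cavities(comps, fg, pf, r_p = 1.4)
cavs[[1]]
#> <cav_cavity> frame 0 id 1: 252 spheres

cavity_volume(cavs[[1]], a = 0.2)        # analytic interior: 4/3*pi*4.5^3 = 381.70
#> [1] 382.664

water_capacity(cavity_volume(cavs[[1]], a = 0.2))
#> [1] 12
```

The cavity volume lands within 0.3% of the analytic interior volume, and
the capacity estimate says about a dozen water molecules would fit.

Tracing a 10-frame dumbbell whose central constriction narrows below the
probe radius between frames 4 and 5:

```r
db    <- make_splitting_dumbbell(capsule_radius = 3.5, capsule_half_length = 3.5)
cfg   <- run_config(output_dir = "db-out", seed = 11,
                    max_clearance = 4, bounding_margin = 2.5)
store <- run_preprocess(cfg, db$trajectory)
tg    <- run_trace(cfg, store)
read.csv(file.path(cfg$output_dir, "events.csv"))
#>   frame  type parents children
#> 1     5 split       1      1,2
```

One cavity (identity 1) persists through frame 4, then splits into two
(identities 1 and 2) exactly at the scripted frame; `volumes.csv` tracks
each identity's volume and water capacity per frame, `timeline.csv` and
`evolution.csv` feed timeline plots, and `time_graph.graphml` holds the
full time graph.

A command-line front end with the same functionality is installed at
`system.file("cli", "cavitrace.R", package = "cavitrace")`, with
subcommands `fixtures`, `preprocess`, `trace`, `volumes`, `timeline`,
`residence`.

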