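Package: cavitrace
Title: Voronoi-Based Detection and Temporal Tracing of Molecular Cavities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects internal cavities and channels of molecules from the
    additively weighted Voronoi diagram of their van der Waals spheres and
    follows those cavities through molecular dynamics trajectories. Per
    frame, the Voronoi vertex-edge graph is computed, filtered by a probe
    radius and an ambient-occlusion criterion, and decomposed into path
    components whose cavities are approximated by unions of empty tangent
    spheres. Cavity volumes and pairwise intersection volumes are estimated
    on a regular cube grid. Across frames, cavities are connected into a
    time graph by an inscribed-intersection-circle criterion, identities are
    assigned by greedy volume-sorted matching, and split/merge timelines,
    dynamic paths, and residence-probability grids are derived and exported
    in plain-text formats (CSV, JSON, GraphML, OpenDX).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
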