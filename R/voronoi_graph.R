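#' Weighted (additively weighted Voronoi) distance to a sphere
#'
#' The distance underlying the Voronoi diagram of spheres: the Euclidean
#' distance from a point to the sphere center minus the sphere radius. It is
#' negative inside the sphere and zero on its surface.
#'
#' @param p Numeric 3-vector (a point) or an m x 3 matrix of points.
#' @param centers Numeric 3-vector (one sphere center) or an n x 3 matrix.
#' @param radii Numeric vector of sphere radii.
#' @return For a single point and sphere, a scalar; in general an m x n
#'   matrix of weighted distances.
#' @export
weighted_distance <- function(p, centers, radii) {
  P <- if (is.matrix(p)) p else matrix(p, ncol = 3L)
  C <- if (is.matrix(centers)) centers else matrix(centers, ncol = 3L)
  d2 <- outer(rowSums(P^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(P)), rowSums(C^2)) - 2 * tcrossprod(P, C)
  d2[d2 < 0] <- 0
  out <- sqrt(d2) - rep(radii, each = nrow(P))
  if (!is.matrix(p) && !is.matrix(centers)) out[1, 1] else out
}

# Gauss-Newton projection of points onto the locus equidistant (weighted)
# to three spheres. P: m x 3 starting points; gc: 3 x 3 generator centers;
# gr: their radii. Returns positions, clearances, convergence flags.
project_to_locus <- function(P, gc, gr, tol = 1e-12, max_iter = 60L) {
  P <- matrix(P, ncol = 3L)
  m <- nrow(P)
  conv <- rep(FALSE, m)
  for (it in seq_len(max_iter)) {
    D1 <- P - matrix(gc[1, ], m, 3L, byrow = TRUE)
    D2 <- P - matrix(gc[2, ], m, 3L, byrow = TRUE)
    D3 <- P - matrix(gc[3, ], m, 3L, byrow = TRUE)
    n1 <- sqrt(rowSums(D1^2)); n2 <- sqrt(rowSums(D2^2)); n3 <- sqrt(rowSums(D3^2))
    bad <- n1 < 1e-12 | n2 < 1e-12 | n3 < 1e-12
    n1[bad] <- 1; n2[bad] <- 1; n3[bad] <- 1
    F1 <- (n1 - gr[1]) - (n2 - gr[2])
    F2 <- (n1 - gr[1]) - (n3 - gr[3])
    res <- pmax(abs(F1), abs(F2))
    conv <- res < tol & !bad
    if (all(conv)) break
    U1 <- D1 / n1; U2 <- D2 / n2; U3 <- D3 / n3
    J1 <- U1 - U2          # gradient of F1
    J2 <- U1 - U3          # gradient of F2
    a <- rowSums(J1^2); b <- rowSums(J1 * J2); cc <- rowSums(J2^2)
    det <- a * cc - b^2
    sing <- det < 1e-14
    det[sing] <- 1
    l1 <- (cc * F1 - b * F2) / det
    l2 <- (a * F2 - b * F1) / det
    l1[sing | conv] <- 0; l2[sing | conv] <- 0
    P <- P - (J1 * l1 + J2 * l2)
  }
  D1 <- P - matrix(gc[1, ], m, 3L, byrow = TRUE)
  D2 <- P - matrix(gc[2, ], m, 3L, byrow = TRUE)
  D3 <- P - matrix(gc[3, ], m, 3L, byrow = TRUE)
  cl <- (sqrt(rowSums(D1^2)) - gr[1] + sqrt(rowSums(D2^2)) - gr[2] +
           sqrt(rowSums(D3^2)) - gr[3]) / 3
  list(position = P, clearance = cl, converged = conv)
}

# unit tangent of the locus at a point: orthogonal to both constraint
# gradients
locus_tangent <- function(p, gc, gr) {
  u <- sweep(-gc, 2, -p)            # rows p - gc_i
  u <- u / sqrt(rowSums(u^2))
  j1 <- u[1, ] - u[2, ]
  j2 <- u[1, ] - u[3, ]
  t <- c(j1[2] * j2[3] - j1[3] * j2[2],
         j1[3] * j2[1] - j1[1] * j2[3],
         j1[1] * j2[2] - j1[2] * j2[1])
  n <- sqrt(sum(t^2))
  if (n < 1e-12) return(NULL)
  t / n
}

# minimum weighted distance to all spheres except the three generators
min_nongen_wdist <- function(P, centers, radii, gens) {
  others <- setdiff(seq_len(nrow(centers)), gens)
  if (!length(others)) return(rep(Inf, nrow(matrix(P, ncol = 3L))))
  wd <- weighted_distance(matrix(P, ncol = 3L), centers[others, , drop = FALSE],
                          radii[others])
  apply(wd, 1L, min)
}

#' Compute the Voronoi vertex-edge graph of a frame
#'
#' Computes all vertices (empty spheres tangent to four atoms) of the
#' additively weighted Voronoi diagram that lie inside the frame's bounding
#' box expanded by `bounding_margin`, and the Voronoi edges (equidistant
#' loci over three atoms) connecting them, sampled as clearance-annotated
#' polylines. This graph carries all locally-widest paths through the
#' molecule: its vertices are the maxima of the distance-to-surface
#' function, its edges the connecting separatrices.
#'
#' Spheres entirely contained in another sphere have an empty Voronoi region
#' and are dropped (with a message) before computation. Unbounded edges are
#' clipped at the expanded bounding box.
#'
#' @param frame A [sphere_frame()] with at least 4 spheres, assumed to be in
#'   general position (apply [perturb_positions()] first for symmetric or
#'   degenerate inputs).
#' @param bounding_margin Expansion of the frame bounding box in Angstrom.
#' @param max_clearance Optional upper bound on vertex clearance, used to
#'   prune the generator search; `Inf` scans exhaustively.
#' @param chord_sag Maximum chord-to-curve deviation of edge polylines (A).
#' @param max_seg Maximum polyline segment length (A), so clearance dips
#'   interior to an edge are resolved.
#' @param empty_tol Tolerance of the empty-sphere test (A).
#' @return An object of class `cav_voronoi_graph` with `vertices` (data
#'   frame: id, x, y, z, clearance, pseudo), `generators` (V x 4 matrix of
#'   sphere indices), `edges` (list of records with `gens`, `v1`, `v2`,
#'   `samples`), the frame index and the expanded box.
#' @export
compute_voronoi_graph <- function(frame, bounding_margin = 5,
                                  max_clearance = Inf, chord_sag = 0.05,
                                  max_seg = 0.3, empty_tol = 1e-9) {
  centers <- frame$centers
  radii <- frame$radii
  n <- nrow(centers)
  if (n < 4L) stop("at least 4 spheres are required for Voronoi vertices")

  # drop spheres entirely contained in another (empty Voronoi region)
  dmat <- as.matrix(stats::dist(centers))
  contained <- vapply(seq_len(n), function(i)
    any(dmat[i, -i] + radii[i] <= radii[-i] + 1e-12), logical(1))
  if (any(contained))
    message(sprintf("dropping %d sphere(s) contained in another sphere: %s",
                    sum(contained), paste(which(contained), collapse = ", ")))
  keep <- which(!contained)
  if (length(keep) < 4L) stop("fewer than 4 non-contained spheres")

  lo <- apply(centers - radii, 2L, min) - bounding_margin
  hi <- apply(centers + radii, 2L, max) + bounding_margin

  vres <- cpp_aw_voronoi_vertices(centers[keep, , drop = FALSE], radii[keep],
                                  lo, hi, max_clearance, empty_tol, 1e-12)
  if (isTRUE(vres$degenerate))
    stop("degenerate sphere configuration (five or more spheres tangent to ",
         "one empty sphere); apply perturb_positions() and retry")
  nv <- nrow(vres$position)
  gens <- matrix(keep[vres$generators], ncol = 4L)   # original indices
  vertices <- data.frame(id = seq_len(nv),
                         x = vres$position[, 1], y = vres$position[, 2],
                         z = vres$position[, 3],
                         clearance = as.numeric(vres$clearance),
                         pseudo = rep(FALSE, nv))
  graph <- structure(list(vertices = vertices, generators = gens,
                          edges = list(), frame_index = frame$time_index,
                          box_lo = lo, box_hi = hi,
                          dropped_spheres = which(contained)),
                     class = "cav_voronoi_graph")
  if (nv == 0L) return(graph)
  graph$edges <- trace_all_edges(vertices, gens, centers, radii, lo, hi,
                                 chord_sag, max_seg, empty_tol)
  graph
}

#' @export
print.cav_voronoi_graph <- function(x, ...) {
  cat(sprintf("<cav_voronoi_graph> frame %d: %d vertices, %d edges\n",
              x$frame_index, nrow(x$vertices), length(x$edges)))
  invisible(x)
}

# ---- edge construction -----------------------------------------------------

trace_all_edges <- function(vertices, gens, centers, radii, lo, hi,
                            chord_sag, max_seg, empty_tol) {
  nv <- nrow(vertices)
  pos <- as.matrix(vertices[, c("x", "y", "z")])
  # every vertex contributes 4 generator triples (its 4 incident edge stubs)
  combs <- utils::combn(4L, 3L)
  keys <- character(0); vids <- integer(0)
  for (ci in seq_len(ncol(combs))) {
    tg <- matrix(gens[, combs[, ci]], ncol = 3L)
    tg <- t(apply(tg, 1L, sort))
    keys <- c(keys, paste(tg[, 1], tg[, 2], tg[, 3], sep = "-"))
    vids <- c(vids, seq_len(nv))
  }
  by_triple <- split(seq_along(keys), keys)
  edges <- list()
  consumed <- rep(FALSE, length(keys))
  for (tk in names(by_triple)) {
    inc <- by_triple[[tk]]
    g3 <- as.integer(strsplit(tk, "-", fixed = TRUE)[[1]])
    gc <- centers[g3, , drop = FALSE]
    gr <- radii[g3]
    vs <- unique(vids[inc])
    if (length(vs) >= 2L) {
      # order the incident vertices along the locus and try consecutive pairs
      dirm <- pos[vs[which.max(
        as.matrix(stats::dist(pos[vs, , drop = FALSE]))[1, ])], ] - pos[vs[1], ]
      ord <- vs[order(as.vector(pos[vs, , drop = FALSE] %*% dirm))]
      for (q in seq_len(length(ord) - 1L)) {
        va <- ord[q]; vb <- ord[q + 1L]
        samp <- refine_edge_samples(pos[va, ], pos[vb, ], gc, gr,
                                    chord_sag, max_seg)
        if (is.null(samp)) next
        ok <- validate_edge_samples(samp, centers, radii, g3, empty_tol)
        if (!ok) next
        edges[[length(edges) + 1L]] <-
          list(gens = g3, v1 = va, v2 = vb, samples = samp)
        consumed[inc[vids[inc] %in% c(va, vb)]] <- TRUE
      }
    }
    # unconsumed stubs become rays: clipped at the box, or snapped onto a
    # partner vertex of the same triple when the locus (e.g. the second
    # branch of a hyperbolic conic) reaches one
    for (ii in inc[!consumed[inc]]) {
      if (consumed[ii]) next
      v <- vids[ii]
      others <- setdiff(vs, v)
      cand <- if (length(others))
        list(ids = others, pos = pos[others, , drop = FALSE],
             clearance = vertices$clearance[others])
      else NULL
      ray <- trace_unbounded_edge(pos[v, ], vertices$clearance[v], gc, gr,
                                  centers, radii, g3, lo, hi, empty_tol,
                                  candidates = cand)
      consumed[ii] <- TRUE
      if (is.null(ray)) next
      v2 <- ray$v2
      edges[[length(edges) + 1L]] <-
        list(gens = g3, v1 = v, v2 = v2, samples = ray$samples)
      if (!is.na(v2))
        consumed[inc[vids[inc] == v2]] <- TRUE
    }
  }
  edges
}

# adaptive polyline between two vertex positions on the locus of a triple;
# returns an m x 4 matrix (x, y, z, clearance) or NULL on failure
refine_edge_samples <- function(pa, pb, gc, gr, chord_sag, max_seg,
                                max_depth = 12L) {
  P <- rbind(pa, pb)
  cl <- project_to_locus(P, gc, gr)$clearance
  for (depth in seq_len(max_depth)) {
    m <- nrow(P)
    seg <- P[-1L, , drop = FALSE] - P[-m, , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    mid <- (P[-1L, , drop = FALSE] + P[-m, , drop = FALSE]) / 2
    pr <- project_to_locus(mid, gc, gr)
    if (any(!pr$converged)) return(NULL)
    sag <- sqrt(rowSums((pr$position - mid)^2))
    need <- sag > chord_sag | len > max_seg
    if (!any(need)) break
    newP <- matrix(0, m + sum(need), 3L)
    newC <- numeric(m + sum(need))
    j <- 1L
    for (i in seq_len(m - 1L)) {
      newP[j, ] <- P[i, ]; newC[j] <- cl[i]; j <- j + 1L
      if (need[i]) {
        newP[j, ] <- pr$position[i, ]; newC[j] <- pr$clearance[i]; j <- j + 1L
      }
    }
    newP[j, ] <- P[m, ]; newC[j] <- cl[m]
    P <- newP; cl <- newC
  }
  cbind(P, cl, deparse.level = 0)
}

# an edge polyline is genuine only if every sample keeps the empty-sphere
# property with respect to all non-generator spheres
validate_edge_samples <- function(samples, centers, radii, g3, empty_tol) {
  mng <- min_nongen_wdist(samples[, 1:3, drop = FALSE], centers, radii, g3)
  all(mng >= samples[, 4] - 1e-6)
}

# follow the locus outward from a vertex until the expanded box is
# reached, the empty-sphere property fails (a fourth sphere ties — i.e.
# another vertex; snap onto it when it is known), or step count runs out
trace_unbounded_edge <- function(p0, c0, gc, gr, centers, radii, g3, lo, hi,
                                 empty_tol, step = 0.3, max_steps = 3000L,
                                 candidates = NULL) {
  tang <- locus_tangent(p0, gc, gr)
  if (is.null(tang)) return(NULL)
  margin <- function(P, cl) min_nongen_wdist(P, centers, radii, g3) - cl
  finish <- function(samples, v2 = NA_integer_) {
    if (nrow(samples) < 2L) NULL else list(samples = samples, v2 = v2)
  }
  for (sgn in c(1, -1)) {
    d <- sgn * tang
    pr <- project_to_locus(matrix(p0 + 1e-3 * d, 1L), gc, gr)
    if (!pr$converged) next
    if (margin(pr$position, pr$clearance) < -1e-6) next
    # march with adaptive step: near locus folds (tight curvature) the
    # projection of a full step collapses back onto the current point, so
    # halve the step until real progress is made
    samples <- rbind(c(p0, c0))
    pcur <- p0; dcur <- d; h <- step
    for (s in seq_len(max_steps)) {
      pr <- NULL
      repeat {
        cand <- project_to_locus(matrix(pcur + h * dcur, 1L), gc, gr)
        if (cand$converged &&
            sqrt(sum((cand$position[1, ] - pcur)^2)) > h / 4) {
          pr <- cand
          break
        }
        h <- h / 2
        if (h < 1e-4) break
      }
      if (is.null(pr)) break
      pn <- pr$position[1, ]
      if (margin(pr$position, pr$clearance) < -1e-6) {
        # a non-generator sphere became weighted-closer: the locus has
        # reached another Voronoi vertex of this triple
        hit <- snap_to_vertex(pcur, pn, gc, gr, centers, radii, g3,
                              candidates)
        if (!is.null(hit)) {
          samples <- rbind(samples, c(hit$pos, hit$clearance))
          return(finish(samples, hit$id))
        }
        break
      }
      if (any(pn < lo) || any(pn > hi)) {
        clip <- clip_to_box(pcur, pn, gc, gr, lo, hi)
        if (!is.null(clip)) samples <- rbind(samples, clip)
        return(finish(samples))
      }
      dn <- pn - pcur
      nl <- sqrt(sum(dn^2))
      if (nl < 1e-9) break
      samples <- rbind(samples, c(pn, pr$clearance[1]))
      dcur <- dn / nl
      pcur <- pn
      h <- min(step, 2 * h)
    }
    return(finish(samples))
  }
  NULL
}

# bisect along the locus between a valid and an emptiness-violating point
# for the zero of the non-generator margin; identify it with a known
# vertex of the same triple when one lies within tolerance
snap_to_vertex <- function(p_ok, p_bad, gc, gr, centers, radii, g3,
                           candidates, iters = 50L) {
  if (is.null(candidates)) return(NULL)
  a <- p_ok; b <- p_bad
  for (i in seq_len(iters)) {
    pr <- project_to_locus(matrix((a + b) / 2, 1L), gc, gr)
    if (!pr$converged) return(NULL)
    pm <- pr$position[1, ]
    mg <- min_nongen_wdist(pm, centers, radii, g3) - pr$clearance[1]
    if (mg < 0) b <- pm else a <- pm
    if (sqrt(sum((a - b)^2)) < 1e-10) break
  }
  pr <- project_to_locus(matrix(a, 1L), gc, gr)
  pb <- pr$position[1, ]
  d2 <- rowSums(sweep(candidates$pos, 2L, pb)^2)
  j <- which.min(d2)
  if (d2[j] < 1e-12)
    list(id = candidates$ids[j], pos = candidates$pos[j, ],
         clearance = candidates$clearance[j])
  else NULL
}

# bisect along the locus between an inside and an outside point to land on
# the box boundary
clip_to_box <- function(p_in, p_out, gc, gr, lo, hi, iters = 40L) {
  a <- p_in; b <- p_out
  for (i in seq_len(iters)) {
    mid <- project_to_locus(matrix((a + b) / 2, 1L), gc, gr)
    if (!mid$converged) return(NULL)
    pm <- mid$position[1, ]
    if (any(pm < lo) || any(pm > hi)) b <- pm else a <- pm
  }
  pr <- project_to_locus(matrix(a, 1L), gc, gr)
  c(pr$position[1, ], pr$clearance[1])
}

# ---- verification ----------------------------------------------------------

#' Verify the defining invariants of a Voronoi vertex
#'
#' Checks by direct evaluation of [weighted_distance()] that (1) the vertex
#' is weighted-equidistant (at its stated clearance) to its four generator
#' spheres and (2) no other sphere is weighted-closer (the empty-sphere
#' property).
#'
#' @param vertex A list with `position` (3-vector), `clearance` (scalar) and
#'   `generators` (4 sphere indices), or a row id of a graph's vertex table
#'   together with the graph via `graph`.
#' @param frame The [sphere_frame()] the vertex was computed from.
#' @param tol Tolerance in Angstrom.
#' @return A list with `pass` (logical), `tangency_residuals` (4 values),
#'   and `empty_margin` (min over non-generators of weighted distance minus
#'   clearance; >= -tol to pass).
#' @export
verify_vertex <- function(vertex, frame, tol = 1e-6) {
  wd <- weighted_distance(vertex$position, frame$centers, frame$radii)
  wd <- as.numeric(wd)
  tang <- wd[vertex$generators] - vertex$clearance
  others <- setdiff(seq_along(wd), vertex$generators)
  margin <- if (length(others)) min(wd[others]) - vertex$clearance else Inf
  list(pass = all(abs(tang) <= tol) && margin >= -tol,
       tangency_residuals = tang, empty_margin = margin)
}

#' @rdname verify_vertex
#' @param graph A `cav_voronoi_graph`.
#' @param id Vertex id within the graph.
#' @export
graph_vertex <- function(graph, id) {
  list(position = as.numeric(graph$vertices[id, c("x", "y", "z")]),
       clearance = graph$vertices$clearance[id],
       generators = graph$generators[id, ])
}

# ---- export ----------------------------------------------------------------

#' Export a Voronoi graph
#'
#' `export_voronoi_json()` writes vertices (position, clearance, generators)
#' and edges (generators, endpoint ids, sample polylines) as JSON;
#' `export_voronoi_graphml()` writes the vertex-edge connectivity (without
#' polylines) as GraphML.
#'
#' @param graph A `cav_voronoi_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_voronoi_json <- function(graph, path) {
  obj <- list(
    frame_index = graph$frame_index,
    box = list(lo = graph$box_lo, hi = graph$box_hi),
    vertices = lapply(seq_len(nrow(graph$vertices)), function(i)
      list(id = graph$vertices$id[i],
           position = as.numeric(graph$vertices[i, c("x", "y", "z")]),
           clearance = graph$vertices$clearance[i],
           generators = as.integer(graph$generators[i, ]),
           pseudo = graph$vertices$pseudo[i])),
    edges = lapply(graph$edges, function(e)
      list(generators = e$gens, v1 = e$v1, v2 = e$v2,
           samples = unname(e$samples))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname export_voronoi_json
#' @export
export_voronoi_graphml <- function(graph, path) {
  ig <- graph_to_igraph(graph)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

graph_to_igraph <- function(graph) {
  vt <- graph$vertices
  bounded <- Filter(function(e) !is.na(e$v1) && !is.na(e$v2), graph$edges)
  el <- if (length(bounded))
    do.call(rbind, lapply(bounded, function(e) c(e$v1, e$v2)))
  else matrix(integer(0), ncol = 2L)
  ig <- igraph::make_empty_graph(n = nrow(vt), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = as.character(vt$id))
  ig <- igraph::set_vertex_attr(ig, "clearance", value = vt$clearance)
  if (nrow(el))
    ig <- igraph::add_edges(ig, t(matrix(match(el, vt$id), ncol = 2L)))
  ig
}
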