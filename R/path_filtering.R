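#' Filtering parameters for static molecular paths
#'
#' Bundles the parameters of the two-stage filter that turns the raw
#' Voronoi graph into static molecular paths: the probe radius (a sphere
#' representing the solvent or substrate that must fit along a path) and
#' the ambient-occlusion threshold separating interior from exterior
#' vertices.
#'
#' @param probe_radius Probe sphere radius r_p in Angstrom (>= 0). The
#'   default 1.4 A approximates a water molecule.
#' @param occlusion_threshold Fraction in \[0, 1\]: vertices receiving more
#'   ambient light than this are considered outside the molecule and
#'   removed. Default 0.15.
#' @param n_rays Number of ray directions of the occlusion estimate
#'   (>= 32).
#' @param seed Integer seed fixing the ray direction set.
#' @return An object of class `cav_filter_params`.
#' @export
filter_params <- function(probe_radius = 1.4, occlusion_threshold = 0.15,
                          n_rays = 256L, seed = 1L) {
  if (probe_radius < 0) stop("`probe_radius` must be >= 0")
  if (occlusion_threshold < 0 || occlusion_threshold > 1)
    stop("`occlusion_threshold` must lie in [0, 1]")
  if (n_rays < 32L) stop("`n_rays` must be >= 32")
  structure(list(probe_radius = probe_radius,
                 occlusion_threshold = occlusion_threshold,
                 n_rays = as.integer(n_rays), seed = as.integer(seed)),
            class = "cav_filter_params")
}

# deterministic low-discrepancy direction set: Fibonacci sphere lattice
# rotated by a seed-derived random rotation
ray_directions <- function(n, seed = 1L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  D <- cbind(rho * cos(phi), rho * sin(phi), z)
  q <- with_local_seed(seed, stats::rnorm(4L))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; zz <- q[4]
  R <- rbind(c(1 - 2 * (y^2 + zz^2), 2 * (x * y - w * zz), 2 * (x * zz + w * y)),
             c(2 * (x * y + w * zz), 1 - 2 * (x^2 + zz^2), 2 * (y * zz - w * x)),
             c(2 * (x * zz - w * y), 2 * (y * zz + w * x), 1 - 2 * (x^2 + y^2)))
  D %*% t(R)
}

#' Fraction of ambient light reaching a point
#'
#' Operational ambient-occlusion measure: casts a deterministic
#' low-discrepancy set of ray directions from `p` and returns the fraction
#' of rays that escape to infinity without hitting any atom sphere. Points
#' deep inside the molecule receive little light; points outside receive
#' most of it.
#'
#' @param p Numeric 3-vector, not inside any atom sphere.
#' @param frame A [sphere_frame()].
#' @param n_rays Number of ray directions.
#' @param seed Integer seed fixing the direction set.
#' @return Escaping-ray fraction in \[0, 1\].
#' @export
ambient_light_fraction <- function(p, frame, n_rays = 256L, seed = 1L) {
  centers <- frame$centers
  radii <- frame$radii
  if (nrow(centers)) {
    dp <- sweep(centers, 2L, p)
    if (any(rowSums(dp^2) < radii^2))
      stop("`p` lies inside an atom sphere")
  } else {
    return(1.0)
  }
  D <- ray_directions(n_rays, seed)
  # ray p + t d hits sphere (c, r) at t > 0 iff the discriminant is
  # positive and the sphere lies ahead of the origin
  Cp <- sweep(centers, 2L, p)             # centers - p, n x 3
  B <- tcrossprod(D, Cp)                  # n_rays x n
  c2 <- rowSums(Cp^2)
  # squared perpendicular distance from the ray line is c2 - B^2; the ray
  # (t > 0) hits iff r^2 - (c2 - B^2) > 0 and the center lies ahead
  disc <- sweep(B^2, 2L, c2) + matrix(radii^2, nrow(D), length(radii),
                                      byrow = TRUE)
  hit <- disc > 0 & B > 0
  mean(rowSums(hit) == 0L)
}

#' Filter a Voronoi graph down to the static molecular paths
#'
#' Two passes, in order: (1) the occlusion pass removes every vertex whose
#' [ambient_light_fraction()] exceeds the threshold, together with its
#' incident edges (vertices outside the domain of the molecule); (2) the
#' probe pass removes every vertex with clearance below the probe radius
#' and truncates edge polylines to maximal sub-polylines whose samples all
#' have clearance at least r_p. A truncated arc end not bounded by a
#' retained vertex receives a terminal pseudo-vertex at the crossing point,
#' carrying clearance exactly r_p; pseudo-vertices are flagged and excluded
#' from occlusion testing. Buried vertices (clearance <= 0) trivially
#' receive no light.
#'
#' @param graph A `cav_voronoi_graph` computed on `frame`.
#' @param frame The same [sphere_frame()].
#' @param params A [filter_params()].
#' @return A filtered `cav_voronoi_graph`; retained arcs keep a reference
#'   to their originating edge via `edge_id`.
#' @export
filter_graph <- function(graph, frame, params = filter_params()) {
  vt <- graph$vertices
  nv <- nrow(vt)
  rp <- params$probe_radius

  # ---- occlusion pass (vertices only) ----
  light <- numeric(nv)
  for (i in seq_len(nv)) {
    light[i] <- if (vt$clearance[i] <= 0) 0 else
      ambient_light_fraction(as.numeric(vt[i, c("x", "y", "z")]), frame,
                             params$n_rays, params$seed)
  }
  occl_keep <- light <= params$occlusion_threshold
  edges <- list()
  for (ei in seq_along(graph$edges)) {
    e <- graph$edges[[ei]]
    ends <- c(e$v1, e$v2)
    ends <- ends[!is.na(ends)]
    if (!all(occl_keep[ends])) next
    if (is.na(e$v2)) {
      # unbounded edge: its free end (clipped at the box) must itself pass
      # the occlusion test, otherwise the ray leaves the molecular domain
      last <- e$samples[nrow(e$samples), ]
      end_light <- if (last[4] <= 0) 0 else
        ambient_light_fraction(last[1:3], frame, params$n_rays, params$seed)
      if (end_light > params$occlusion_threshold) next
    }
    e$edge_id <- ei
    edges[[length(edges) + 1L]] <- e
  }

  # ---- probe pass ----
  if (rp <= 0) {
    # a zero-radius probe removes nothing; keep the occlusion survivors
    res <- graph
    res$vertices <- vt[occl_keep, , drop = FALSE]
    res$generators <- graph$generators[occl_keep, , drop = FALSE]
    res$edges <- edges
    res$filter_params <- params
    return(res)
  }
  new_vt <- vt[occl_keep & vt$clearance >= rp, , drop = FALSE]
  new_gens <- graph$generators[occl_keep & vt$clearance >= rp, , drop = FALSE]
  kept_ids <- new_vt$id
  next_id <- if (nv) max(vt$id) + 1L else 1L
  out_edges <- list()
  for (e in edges) {
    s <- e$samples
    ok <- s[, 4] >= rp
    if (!any(ok)) next
    runs <- rle(ok)
    ends_run <- cumsum(runs$lengths)
    starts_run <- ends_run - runs$lengths + 1L
    for (ri in which(runs$values)) {
      i0 <- starts_run[ri]; i1 <- ends_run[ri]
      sub <- s[i0:i1, , drop = FALSE]
      a_id <- if (i0 == 1L && !is.na(e$v1) && e$v1 %in% kept_ids) e$v1 else NA
      b_id <- if (i1 == nrow(s) && !is.na(e$v2) && e$v2 %in% kept_ids) e$v2 else NA
      gc <- frame$centers[e$gens, , drop = FALSE]
      gr <- frame$radii[e$gens]
      if (is.na(a_id)) {
        if (i0 > 1L) {   # interpolate the r_p crossing on the lower side
          cross <- probe_crossing(s[i0 - 1L, ], s[i0, ], gc, gr, rp)
          sub <- rbind(cross, sub)
        }
        new_vt <- rbind(new_vt, data.frame(id = next_id, x = sub[1, 1],
                                           y = sub[1, 2], z = sub[1, 3],
                                           clearance = rp, pseudo = TRUE))
        new_gens <- rbind(new_gens, c(e$gens, NA))
        sub[1, 4] <- rp
        a_id <- next_id; next_id <- next_id + 1L
      }
      if (is.na(b_id)) {
        if (i1 < nrow(s)) {
          cross <- probe_crossing(s[i1 + 1L, ], s[i1, ], gc, gr, rp)
          sub <- rbind(sub, cross)
          sub[nrow(sub), 4] <- rp
          cl_new <- rp
        } else {
          cl_new <- sub[nrow(sub), 4]   # clipped/unbounded end keeps its clearance
        }
        new_vt <- rbind(new_vt, data.frame(id = next_id,
                                           x = sub[nrow(sub), 1],
                                           y = sub[nrow(sub), 2],
                                           z = sub[nrow(sub), 3],
                                           clearance = cl_new, pseudo = TRUE))
        new_gens <- rbind(new_gens, c(e$gens, NA))
        b_id <- next_id; next_id <- next_id + 1L
      }
      out_edges[[length(out_edges) + 1L]] <-
        list(gens = e$gens, v1 = a_id, v2 = b_id, samples = sub,
             edge_id = e$edge_id)
    }
  }
  rownames(new_vt) <- NULL
  res <- graph
  res$vertices <- new_vt
  res$generators <- new_gens
  res$edges <- out_edges
  res$filter_params <- params
  res
}

# point on the locus between a failing and a qualifying sample where the
# clearance equals r_p
probe_crossing <- function(s_below, s_above, gc, gr, rp) {
  f <- function(t) {
    p <- (1 - t) * s_below[1:3] + t * s_above[1:3]
    project_to_locus(matrix(p, 1L), gc, gr)$clearance - rp
  }
  t0 <- tryCatch(stats::uniroot(f, c(0, 1), tol = 1e-10)$root,
                 error = function(e) NA_real_)
  if (is.na(t0)) t0 <- 0.5
  p <- (1 - t0) * s_below[1:3] + t0 * s_above[1:3]
  pr <- project_to_locus(matrix(p, 1L), gc, gr)
  c(pr$position[1, ], pr$clearance[1])
}

#' Split a filtered graph into path components
#'
#' Partitions the surviving vertices and edge arcs of a filtered Voronoi
#' graph into maximal connected subgraphs. Each component carries all
#' locally-widest paths of one cavity. Components are numbered in
#' descending order of total clearance-weighted arc length (ties broken by
#' smallest vertex id) so cavity ids are reproducible.
#'
#' @param graph A `cav_voronoi_graph` returned by [filter_graph()].
#' @return List of `cav_path_component` objects with `component_id`,
#'   `vertex_ids` and `edge_ids` (indices into `graph$edges`).
#' @export
connected_components <- function(graph) {
  vt <- graph$vertices
  if (!nrow(vt)) return(list())
  ids <- as.character(vt$id)
  ig <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = ids)
  if (length(graph$edges)) {
    el <- do.call(rbind, lapply(graph$edges, function(e) c(e$v1, e$v2)))
    ig <- igraph::add_edges(ig, t(matrix(match(as.character(el), ids),
                                         ncol = 2L)))
  }
  memb <- igraph::components(ig)$membership
  comp_of_vertex <- stats::setNames(memb, ids)
  edge_comp <- vapply(graph$edges, function(e)
    comp_of_vertex[[as.character(e$v1)]], numeric(1))
  comps <- lapply(sort(unique(memb)), function(ci) {
    eids <- which(edge_comp == ci)
    w <- 0
    for (ei in eids) {
      s <- graph$edges[[ei]]$samples
      m <- nrow(s)
      if (m >= 2L) {
        len <- sqrt(rowSums((s[-1L, 1:3, drop = FALSE] -
                               s[-m, 1:3, drop = FALSE])^2))
        w <- w + sum(len * (s[-1L, 4] + s[-m, 4]) / 2)
      }
    }
    list(vertex_ids = vt$id[memb == ci], edge_ids = eids, weight = w)
  })
  ord <- order(-vapply(comps, `[[`, numeric(1), "weight"),
               vapply(comps, function(cp) min(cp$vertex_ids), numeric(1)))
  comps <- comps[ord]
  lapply(seq_along(comps), function(i)
    structure(list(component_id = i, vertex_ids = comps[[i]]$vertex_ids,
                   edge_ids = comps[[i]]$edge_ids,
                   weight = comps[[i]]$weight),
              class = "cav_path_component"))
}

#' @export
print.cav_path_component <- function(x, ...) {
  cat(sprintf("<cav_path_component> id %d: %d vertices, %d arcs\n",
              x$component_id, length(x$vertex_ids), length(x$edge_ids)))
  invisible(x)
}
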