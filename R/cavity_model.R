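#' Place empty spheres along an edge arc with the probe-continuity criterion
#'
#' Returns spheres centered on the samples of an edge arc (radius = local
#' clearance) such that for each consecutive pair the largest circle
#' inscribed in their intersection has radius at least r_p. Where the
#' criterion fails between adjacent geometric samples, additional samples
#' are inserted at locus midpoints (clearance recomputed from the three
#' generators, not interpolated) up to `max_refine` levels. With the
#' criterion satisfied, a probe of radius r_p can roll along the whole arc
#' without leaving the sphere union by more than `tol`.
#'
#' The tolerance exists because the exact criterion is unattainable where
#' the clearance dips to exactly r_p with vanishing slope: there the probe
#' touches the cavity boundary tangentially and any finite sphere set
#' leaves an arbitrarily small gap. `tol` bounds that protrusion.
#'
#' @param samples m x 4 matrix (x, y, z, clearance) of arc samples, all
#'   clearances >= r_p.
#' @param gc 3 x 3 matrix of the arc's generator centers.
#' @param gr Radii of the three generators.
#' @param r_p Probe radius in Angstrom.
#' @param max_refine Maximum number of midpoint-insertion levels.
#' @param tol Criterion slack in Angstrom.
#' @return m' x 4 matrix of spheres (x, y, z, radius), endpoints included.
#' @export
sample_edge_spheres <- function(samples, gc, gr, r_p, max_refine = 12L,
                                tol = 1e-6) {
  S <- samples
  if (nrow(S) == 1L) return(S)
  for (lev in seq_len(max_refine + 1L)) {
    m <- nrow(S)
    d <- sqrt(rowSums((S[-1L, 1:3, drop = FALSE] - S[-m, 1:3, drop = FALSE])^2))
    circ <- intersection_circle_vec(d, S[-m, 4], S[-1L, 4])
    bad <- is.na(circ) | circ < r_p - tol
    if (!any(bad)) return(S)
    if (lev > max_refine)
      stop("probe-continuity criterion unattainable at max refinement; ",
           "edge polyline sampling too coarse")
    mid <- (S[-1L, 1:3, drop = FALSE] + S[-m, 1:3, drop = FALSE]) / 2
    pr <- project_to_locus(mid[bad, , drop = FALSE], gc, gr)
    newS <- matrix(0, m + sum(bad), 4L)
    j <- 1L; k <- 1L
    for (i in seq_len(m - 1L)) {
      newS[j, ] <- S[i, ]; j <- j + 1L
      if (bad[i]) {
        newS[j, ] <- c(pr$position[k, ], pr$clearance[k])
        j <- j + 1L; k <- k + 1L
      }
    }
    newS[j, ] <- S[m, ]
    S <- newS
  }
  S
}

#' Build cavity approximations for path components
#'
#' A cavity is the region around one path component in which the probe
#' sphere fits; it is approximated by the union of the empty tangent
#' spheres at the component's Voronoi vertices and of spheres sampled along
#' its edge arcs under the probe-continuity criterion (see
#' [sample_edge_spheres()]).
#'
#' @param components List of path components from [connected_components()].
#' @param graph The filtered `cav_voronoi_graph` they came from.
#' @param frame The originating [sphere_frame()] (provides generator
#'   geometry for refinement).
#' @param r_p Probe radius in Angstrom.
#' @param dedupe_tol Spheres whose centers coincide within this tolerance
#'   are stored once.
#' @return List of `cav_cavity` objects with `frame_index`, `cavity_id`,
#'   `spheres` (m x 4 matrix x, y, z, r), `component_id` and `aabb` (2 x 3
#'   matrix, min and max corners of the sphere extents).
#' @export
build_cavities <- function(components, graph, frame, r_p = 1.4,
                           dedupe_tol = 1e-6) {
  lapply(seq_along(components), function(i) {
    comp <- components[[i]]
    vt <- graph$vertices[graph$vertices$id %in% comp$vertex_ids, ,
                         drop = FALSE]
    sph <- as.matrix(vt[, c("x", "y", "z", "clearance")])
    for (ei in comp$edge_ids) {
      e <- graph$edges[[ei]]
      es <- sample_edge_spheres(e$samples,
                                frame$centers[e$gens, , drop = FALSE],
                                frame$radii[e$gens], r_p)
      sph <- rbind(sph, es)
    }
    key <- paste(round(sph[, 1] / dedupe_tol), round(sph[, 2] / dedupe_tol),
                 round(sph[, 3] / dedupe_tol))
    sph <- sph[!duplicated(key), , drop = FALSE]
    dimnames(sph) <- list(NULL, c("x", "y", "z", "r"))
    aabb <- unname(rbind(apply(sph[, 1:3, drop = FALSE] - sph[, 4], 2L, min),
                         apply(sph[, 1:3, drop = FALSE] + sph[, 4], 2L, max)))
    structure(list(frame_index = graph$frame_index, cavity_id = i,
                   spheres = sph, component_id = comp$component_id,
                   aabb = aabb),
              class = "cav_cavity")
  })
}

#' @export
print.cav_cavity <- function(x, ...) {
  cat(sprintf("<cav_cavity> frame %d id %d: %d spheres\n",
              x$frame_index, x$cavity_id, nrow(x$spheres)))
  invisible(x)
}

#' Export cavities
#'
#' `export_cavities_json()` writes frame index, cavity id and spheres as
#' JSON. `export_cavities_pdb()` writes a PDB-like sphere dump (HETATM
#' records, sphere radius in the B-factor column) for external viewers.
#'
#' @param cavities List of `cav_cavity` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_cavities_json <- function(cavities, path) {
  obj <- lapply(cavities, function(cv)
    list(frame_index = cv$frame_index, cavity_id = cv$cavity_id,
         component_id = cv$component_id,
         aabb = unname(cv$aabb), spheres = unname(cv$spheres)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_cavities_json
#' @export
export_cavities_pdb <- function(cavities, path) {
  lines <- character(0)
  serial <- 1L
  for (cv in cavities) {
    for (i in seq_len(nrow(cv$spheres))) {
      s <- cv$spheres[i, ]
      lines <- c(lines, sprintf(
        "HETATM%5d  O   CAV %1s%4d    %8.3f%8.3f%8.3f  1.00%6.2f           O",
        serial %% 100000L, LETTERS[(cv$cavity_id - 1L) %% 26L + 1L],
        cv$cavity_id %% 10000L, s[1], s[2], s[3], min(s[4], 999.99)))
      serial <- serial + 1L
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# read back a cavities JSON written by export_cavities_json
read_cavities_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(obj)) return(list())
  lapply(seq_len(nrow(obj)), function(i) {
    sph <- obj$spheres[[i]]
    if (!is.matrix(sph)) sph <- matrix(unlist(sph), ncol = 4L, byrow = TRUE)
    colnames(sph) <- c("x", "y", "z", "r")
    aabb <- obj$aabb[[i]]
    if (!is.matrix(aabb)) aabb <- matrix(unlist(aabb), nrow = 2L, byrow = TRUE)
    structure(list(frame_index = obj$frame_index[i],
                   cavity_id = obj$cavity_id[i],
                   spheres = sph,
                   component_id = obj$component_id[i],
                   aabb = aabb),
              class = "cav_cavity")
  })
}
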