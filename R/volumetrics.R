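# closed-form radius of the largest circle inscribed in the intersection of
# two spheres, vectorized over (d, r1, r2); NA where the spheres are disjoint
intersection_circle_vec <- function(d, r1, r2) {
  out <- rep(NA_real_, length(d))
  # the smaller great disc fits inside the larger ball when
  # d^2 + rmin^2 <= rmax^2, i.e. d <= sqrt(|r1^2 - r2^2|) (covers strict
  # containment d <= |r1 - r2| as well)
  great <- d^2 <= abs(r1^2 - r2^2)
  out[great] <- pmin(r1, r2)[great]
  lens <- !great & d < r1 + r2
  if (any(lens)) {
    x <- (d[lens]^2 + r1[lens]^2 - r2[lens]^2) / (2 * d[lens])
    out[lens] <- sqrt(pmax(0, r1[lens]^2 - x^2))
  }
  out
}

#' Largest circle inscribed in the intersection of two spheres
#'
#' The largest circle that fits inside the intersection volume of two
#' spheres with center distance d. Three regimes: if the spheres are
#' disjoint (d >= r1 + r2) there is no circle and `NA` is returned; if the
#' smaller sphere's great disc fits inside the larger ball
#' (d <= sqrt(|r1^2 - r2^2|), which includes strict containment) the
#' largest circle is that great disc, radius min(r1, r2); otherwise the
#' circle lies in the radical plane at distance
#' x = (d^2 + r1^2 - r2^2) / (2 d) from the first center and has radius
#' sqrt(r1^2 - x^2). (A circle of radius rho in the plane perpendicular to
#' the center line at offset t from the first center fits iff
#' rho <= sqrt(r1^2 - t^2) and rho <= sqrt(r2^2 - (d - t)^2); maximizing
#' over t gives exactly these cases.)
#'
#' This primitive decides both the edge-sampling density of cavities and
#' the cavity correspondence test used in tracing.
#'
#' @param s1,s2 Numeric length-4 vectors (x, y, z, r).
#' @return Circle radius in Angstrom, or `NA` for disjoint spheres.
#' @export
largest_intersection_circle_radius <- function(s1, s2) {
  d <- sqrt(sum((s1[1:3] - s2[1:3])^2))
  intersection_circle_vec(d, s1[4], s2[4])
}

# spheres matrix from a cavity object or a plain m x 4 matrix
cavity_spheres <- function(x) {
  if (inherits(x, "cav_cavity")) x$spheres
  else if (is.matrix(x) && ncol(x) == 4L) x
  else stop("expected a cav_cavity or an m x 4 sphere matrix")
}

cavity_aabb <- function(x) {
  if (inherits(x, "cav_cavity")) return(x$aabb)
  s <- cavity_spheres(x)
  rbind(apply(s[, 1:3, drop = FALSE] - s[, 4], 2L, min),
        apply(s[, 1:3, drop = FALSE] + s[, 4], 2L, max))
}

# grid dimensions covering a box [lo, hi] with cube side a, anchored at lo
grid_dims <- function(lo, hi, a) pmax(1L, as.integer(ceiling((hi - lo) / a - 1e-9)))

#' Cube-grid volume of a cavity
#'
#' Approximates the volume of a union of spheres by a regular grid of cubes
#' with side length `a` spanning the cavity's bounding box: the volume is
#' the number of cubes whose center lies strictly inside at least one
#' sphere, times a^3. The approximation converges to the true volume as `a`
#' decreases.
#'
#' @param cavity A `cav_cavity` or an m x 4 sphere matrix (x, y, z, r).
#' @param a Cube side length in Angstrom; default 0.2.
#' @return Volume in cubic Angstrom (0 for an empty sphere set).
#' @export
cavity_volume <- function(cavity, a = 0.2) {
  if (a <= 0) stop("`a` must be > 0")
  s <- cavity_spheres(cavity)
  if (!nrow(s)) return(0)
  box <- cavity_aabb(cavity)
  dims <- grid_dims(box[1, ], box[2, ], a)
  occ <- cpp_grid_occupancy(box[1, ], dims, a, s[, 1:3, drop = FALSE], s[, 4])
  sum(occ) * a^3
}

#' Cube-grid intersection volume of two cavities
#'
#' Counts cubes whose center lies inside at least one sphere of each
#' cavity, on a grid restricted to (and anchored at) the intersection of
#' the two bounding boxes; spheres that do not reach the reduced box are
#' ignored. The shared anchoring makes the result exactly symmetric in its
#' arguments and identical to the computation over the full combined box.
#'
#' @param c1,c2 `cav_cavity` objects or m x 4 sphere matrices.
#' @param a Cube side length in Angstrom.
#' @param reduce Restrict the grid to the intersection box (default). With
#'   `reduce = FALSE` the same lattice is extended over the union of both
#'   boxes (identical result; provided for verification).
#' @return Intersection volume in cubic Angstrom; 0 when the boxes are
#'   disjoint (no grid is allocated).
#' @export
cavity_intersection_volume <- function(c1, c2, a = 0.2, reduce = TRUE) {
  if (a <= 0) stop("`a` must be > 0")
  s1 <- cavity_spheres(c1); s2 <- cavity_spheres(c2)
  if (!nrow(s1) || !nrow(s2)) return(0)
  b1 <- cavity_aabb(c1); b2 <- cavity_aabb(c2)
  lo <- pmax(b1[1, ], b2[1, ]); hi <- pmin(b1[2, ], b2[2, ])
  if (any(lo >= hi)) return(0)
  if (reduce) {
    origin <- lo
    dims <- grid_dims(lo, hi, a)
    s1 <- s1[sphere_touches_box(s1, lo, hi), , drop = FALSE]
    s2 <- s2[sphere_touches_box(s2, lo, hi), , drop = FALSE]
    if (!nrow(s1) || !nrow(s2)) return(0)
  } else {
    ulo <- pmin(b1[1, ], b2[1, ]); uhi <- pmax(b1[2, ], b2[2, ])
    # extend the intersection-anchored lattice to cover the union box
    shift <- ceiling((lo - ulo) / a)
    origin <- lo - shift * a
    dims <- grid_dims(origin, uhi, a)
  }
  o1 <- cpp_grid_occupancy(origin, dims, a, s1[, 1:3, drop = FALSE], s1[, 4])
  o2 <- cpp_grid_occupancy(origin, dims, a, s2[, 1:3, drop = FALSE], s2[, 4])
  sum(o1 & o2) * a^3
}

sphere_touches_box <- function(s, lo, hi) {
  cl <- pmin(pmax(s[, 1:3, drop = FALSE],
                  matrix(lo, nrow(s), 3L, byrow = TRUE)),
             matrix(hi, nrow(s), 3L, byrow = TRUE))
  rowSums((cl - s[, 1:3, drop = FALSE])^2) < s[, 4]^2
}

#' Number of water molecules fitting a volume
#'
#' Heuristic capacity estimate: the volume of one water molecule is
#' approximated by 30 cubic Angstrom, so a cavity of volume V holds
#' floor(V / 30) waters.
#'
#' @param volume Volume in cubic Angstrom (>= 0).
#' @param water_volume Volume per water molecule; default 30.
#' @return Integer count.
#' @export
water_capacity <- function(volume, water_volume = 30) {
  if (any(volume < 0)) stop("`volume` must be >= 0")
  as.integer(floor(volume / water_volume))
}

#' Regular cube grid container
#'
#' @param origin Min corner of the grid (3-vector, Angstrom); cube centers
#'   lie at origin + (i + 1/2) a elementwise.
#' @param dims Integer 3-vector of cube counts.
#' @param a Cube side length (> 0).
#' @param values Numeric vector of length prod(dims), x fastest.
#' @return An object of class `cav_volume_grid`.
#' @export
volume_grid <- function(origin, dims, a, values) {
  if (a <= 0) stop("`a` must be > 0")
  dims <- as.integer(dims)
  if (length(values) != prod(dims)) stop("`values` length must equal prod(dims)")
  structure(list(origin = as.numeric(origin), dims = dims, a = a,
                 values = as.numeric(values)),
            class = "cav_volume_grid")
}

#' @export
print.cav_volume_grid <- function(x, ...) {
  cat(sprintf("<cav_volume_grid> %d x %d x %d cubes, a = %g A\n",
              x$dims[1], x$dims[2], x$dims[3], x$a))
  invisible(x)
}

#' Occupancy grid of a sphere set
#'
#' @param spheres m x 4 matrix (x, y, z, r) or `cav_cavity`.
#' @param a Cube side length.
#' @param aabb Optional 2 x 3 box (min and max corner rows); defaults to
#'   the sphere extents.
#' @return A [volume_grid()] with 0/1 values.
#' @export
occupancy_grid <- function(spheres, a = 0.2, aabb = NULL) {
  s <- cavity_spheres(spheres)
  box <- if (is.null(aabb)) cavity_aabb(spheres) else aabb
  dims <- grid_dims(box[1, ], box[2, ], a)
  occ <- cpp_grid_occupancy(box[1, ], dims, a, s[, 1:3, drop = FALSE], s[, 4])
  volume_grid(box[1, ], dims, a, occ)
}

#' Write a grid as an OpenDX scalar volume
#'
#' Plain-text OpenDX format readable by PyMOL, VMD and Chimera. Values are
#' written on the cube centers.
#'
#' @param grid A [volume_grid()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_grid_dx <- function(grid, path) {
  d <- grid$dims
  orig <- grid$origin + grid$a / 2      # first cube center
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", orig[1], orig[2], orig[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$a),
    sprintf("delta 0.000000 %.6f 0.000000", grid$a),
    sprintf("delta 0.000000 0.000000 %.6f", grid$a),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX expects z fastest; internal storage is x fastest
  arr <- array(grid$values, dim = d)
  vals <- as.vector(aperm(arr, c(3L, 2L, 1L)))
  idx <- seq(1L, length(vals), by = 3L)
  lines <- vapply(idx, function(i)
    paste(sprintf("%.6g", vals[i:min(i + 2L, length(vals))]), collapse = " "),
    character(1))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
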