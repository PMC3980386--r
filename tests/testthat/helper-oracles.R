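# Independent oracles used to validate the implementation. These
# deliberately take different computational routes than the package code.

# Brute-force vertex enumeration for the additively weighted Voronoi
# diagram: for every 4-subset, trilaterate the tangency point from three
# spheres as a function of the common clearance c and root-find the fourth
# tangency condition on a c grid. Entirely independent of the package's
# linear-reduction solver.
oracle_aw_vertices <- function(centers, radii, c_lo = NULL, c_hi = NULL,
                               n_grid = 1200L, tol = 1e-10) {
  n <- nrow(centers)
  if (is.null(c_lo)) c_lo <- -min(radii) + 1e-9
  if (is.null(c_hi)) {
    span <- apply(centers, 2, max) - apply(centers, 2, min)
    c_hi <- sqrt(sum((span + 2 * max(radii))^2))
  }
  # trilateration of the point tangent to spheres 1..3 at clearance c, in
  # the local (ex, ey, ez) frame: x(c) and y(c) are affine in c, z(c)^2
  # quadratic, so f(c) evaluates vectorized over a whole c grid
  found <- list()
  for (sub in utils::combn(n, 4L, simplify = FALSE)) {
    p <- centers[sub, , drop = FALSE]; r <- radii[sub]
    ex <- p[2, ] - p[1, ]; d <- sqrt(sum(ex^2)); ex <- ex / d
    i0 <- sum(ex * (p[3, ] - p[1, ]))
    ey <- p[3, ] - p[1, ] - i0 * ex; j0 <- sqrt(sum(ey^2)); ey <- ey / j0
    ez <- c(ex[2] * ey[3] - ex[3] * ey[2], ex[3] * ey[1] - ex[1] * ey[3],
            ex[1] * ey[2] - ex[2] * ey[1])
    trilat_pts <- function(cc, branch) {
      R1 <- r[1] + cc; R2 <- r[2] + cc; R3 <- r[3] + cc
      x <- (R1^2 - R2^2 + d^2) / (2 * d)
      y <- (R1^2 - R3^2 + i0^2 + j0^2 - 2 * i0 * x) / (2 * j0)
      z2 <- R1^2 - x^2 - y^2
      z <- ifelse(z2 < 0, NA_real_, sqrt(pmax(0, z2)))
      s <- if (branch == 1L) -1 else 1
      cbind(p[1, 1] + x * ex[1] + y * ey[1] + s * z * ez[1],
            p[1, 2] + x * ex[2] + y * ey[2] + s * z * ez[2],
            p[1, 3] + x * ex[3] + y * ey[3] + s * z * ez[3])
    }
    for (branch in 1:2) {
      f <- function(cc) {
        pt <- trilat_pts(cc, branch)
        sqrt((pt[, 1] - p[4, 1])^2 + (pt[, 2] - p[4, 2])^2 +
               (pt[, 3] - p[4, 3])^2) - r[4] - cc
      }
      cs <- seq(c_lo, c_hi, length.out = n_grid)
      fv <- f(cs)
      both <- !is.na(fv[-length(fv)]) & !is.na(fv[-1])
      ok <- which(both & sign(fv[-length(fv)]) * sign(fv[-1]) <= 0)
      # near-tangential root pairs and roots adjacent to the z^2 < 0
      # domain boundary can hide inside one grid cell without a detected
      # sign change; sub-sample every cell whose defined values dip near
      # zero (including cells with an NA endpoint)
      absmin <- pmin(abs(fv[-length(fv)]), abs(fv[-1]), na.rm = TRUE)
      close <- which(!(seq_len(n_grid - 1L) %in% ok) &
                       is.finite(absmin) & absmin < 0.4)
      brackets <- lapply(ok, function(k) c(cs[k], cs[k + 1]))
      for (k in close) {
        sub <- seq(cs[k], cs[k + 1], length.out = 801L)
        fs <- f(sub)
        sok <- which(!is.na(fs[-length(fs)]) & !is.na(fs[-1]) &
                       sign(fs[-length(fs)]) * sign(fs[-1]) <= 0)
        for (j in sok)
          brackets[[length(brackets) + 1L]] <- c(sub[j], sub[j + 1])
      }
      for (br in brackets) {
        root <- tryCatch(stats::uniroot(f, br, tol = tol)$root,
                         error = function(e) NA_real_)
        if (is.na(root)) next
        pt <- trilat_pts(root, branch)[1, ]
        # empty-sphere test
        others <- setdiff(seq_len(n), sub)
        if (length(others)) {
          wd <- sqrt(rowSums(sweep(centers[others, , drop = FALSE],
                                   2, pt)^2)) - radii[others]
          if (min(wd) < root - 1e-7) next
        }
        found[[length(found) + 1L]] <- c(pt, root)
      }
    }
  }
  if (!length(found)) return(matrix(numeric(0), 0L, 4L))
  m <- do.call(rbind, found)
  # dedupe (same vertex found through several subsets or branches)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (keep[j] && sum((m[i, 1:3] - m[j, 1:3])^2) < 1e-12) {
        keep[i] <- FALSE
        break
      }
    }
  }
  m[keep, , drop = FALSE]
}

# Ordinary point-Voronoi vertices by circumcenter enumeration: for every
# 4-subset of points, the circumcenter (linear system of squared-distance
# differences) kept when no other point is strictly closer. Radii never
# enter, so this is independent of the weighted solver.
oracle_point_voronoi <- function(points) {
  n <- nrow(points)
  found <- list()
  for (sub in utils::combn(n, 4L, simplify = FALSE)) {
    p <- points[sub, , drop = FALSE]
    A <- 2 * sweep(p[2:4, , drop = FALSE], 2, p[1, ])
    b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
    det <- det(A)
    if (abs(det) < 1e-10) next
    cc <- solve(A, b)
    rad <- sqrt(sum((cc - p[1, ])^2))
    others <- setdiff(seq_len(n), sub)
    if (length(others)) {
      dmin <- min(sqrt(rowSums(sweep(points[others, , drop = FALSE],
                                     2, cc)^2)))
      if (dmin < rad - 1e-9) next
    }
    found[[length(found) + 1L]] <- c(cc, rad)
  }
  if (!length(found)) return(matrix(numeric(0), 0L, 4L))
  m <- do.call(rbind, found)
  keep <- !duplicated(round(m[, 1:3], 8L))
  m[keep, , drop = FALSE]
}

# Largest circle inside the intersection of two balls by direct constrained
# maximization: a circle of radius rho in the plane perpendicular to the
# center line at offset t fits iff rho <= sqrt(r1^2 - t^2) and
# rho <= sqrt(r2^2 - (d - t)^2); maximize the min over t numerically.
oracle_inscribed_circle <- function(d, r1, r2) {
  if (d >= r1 + r2) return(NA_real_)
  f <- function(t) pmin(sqrt(pmax(0, r1^2 - t^2)),
                        sqrt(pmax(0, r2^2 - (d - t)^2)))
  # f has zero plateaus outside the lens, so seed a local search from a
  # dense grid argmax instead of trusting unimodality
  ts <- seq(-r1, d + r2, length.out = 4001L)
  k <- which.max(f(ts))
  lo <- ts[max(1L, k - 1L)]; hi <- ts[min(length(ts), k + 1L)]
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)$objective
}

# Monte-Carlo volume of a union of spheres
oracle_mc_volume <- function(spheres, n_points = 1e6, seed = 1) {
  lo <- apply(spheres[, 1:3, drop = FALSE] - spheres[, 4], 2, min)
  hi <- apply(spheres[, 1:3, drop = FALSE] + spheres[, 4], 2, max)
  set.seed(seed)
  P <- cbind(runif(n_points, lo[1], hi[1]), runif(n_points, lo[2], hi[2]),
             runif(n_points, lo[3], hi[3]))
  inside <- rep(FALSE, n_points)
  for (i in seq_len(nrow(spheres)))
    inside <- inside | rowSums(sweep(P, 2, spheres[i, 1:3])^2) <
      spheres[i, 4]^2
  vbox <- prod(hi - lo)
  p <- mean(inside)
  list(volume = p * vbox,
       sigma = sqrt(p * (1 - p) / n_points) * vbox)
}

# deterministic random test frame
random_frame <- function(n, seed, box = 10, rmin = 1, rmax = 2) {
  set.seed(seed)
  sphere_frame(matrix(runif(3 * n, 0, box), ncol = 3L),
               runif(n, rmin, rmax))
}

# small helper: wrap a sphere matrix as a cavity object
as_cavity <- function(spheres, cavity_id = 1L, frame_index = 0L) {
  spheres <- matrix(spheres, ncol = 4L,
                    dimnames = list(NULL, c("x", "y", "z", "r")))
  structure(list(frame_index = frame_index, cavity_id = cavity_id,
                 spheres = spheres, component_id = cavity_id,
                 aabb = unname(rbind(apply(spheres[, 1:3, drop = FALSE] -
                                             spheres[, 4], 2, min),
                                     apply(spheres[, 1:3, drop = FALSE] +
                                             spheres[, 4], 2, max)))),
            class = "cav_cavity")
}
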