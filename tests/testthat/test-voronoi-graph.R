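test_that("weighted distance matches its definition", {
  expect_equal(weighted_distance(c(0, 0, 0), c(0, 0, 0), 1), -1)
  expect_equal(weighted_distance(c(1, 0, 0), c(0, 0, 0), 1), 0)
  expect_equal(weighted_distance(c(3, 0, 0), c(0, 0, 0), 1), 2)
  # matrix form
  wd <- weighted_distance(rbind(c(0, 0, 0), c(3, 0, 0)),
                          rbind(c(0, 0, 0), c(0, 4, 0)), c(1, 2))
  expect_equal(dim(wd), c(2L, 2L))
  expect_equal(wd[1, ], c(-1, 2))
})

test_that("tetrahedral cage has one interior vertex at the closed form", {
  fr <- make_tetra_cage(2, 1)
  g <- compute_voronoi_graph(fr)
  # exactly one vertex inside the hull (at the centroid), clearance
  # = circumradius - atom radius
  int <- which(rowSums(as.matrix(g$vertices[, c("x", "y", "z")])^2) < 1e-6)
  expect_length(int, 1L)
  expect_equal(g$vertices$clearance[int], 2 * sqrt(3 / 8) - 1,
               tolerance = 1e-9)
  rep <- verify_vertex(graph_vertex(g, int), fr, tol = 1e-9)
  expect_true(rep$pass)
  expect_lt(max(abs(rep$tangency_residuals)), 1e-9)
  # a wrong clearance is detected with the residual reported
  bad <- graph_vertex(g, int)
  bad$clearance <- bad$clearance + 0.01
  rep2 <- verify_vertex(bad, fr, tol = 1e-6)
  expect_false(rep2$pass)
  expect_equal(max(abs(rep2$tangency_residuals)), 0.01, tolerance = 1e-8)
})

test_that("fewer than 4 spheres is an error", {
  fr <- sphere_frame(diag(3), rep(1, 3))
  expect_error(compute_voronoi_graph(fr), "4 spheres")
})

test_that("every vertex of random frames passes verification", {
  for (seed in c(11, 12, 13)) {
    fr <- random_frame(20, seed)
    g <- compute_voronoi_graph(fr)
    expect_gt(nrow(g$vertices), 0)
    for (i in seq_len(nrow(g$vertices)))
      expect_true(verify_vertex(graph_vertex(g, i), fr, tol = 1e-6)$pass)
  }
})

test_that("vertex set equals independent brute-force enumeration (n <= 8)", {
  for (n in c(6L, 8L)) {
    fr <- random_frame(n, 100 + n)
    g <- compute_voronoi_graph(fr)
    o <- oracle_aw_vertices(fr$centers, fr$radii)
    # restrict the oracle to the graph's expanded box
    inb <- o[, 1] >= g$box_lo[1] & o[, 1] <= g$box_hi[1] &
      o[, 2] >= g$box_lo[2] & o[, 2] <= g$box_hi[2] &
      o[, 3] >= g$box_lo[3] & o[, 3] <= g$box_hi[3]
    o <- o[inb, , drop = FALSE]
    expect_equal(nrow(g$vertices), nrow(o))
    m <- as.matrix(g$vertices[, c("x", "y", "z", "clearance")])
    for (i in seq_len(nrow(o))) {
      d <- sqrt(rowSums(sweep(m[, 1:3, drop = FALSE], 2, o[i, 1:3])^2))
      j <- which.min(d)
      expect_lt(d[j], 1e-7)
      expect_lt(abs(m[j, 4] - o[i, 4]), 1e-7)
    }
  }
})

test_that("equal radii reduce to the ordinary point Voronoi diagram", {
  for (seed in 1:10) {
    set.seed(seed)
    pts <- matrix(runif(30, 0, 10), ncol = 3)
    r0 <- 1.2
    fr <- sphere_frame(pts, rep(r0, 10))
    g <- compute_voronoi_graph(fr)
    o <- oracle_point_voronoi(pts)
    inb <- o[, 1] >= g$box_lo[1] & o[, 1] <= g$box_hi[1] &
      o[, 2] >= g$box_lo[2] & o[, 2] <= g$box_hi[2] &
      o[, 3] >= g$box_lo[3] & o[, 3] <= g$box_hi[3]
    o <- o[inb, , drop = FALSE]
    expect_equal(nrow(g$vertices), nrow(o))
    m <- as.matrix(g$vertices[, c("x", "y", "z", "clearance")])
    for (i in seq_len(nrow(o))) {
      d <- sqrt(rowSums(sweep(m[, 1:3, drop = FALSE], 2, o[i, 1:3])^2))
      j <- which.min(d)
      expect_lt(d[j], 1e-6)
      # clearance = point-Voronoi circumradius minus the common radius
      expect_lt(abs(m[j, 4] - (o[i, 4] - r0)), 1e-6)
    }
  }
})

test_that("edge samples are weighted-equidistant to their generators", {
  fr <- random_frame(20, 21)
  g <- compute_voronoi_graph(fr)
  expect_gt(length(g$edges), 0)
  for (e in g$edges) {
    wd <- weighted_distance(e$samples[, 1:3, drop = FALSE],
                            fr$centers[e$gens, , drop = FALSE],
                            fr$radii[e$gens])
    expect_lt(max(abs(wd - e$samples[, 4])), 1e-6)
    # samples keep the empty-sphere property
    others <- setdiff(seq_len(nrow(fr$centers)), e$gens)
    wdo <- weighted_distance(e$samples[, 1:3, drop = FALSE],
                             fr$centers[others, , drop = FALSE],
                             fr$radii[others])
    expect_gt(min(apply(wdo, 1, min) - e$samples[, 4]), -1e-5)
  }
})

test_that("graph structure is consistent", {
  fr <- random_frame(20, 33)
  g <- compute_voronoi_graph(fr)
  ids <- g$vertices$id
  for (e in g$edges) {
    expect_true(e$v1 %in% ids)
    if (!is.na(e$v2)) {
      expect_true(e$v2 %in% ids)
      # the two endpoint generator sets share exactly the edge's 3 generators
      g1 <- g$generators[match(e$v1, ids), ]
      g2 <- g$generators[match(e$v2, ids), ]
      expect_setequal(intersect(g1, g2), e$gens)
      # polyline endpoints coincide with the vertex positions
      expect_lt(sum((as.numeric(g$vertices[match(e$v1, ids),
                                           c("x", "y", "z")]) -
                       e$samples[1, 1:3])^2), 1e-12)
      expect_lt(sum((as.numeric(g$vertices[match(e$v2, ids),
                                           c("x", "y", "z")]) -
                       e$samples[nrow(e$samples), 1:3])^2), 1e-12)
    }
  }
})

test_that("contained spheres are dropped before computation", {
  fr <- make_tetra_cage(4, 1)
  centers <- rbind(fr$centers, fr$centers[1, ] + c(0.1, 0, 0))
  radii <- c(fr$radii, 0.2)   # tiny sphere inside atom 1
  fr2 <- sphere_frame(centers, radii)
  expect_message(g <- compute_voronoi_graph(fr2), "contained")
  expect_false(any(g$generators == 5L))
  # result identical to the 4-sphere graph
  g0 <- compute_voronoi_graph(fr)
  expect_equal(g$vertices$clearance, g0$vertices$clearance, tolerance = 1e-12)
})

test_that("exact degeneracy errors and perturbation repairs it", {
  # octahedron: six cospherical equal spheres, degenerate center vertex
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1)) * 2
  fr <- sphere_frame(oct, rep(1, 6))
  expect_error(compute_voronoi_graph(fr), "perturb")
  pf <- perturb_positions(fr, 1e-6, seed = 4L)
  g <- compute_voronoi_graph(pf)
  expect_gt(nrow(g$vertices), 0)
  for (i in seq_len(nrow(g$vertices)))
    expect_true(verify_vertex(graph_vertex(g, i), pf, tol = 1e-6)$pass)
})

test_that("voronoi graph exports are well-formed", {
  fr <- random_frame(10, 55)
  g <- compute_voronoi_graph(fr)
  jp <- withr::local_tempfile(fileext = ".json")
  export_voronoi_json(g, jp)
  back <- jsonlite::read_json(jp)
  expect_length(back$vertices, nrow(g$vertices))
  expect_length(back$edges, length(g$edges))
  gp <- withr::local_tempfile(fileext = ".graphml")
  export_voronoi_graphml(g, gp)
  ig <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(g$vertices))
})
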