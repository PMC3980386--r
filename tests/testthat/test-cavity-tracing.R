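# toy cavities: well-separated single- or few-sphere cavities whose
# overlaps are fully controlled by construction
ball <- function(x, y, z, r, id) as_cavity(matrix(c(x, y, z, r), 1),
                                           cavity_id = id)

test_that("identical frames map every cavity onto itself", {
  cavs <- list(ball(0, 0, 0, 2, 1L), ball(10, 0, 0, 2, 2L))
  em <- map_cavities_between_frames(cavs, cavs, r_ic = 1.4)
  expect_equal(nrow(em), 2L)
  expect_equal(em$cav_t, em$cav_t1)
  # self-overlap: the circle is the sphere's own great circle
  expect_equal(em$circle_radius, c(2, 2))
})

test_that("cavities translated far apart produce no edges", {
  a <- list(ball(0, 0, 0, 2, 1L))
  b <- list(ball(10, 0, 0, 2, 1L))
  expect_equal(nrow(map_cavities_between_frames(a, b, 1.4)), 0L)
})

test_that("the r_ic test is strict and monotone", {
  # two unit... two 2 A spheres at distance 2: circle = sqrt(4 - 1) = sqrt(3)
  a <- list(ball(0, 0, 0, 2, 1L))
  b <- list(ball(2, 0, 0, 2, 1L))
  circ <- sqrt(3)
  expect_equal(nrow(map_cavities_between_frames(a, b, r_ic = circ - 1e-9)), 1L)
  # strictly greater than r_ic is required
  expect_equal(nrow(map_cavities_between_frames(a, b, r_ic = circ)), 0L)
  prev <- Inf
  for (ric in c(0.5, 1.0, 1.5, 1.71, 1.8)) {
    n <- nrow(map_cavities_between_frames(a, b, r_ic = ric))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("splits inherit identity along the larger intersection volume", {
  # frame t: one big cavity; frame t+1: two overlapping it, B more than C
  A <- list(as_cavity(rbind(c(0, 0, 0, 2), c(3, 0, 0, 2)), 1L, 0L))
  B <- ball(0, 0, 0, 2, 1L); B$frame_index <- 1L     # large overlap
  C <- ball(4, 0, 0, 1.8, 2L); C$frame_index <- 1L   # smaller overlap
  tg <- build_time_graph(list(A, list(B, C)), frame_indices = c(0, 1),
                         r_ic = 1.4, a = 0.1)
  expect_equal(nrow(tg$edges), 2L)
  n <- tg$nodes
  expect_equal(n$identity[n$frame == 0], 1L)
  expect_equal(n$identity[n$frame == 1 & n$cavity_id == 1], 1L)
  expect_equal(n$identity[n$frame == 1 & n$cavity_id == 2], 2L)
  ev <- cavitrace:::time_graph_events(tg)
  expect_equal(ev$type, "split")
  expect_equal(ev$frame, 1)
  expect_equal(ev$children, "1,2")
})

test_that("merges keep the identity of the larger-overlap parent", {
  A <- ball(0, 0, 0, 2, 1L)
  B <- ball(4.5, 0, 0, 1.6, 2L)
  Cm <- as_cavity(rbind(c(0, 0, 0, 2), c(4.5, 0, 0, 1.6)), 1L, 1L)
  tg <- build_time_graph(list(list(A, B), list(Cm)), frame_indices = c(0, 1),
                         r_ic = 1.4, a = 0.1)
  expect_equal(nrow(tg$edges), 2L)
  n <- tg$nodes
  # A has the larger intersection volume with C, so C inherits identity 1
  expect_equal(n$identity[n$frame == 1], 1L)
  ev <- cavitrace:::time_graph_events(tg)
  expect_equal(ev$type, "merge")
  expect_equal(ev$parents, "1,2")
  expect_equal(ev$children, "1")
})

test_that("a single cavity persisting keeps one identity throughout", {
  frames <- lapply(0:9, function(t) {
    cv <- ball(0.05 * t, 0, 0, 2, 1L); cv$frame_index <- t; list(cv)
  })
  tg <- build_time_graph(frames, frame_indices = 0:9, r_ic = 1.4, a = 0.1)
  expect_equal(unique(tg$nodes$identity), 1L)
  expect_equal(nrow(tg$edges), 9L)
  expect_true(all(tg$edges$matched))
})

test_that("identities are unique within every frame", {
  set.seed(44)
  frames <- lapply(0:4, function(t) {
    lapply(1:3, function(i) {
      cv <- ball(6 * i + 0.3 * t, 0, 0, 2, i); cv$frame_index <- t; cv
    })
  })
  tg <- build_time_graph(frames, frame_indices = 0:4, r_ic = 1.4, a = 0.1)
  for (f in unique(tg$nodes$frame)) {
    ids <- tg$nodes$identity[tg$nodes$frame == f]
    expect_false(any(duplicated(ids)))
  }
  # greedy matching is a matching: no node matched twice
  me <- tg$edges[tg$edges$matched, ]
  for (f in unique(me$frame_t)) {
    expect_false(any(duplicated(me$cav_t[me$frame_t == f])))
    expect_false(any(duplicated(me$cav_t1[me$frame_t == f])))
  }
})

# fabricated time graph: a trunk that splits at frame 2 into a branch that
# dies at frame 5 (of 10 frames) while the trunk persists
make_branchy_tg <- function() {
  nodes <- rbind(
    data.frame(frame = 0:9, cavity_id = 1L, volume = 10),
    data.frame(frame = 3:5, cavity_id = 2L, volume = 5))
  nodes <- nodes[order(nodes$frame, nodes$cavity_id), ]
  edges <- rbind(
    data.frame(frame_t = 0:8, cav_t = 1L, cav_t1 = 1L, circle_radius = 2,
               intersection_volume = 8),
    data.frame(frame_t = 2L, cav_t = 1L, cav_t1 = 2L, circle_radius = 1.8,
               intersection_volume = 4),
    data.frame(frame_t = 3:4, cav_t = 2L, cav_t1 = 2L, circle_radius = 1.8,
               intersection_volume = 4))
  nodes$identity <- NA_integer_
  tg <- structure(list(nodes = nodes, edges = edges, frame_indices = 0:9,
                       r_ic = 1.4, a = 0.2),
                  class = "cav_time_graph")
  assign_identity_numbers(tg)
}

test_that("dead-end removal truncates a vanished branch back to its split", {
  tg <- make_branchy_tg()
  expect_equal(nrow(tg$nodes), 13L)
  out <- remove_dead_ends(tg)
  # branch nodes (frames 3-5, cavity 2) are gone, trunk intact
  expect_equal(nrow(out$nodes), 10L)
  expect_true(all(out$nodes$cavity_id == 1L))
  expect_equal(out$nodes$frame, 0:9)
  # a cavity alive through the final frame is retained
  expect_true(any(out$nodes$frame == 9))
})

test_that("dead-end removal leaves a persistent cavity unchanged", {
  tg <- make_branchy_tg()
  trunk <- tg
  trunk$nodes <- trunk$nodes[trunk$nodes$cavity_id == 1L, ]
  trunk$edges <- trunk$edges[trunk$edges$cav_t == 1L &
                               trunk$edges$cav_t1 == 1L, ]
  out <- remove_dead_ends(trunk)
  expect_equal(out$nodes, trunk$nodes)
  expect_equal(out$edges, trunk$edges)
})

test_that("forbid-splits drops the unmatched branch and keeps chains", {
  tg <- make_branchy_tg()
  out <- forbid_splits(tg)
  expect_true(all(out$nodes$cavity_id == 1L))
  expect_true(all(out$edges$matched))
  # each node has at most one forward edge: simple chains
  expect_false(any(duplicated(out$edges$frame_t)))
  # absent any splits the graph is unchanged
  chain <- make_branchy_tg()
  chain$nodes <- chain$nodes[chain$nodes$cavity_id == 1L, ]
  chain$edges <- chain$edges[chain$edges$cav_t1 == 1L, ]
  out2 <- forbid_splits(chain)
  expect_equal(nrow(out2$nodes), 10L)
  expect_equal(nrow(out2$edges), 9L)
})

test_that("dynamic paths follow time-adjacent edges and report no-path", {
  tg <- make_branchy_tg()
  # trivial two-node leg
  dp <- extract_dynamic_path(tg, list(c(0, 1), c(1, 1)))
  expect_true(dp$found)
  expect_equal(nrow(dp$nodes), 2L)
  # through the split into the branch
  dp2 <- extract_dynamic_path(tg, list(c(0, 1), c(5, 2)))
  expect_true(dp2$found)
  expect_equal(dp2$nodes$cavity_id, c(1, 1, 1, 2, 2, 2))
  # via an intermediate selection on the trunk
  dp3 <- extract_dynamic_path(tg, list(c(0, 1), c(4, 1), c(9, 1)))
  expect_true(dp3$found)
  expect_equal(nrow(dp3$nodes), 10L)
  expect_true(all(dp3$nodes$cavity_id == 1L))
  # branch dies at 5: no path from the branch to frame 9
  dp4 <- extract_dynamic_path(tg, list(c(5, 2), c(9, 1)))
  expect_false(dp4$found)
  expect_error(extract_dynamic_path(tg, list(c(5, 2))), "at least 2")
  expect_error(extract_dynamic_path(tg, list(c(5, 2), c(5, 1))),
               "increasing frame")
})

test_that("the DFS prefers the larger intersection volume at ties in length", {
  # two routes from (0,1) to (2,1): via (1,1) [big volumes] or (1,2) [small]
  nodes <- data.frame(frame = c(0, 1, 1, 2), cavity_id = c(1, 1, 2, 1),
                      volume = 1, identity = c(1L, 1L, 2L, 1L))
  edges <- data.frame(frame_t = c(0, 0, 1, 1), cav_t = c(1, 1, 1, 2),
                      cav_t1 = c(1, 2, 1, 1), circle_radius = 2,
                      intersection_volume = c(9, 1, 9, 1),
                      matched = c(TRUE, FALSE, TRUE, FALSE))
  tg <- structure(list(nodes = nodes, edges = edges, frame_indices = 0:2,
                       r_ic = 1.4, a = 0.2), class = "cav_time_graph")
  dp <- extract_dynamic_path(tg, list(c(0, 1), c(2, 1)))
  expect_true(dp$found)
  expect_equal(dp$nodes$cavity_id, c(1, 1, 1))
})

test_that("time graph exports are readable", {
  tg <- make_branchy_tg()
  jp <- withr::local_tempfile(fileext = ".json")
  export_time_graph_json(tg, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(nrow(back$nodes), nrow(tg$nodes))
  gp <- withr::local_tempfile(fileext = ".graphml")
  export_time_graph_graphml(tg, gp)
  ig <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(tg$nodes))
  expect_equal(igraph::ecount(ig), nrow(tg$edges))
})
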