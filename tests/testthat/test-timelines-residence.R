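persistent_tg <- function(n_frames = 10L) {
  nodes <- data.frame(frame = seq_len(n_frames) - 1L, cavity_id = 1L,
                      volume = 33.3, identity = 1L)
  ft <- seq_len(max(n_frames - 1L, 0L)) - 1L
  edges <- data.frame(frame_t = ft, cav_t = rep(1L, length(ft)),
                      cav_t1 = rep(1L, length(ft)),
                      circle_radius = rep(2, length(ft)),
                      intersection_volume = rep(30, length(ft)),
                      matched = rep(TRUE, length(ft)))
  structure(list(nodes = nodes, edges = edges,
                 frame_indices = seq_len(n_frames) - 1L,
                 r_ic = 1.4, a = 0.2), class = "cav_time_graph")
}

# scripted merge at frame 2 then split at frame 4:
# identities 1,2 -> merge into 1 -> split into 1,3
merge_split_tg <- function() {
  nodes <- rbind(data.frame(frame = c(0, 1), cavity_id = 1L, volume = 10),
                 data.frame(frame = c(0, 1), cavity_id = 2L, volume = 6),
                 data.frame(frame = c(2, 3), cavity_id = 1L, volume = 16),
                 data.frame(frame = c(4, 5), cavity_id = 1L, volume = 9),
                 data.frame(frame = c(4, 5), cavity_id = 2L, volume = 7))
  nodes <- nodes[order(nodes$frame, nodes$cavity_id), ]
  nodes$identity <- NA_integer_
  edges <- rbind(
    data.frame(frame_t = 0L, cav_t = 1:2, cav_t1 = 1:2, circle_radius = 2,
               intersection_volume = c(9, 5)),
    data.frame(frame_t = 1L, cav_t = 1:2, cav_t1 = 1L, circle_radius = 2,
               intersection_volume = c(9, 5)),
    data.frame(frame_t = 2L, cav_t = 1L, cav_t1 = 1L, circle_radius = 2,
               intersection_volume = 14),
    data.frame(frame_t = 3L, cav_t = 1L, cav_t1 = 1:2, circle_radius = 2,
               intersection_volume = c(8, 6)),
    data.frame(frame_t = 4L, cav_t = 1:2, cav_t1 = 1:2, circle_radius = 2,
               intersection_volume = c(8, 6)))
  tg <- structure(list(nodes = nodes, edges = edges, frame_indices = 0:5,
                       r_ic = 1.4, a = 0.2), class = "cav_time_graph")
  assign_identity_numbers(tg)
}

test_that("a single persistent cavity gives one polyline and no events", {
  tl <- split_merge_timeline(persistent_tg())
  expect_equal(nrow(tl$polylines), 10L)
  expect_equal(unique(tl$polylines$identity), 1L)
  expect_equal(unique(tl$polylines$row), 1L)
  expect_equal(unique(tl$polylines$volume), 33.3)
  expect_equal(nrow(tl$events), 0L)
})

test_that("the scripted merge-then-split event list is reconstructed", {
  tg <- merge_split_tg()
  # identity bookkeeping: merged cavity keeps 1; the split spawns 3
  n <- tg$nodes
  expect_equal(n$identity[n$frame == 2], 1L)
  expect_setequal(n$identity[n$frame == 4], c(1L, 3L))
  tl <- split_merge_timeline(tg)
  expect_equal(nrow(tl$events), 2L)
  expect_equal(tl$events$frame, c(2, 4))
  expect_equal(tl$events$type, c("merge", "split"))
  expect_equal(tl$events$parents, c("1,2", "1"))
  expect_equal(tl$events$children, c("1", "1,3"))
  # rows run top to bottom by identity within each frame
  f0 <- tl$polylines[tl$polylines$frame == 0, ]
  expect_equal(f0$row, seq_len(nrow(f0)))
  expect_equal(f0$identity, sort(f0$identity))
})

test_that("an empty time range yields an empty table", {
  tl <- split_merge_timeline(persistent_tg(), t_range = c(100, 200))
  expect_equal(nrow(tl$polylines), 0L)
  expect_equal(nrow(tl$events), 0L)
})

test_that("evolution profiles project cavity extents onto an axis", {
  cv <- as_cavity(matrix(c(0, 0, 0, 1), 1))
  tg <- persistent_tg(1L)
  pr <- evolution_profile(tg, list(list(cv)), axis = c(0, 0, 1))
  expect_equal(pr$min_proj, -1)
  expect_equal(pr$max_proj, 1)
  expect_true(pr$present)
  # axis is normalized; zero axis errors
  pr2 <- evolution_profile(tg, list(list(cv)), axis = c(0, 0, 7))
  expect_equal(pr2$min_proj, -1)
  expect_error(evolution_profile(tg, list(list(cv)), axis = c(0, 0, 0)),
               "nonzero")
})

make_branchy_tg_timeline <- function() {
  nodes <- rbind(
    data.frame(frame = 0:9, cavity_id = 1L, volume = 10),
    data.frame(frame = 3:5, cavity_id = 2L, volume = 5))
  nodes <- nodes[order(nodes$frame, nodes$cavity_id), ]
  nodes$identity <- NA_integer_
  edges <- rbind(
    data.frame(frame_t = 0:8, cav_t = 1L, cav_t1 = 1L, circle_radius = 2,
               intersection_volume = 8),
    data.frame(frame_t = 2L, cav_t = 1L, cav_t1 = 2L, circle_radius = 1.8,
               intersection_volume = 4),
    data.frame(frame_t = 3:4, cav_t = 2L, cav_t1 = 2L, circle_radius = 1.8,
               intersection_volume = 4))
  tg <- structure(list(nodes = nodes, edges = edges, frame_indices = 0:9,
                       r_ic = 1.4, a = 0.2), class = "cav_time_graph")
  assign_identity_numbers(tg)
}

test_that("absent identities are flagged not-present", {
  tg <- make_branchy_tg_timeline()
  cavs <- lapply(0:9, function(t) {
    out <- list(as_cavity(matrix(c(0, 0, 0.2 * t, 2), 1), 1L, t))
    if (t >= 3 && t <= 5)
      out <- c(out, list(as_cavity(matrix(c(6, 0, 0, 1.5), 1), 2L, t)))
    out
  })
  pr <- evolution_profile(tg, cavs, axis = c(0, 0, 1))
  branch <- pr[pr$identity == 2L, ]
  expect_equal(branch$present, 0:9 %in% 3:5)
  expect_true(all(is.na(branch$min_proj[!branch$present])))
  trunk <- pr[pr$identity == 1L, ]
  expect_equal(trunk$min_proj, 0.2 * (0:9) - 2)
  expect_equal(trunk$max_proj, 0.2 * (0:9) + 2)
})

test_that("single-frame residence equals the occupancy grid", {
  s <- matrix(c(0, 0, 0, 1), 1)
  rg <- residence_probability(list(s), a = 0.2)
  og <- occupancy_grid(s, a = 0.2)
  expect_true(all(rg$values %in% c(0, 1)))
  expect_equal(rg$values, as.numeric(og$values))
  expect_equal(rg$origin, og$origin)
  expect_equal(rg$dims, og$dims)
})

test_that("a static cavity over 10 frames has core value exactly 1", {
  s <- matrix(c(0, 0, 0, 1.5), 1)
  rg <- residence_probability(rep(list(s), 10L), a = 0.2)
  # the cube containing the center
  d <- rg$dims
  ctr <- floor((c(0, 0, 0) - rg$origin) / rg$a)
  idx <- 1 + ctr[1] + d[1] * (ctr[2] + d[2] * ctr[3])
  expect_identical(rg$values[idx], 1)
  expect_true(all(rg$values >= 0 & rg$values <= 1))
})

test_that("a sphere present 3 of 4 frames scores 0.75 at its center", {
  s <- matrix(c(0, 0, 0, 1), 1)
  none <- matrix(numeric(0), 0, 4)
  rg <- residence_probability(list(s, s, none, s), a = 0.2)
  d <- rg$dims
  ctr <- floor((c(0, 0, 0) - rg$origin) / rg$a)
  idx <- 1 + ctr[1] + d[1] * (ctr[2] + d[2] * ctr[3])
  expect_identical(rg$values[idx], 0.75)
  # every value is a multiple of 1/T
  expect_true(all(abs(rg$values * 4 - round(rg$values * 4)) < 1e-12))
})

test_that("thresholding above (T-1/2)/T recovers the all-frame intersection", {
  s1 <- matrix(c(0, 0, 0, 1.2), 1)
  s2 <- matrix(c(0.6, 0, 0, 1.2), 1)
  rg <- residence_probability(list(s1, s2), a = 0.2)
  stable <- rg$values > (2 - 0.5) / 2
  # cubes inside both spheres, on the same grid
  o1 <- cpp_occ <- cavitrace:::cpp_grid_occupancy(rg$origin, rg$dims, rg$a,
                                                  s1[, 1:3, drop = FALSE],
                                                  s1[, 4])
  o2 <- cavitrace:::cpp_grid_occupancy(rg$origin, rg$dims, rg$a,
                                       s2[, 1:3, drop = FALSE], s2[, 4])
  expect_equal(stable, as.logical(o1 & o2))
})

test_that("stable-core counting finds the connected high-residence core", {
  s1 <- matrix(c(0, 0, 0, 1.2), 1)
  s2 <- matrix(c(0.6, 0, 0, 1.2), 1)
  rg <- residence_probability(list(s1, s2), a = 0.2)
  core <- stable_core_count(rg, 0.75)
  expect_gt(core$n_above, 0L)
  expect_equal(core$largest_component, core$n_above)  # one lens, connected
  none <- stable_core_count(rg, 1.0)
  expect_identical(none$n_above, 0L)
})
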