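# split and merge events of a time graph: a split is a node with two or
# more forward edges, a merge a node with two or more backward edges; the
# event is recorded at the later frame
time_graph_events <- function(tg) {
  edges <- tg$edges
  nodes <- tg$nodes
  ev <- list()
  if (nrow(edges)) {
    idy <- function(f, cv) {
      v <- nodes$identity[nodes$frame == f & nodes$cavity_id == cv]
      if (length(v)) v else NA_integer_
    }
    for (t0 in sort(unique(edges$frame_t))) {
      t1 <- next_frame_of(tg, t0)
      sub <- edges[edges$frame_t == t0, , drop = FALSE]
      for (cv in unique(sub$cav_t)) {
        kids <- sub$cav_t1[sub$cav_t == cv]
        if (length(kids) >= 2L)
          ev[[length(ev) + 1L]] <- data.frame(
            frame = t1, type = "split",
            parents = as.character(idy(t0, cv)),
            children = paste(sort(vapply(kids, function(k) idy(t1, k),
                                         numeric(1))), collapse = ","))
      }
      for (cv in unique(sub$cav_t1)) {
        par <- sub$cav_t[sub$cav_t1 == cv]
        if (length(par) >= 2L)
          ev[[length(ev) + 1L]] <- data.frame(
            frame = t1, type = "merge",
            parents = paste(sort(vapply(par, function(p) idy(t0, p),
                                        numeric(1))), collapse = ","),
            children = as.character(idy(t1, cv)))
      }
    }
  }
  if (!length(ev))
    return(data.frame(frame = numeric(0), type = character(0),
                      parents = character(0), children = character(0)))
  ev <- do.call(rbind, ev)
  ev[order(ev$frame, ev$type), , drop = FALSE]
}

#' Split-and-merge timeline layout
#'
#' Produces the data behind the split/merge graph: one polyline per traced
#' identity, running left to right over time, with a per-frame row index
#' (identities simply ordered top to bottom) and the cavity volume as line
#' thickness, plus an explicit table of split and merge events (frame,
#' parent identities, child identities).
#'
#' @param tg A `cav_time_graph` with identities assigned.
#' @param t_range Optional numeric length-2 vector restricting the frames.
#' @return List with `polylines` (data frame: frame, identity, row, volume)
#'   and `events` (data frame: frame, type, parents, children).
#' @export
split_merge_timeline <- function(tg, t_range = NULL) {
  nodes <- tg$nodes
  if (!is.null(t_range))
    nodes <- nodes[nodes$frame >= t_range[1] & nodes$frame <= t_range[2], ,
                   drop = FALSE]
  if (!nrow(nodes))
    return(list(polylines = data.frame(frame = numeric(0),
                                       identity = numeric(0),
                                       row = integer(0), volume = numeric(0)),
                events = data.frame(frame = numeric(0), type = character(0),
                                    parents = character(0),
                                    children = character(0))))
  poly <- do.call(rbind, lapply(sort(unique(nodes$frame)), function(f) {
    sub <- nodes[nodes$frame == f, , drop = FALSE]
    sub <- sub[order(sub$identity), , drop = FALSE]
    data.frame(frame = f, identity = sub$identity,
               row = seq_len(nrow(sub)), volume = sub$volume)
  }))
  ev <- time_graph_events(tg)
  if (!is.null(t_range))
    ev <- ev[ev$frame >= t_range[1] & ev$frame <= t_range[2], , drop = FALSE]
  list(polylines = poly, events = ev)
}

#' Evolution of cavity extents along an axis
#'
#' For each identity and frame, the projection interval of the cavity onto
#' a user-chosen direction (for membrane proteins typically the membrane
#' normal): minimum over the cavity spheres of (center projection - r) and
#' maximum of (center projection + r).
#'
#' @param tg A `cav_time_graph`.
#' @param cavities_by_frame The per-frame cavity lists the graph was built
#'   from.
#' @param axis Direction 3-vector (normalized internally; must be nonzero).
#' @return Data frame: identity, frame, present, min_proj, max_proj (the
#'   projections are `NA` where the identity is absent).
#' @export
evolution_profile <- function(tg, cavities_by_frame, axis = c(0, 0, 1)) {
  axis <- as.numeric(axis)
  nr <- sqrt(sum(axis^2))
  if (nr < 1e-12) stop("`axis` must be a nonzero vector")
  axis <- axis / nr
  nodes <- tg$nodes
  frames <- tg$frame_indices
  ids <- sort(unique(nodes$identity))
  out <- list()
  for (id in ids) {
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      sel <- nodes$frame == f & nodes$identity == id
      if (any(sel)) {
        cv_id <- nodes$cavity_id[sel][1]
        cavs <- cavities_by_frame[[fi]]
        cv <- cavs[[which(vapply(cavs, `[[`, numeric(1), "cavity_id") ==
                            cv_id)[1]]]
        pr <- as.vector(cv$spheres[, 1:3, drop = FALSE] %*% axis)
        out[[length(out) + 1L]] <- data.frame(
          identity = id, frame = f, present = TRUE,
          min_proj = min(pr - cv$spheres[, 4]),
          max_proj = max(pr + cv$spheres[, 4]))
      } else {
        out[[length(out) + 1L]] <- data.frame(
          identity = id, frame = f, present = FALSE,
          min_proj = NA_real_, max_proj = NA_real_)
      }
    }
  }
  do.call(rbind, out)
}

#' Residence-probability grid of a (dynamic) cavity
#'
#' For each cube of a regular grid spanning the union bounding box of all
#' frames' sphere sets, the proportion of frames in which the cube center
#' lies inside at least one sphere of that frame's set. Applicable to the
#' cavities of a selected dynamic path as well as to all cavities over a
#' whole time interval. Values are k / T with T the number of frames.
#'
#' @param cavity_sets_per_frame List (one per frame) of m x 4 sphere
#'   matrices or `cav_cavity` objects; an empty matrix marks a frame
#'   without the cavity.
#' @param a Cube side length in Angstrom.
#' @param frame_range Optional length-2 vector recorded in the result.
#' @return A `cav_residence_grid`: a [volume_grid()] with values in
#'   \[0, 1\] plus `n_frames` and `frame_range`.
#' @export
residence_probability <- function(cavity_sets_per_frame, a = 0.2,
                                  frame_range = NULL) {
  if (!length(cavity_sets_per_frame)) stop("need at least one frame")
  if (a <= 0) stop("`a` must be > 0")
  sets <- lapply(cavity_sets_per_frame, function(x) {
    if (inherits(x, "cav_cavity")) x$spheres
    else if (is.list(x) && !is.matrix(x))
      do.call(rbind, lapply(x, cavity_spheres))
    else x
  })
  nonempty <- Filter(function(s) !is.null(s) && nrow(s), sets)
  if (!length(nonempty)) stop("all frames are empty")
  lo <- apply(do.call(rbind, lapply(nonempty, function(s)
    apply(s[, 1:3, drop = FALSE] - s[, 4], 2L, min))), 2L, min)
  hi <- apply(do.call(rbind, lapply(nonempty, function(s)
    apply(s[, 1:3, drop = FALSE] + s[, 4], 2L, max))), 2L, max)
  dims <- grid_dims(lo, hi, a)
  counts <- integer(prod(dims))
  for (s in sets) {
    if (is.null(s) || !nrow(s)) next
    counts <- counts + cpp_grid_occupancy(lo, dims, a,
                                          s[, 1:3, drop = FALSE], s[, 4])
  }
  g <- volume_grid(lo, dims, a, counts / length(sets))
  g$n_frames <- length(sets)
  g$frame_range <- frame_range
  class(g) <- c("cav_residence_grid", class(g))
  g
}

#' Stable-core summary of a residence grid
#'
#' Reports, for a given residence-probability threshold, the number of
#' cubes above the threshold and the size of their largest 6-connected
#' component (the "stable core" a maximum-intensity projection would
#' highlight).
#'
#' @param grid A `cav_residence_grid` (or any [volume_grid()]).
#' @param threshold Residence probability threshold (cubes with value
#'   strictly greater are counted).
#' @return List with `n_above` and `largest_component`.
#' @export
stable_core_count <- function(grid, threshold) {
  d <- grid$dims
  above <- which(grid$values > threshold)
  if (!length(above)) return(list(n_above = 0L, largest_component = 0L))
  ijk <- arrayInd(above, d)
  key <- (ijk[, 1] - 1L) + d[1] * ((ijk[, 2] - 1L) + d[2] * (ijk[, 3] - 1L))
  idx_of <- stats::setNames(seq_along(above), key)
  el <- list()
  offs <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  for (o in seq_len(3L)) {
    nb <- sweep(ijk, 2L, offs[o, ], `+`)
    ok <- nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    nb_key <- (nb[, 1] - 1L) + d[1] * ((nb[, 2] - 1L) + d[2] * (nb[, 3] - 1L))
    hit <- ok & as.character(nb_key) %in% names(idx_of)
    if (any(hit))
      el[[length(el) + 1L]] <- cbind(which(hit),
                                     idx_of[as.character(nb_key[hit])])
  }
  ig <- igraph::make_empty_graph(n = length(above), directed = FALSE)
  if (length(el))
    ig <- igraph::add_edges(ig, t(do.call(rbind, el)))
  comp <- igraph::components(ig)
  list(n_above = length(above), largest_component = max(comp$csize))
}

#' Export timeline tables as CSV
#'
#' Writes the split/merge polylines and events of [split_merge_timeline()]
#' (files `timeline.csv`, `events.csv`) or an [evolution_profile()] table
#' (`evolution.csv`) into a directory.
#'
#' @param timeline Result of [split_merge_timeline()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
export_timeline_csv <- function(timeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(timeline$polylines, file.path(dir, "timeline.csv"),
                   row.names = FALSE)
  utils::write.csv(timeline$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname export_timeline_csv
#' @param profile Result of [evolution_profile()].
#' @export
export_evolution_csv <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(profile, file.path(dir, "evolution.csv"),
                   row.names = FALSE)
  invisible(dir)
}
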