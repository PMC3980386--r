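#' Correspondence edges between cavities of consecutive frames
#'
#' Two cavities of consecutive frames correspond when some empty sphere of
#' the first and some empty sphere of the second intersect with an
#' inscribed intersection circle of radius strictly greater than r_ic (so a
#' probe of that radius can pass from one cavity into the other without
#' leaving their intersection). Each emitted edge carries the maximal
#' circle radius over all sphere pairs and the grid intersection volume of
#' the two cavities.
#'
#' @param cavs_t,cavs_t1 Lists of `cav_cavity` objects from frames t and
#'   t + 1.
#' @param r_ic Minimal intersection-circle radius in Angstrom; sensibly
#'   equal (or similar) to the probe radius used for filtering. Default 1.4.
#' @param a Cube side for the intersection volumes.
#' @return Data frame with columns `cav_t`, `cav_t1`, `circle_radius`,
#'   `intersection_volume`.
#' @export
map_cavities_between_frames <- function(cavs_t, cavs_t1, r_ic = 1.4,
                                        a = 0.2) {
  out <- list()
  for (i in seq_along(cavs_t)) {
    for (j in seq_along(cavs_t1)) {
      s1 <- cavs_t[[i]]$spheres; s2 <- cavs_t1[[j]]$spheres
      # quick reject via bounding boxes grown by r_ic
      b1 <- cavs_t[[i]]$aabb; b2 <- cavs_t1[[j]]$aabb
      if (any(pmax(b1[1, ], b2[1, ]) >= pmin(b1[2, ], b2[2, ]))) next
      d2 <- outer(rowSums(s1[, 1:3, drop = FALSE]^2), rep(1, nrow(s2))) +
        outer(rep(1, nrow(s1)), rowSums(s2[, 1:3, drop = FALSE]^2)) -
        2 * tcrossprod(s1[, 1:3, drop = FALSE], s2[, 1:3, drop = FALSE])
      d <- sqrt(pmax(0, d2))
      circ <- intersection_circle_vec(as.vector(d),
                                      rep(s1[, 4], times = nrow(s2)),
                                      rep(s2[, 4], each = nrow(s1)))
      mx <- suppressWarnings(max(circ, na.rm = TRUE))
      if (is.finite(mx) && mx > r_ic) {
        out[[length(out) + 1L]] <- data.frame(
          cav_t = cavs_t[[i]]$cavity_id, cav_t1 = cavs_t1[[j]]$cavity_id,
          circle_radius = mx,
          intersection_volume = cavity_intersection_volume(
            cavs_t[[i]], cavs_t1[[j]], a))
      }
    }
  }
  if (!length(out))
    return(data.frame(cav_t = integer(0), cav_t1 = integer(0),
                      circle_radius = numeric(0),
                      intersection_volume = numeric(0)))
  do.call(rbind, out)
}

#' Build the time graph of a trajectory's cavities
#'
#' Nodes are (frame, cavity) pairs; undirected edges connect corresponding
#' cavities of consecutive frames (see [map_cavities_between_frames()]).
#' Splits (one cavity mapping to several in the next frame) and merges
#' (several to one) appear naturally as node degrees. Node volumes are
#' computed once at grid spacing `a`. Identities are assigned with
#' [assign_identity_numbers()].
#'
#' @param cavities_by_frame List (one element per frame, in time order) of
#'   lists of `cav_cavity` objects.
#' @param frame_indices Optional integer vector of frame indices; defaults
#'   to indices recorded in the cavities (or 0, 1, ... when absent).
#' @param r_ic Minimal intersection-circle radius (Angstrom).
#' @param a Cube side for volumes and intersection volumes.
#' @return An object of class `cav_time_graph` with `nodes` (data frame:
#'   frame, cavity_id, volume, identity) and `edges` (data frame: frame_t,
#'   cav_t, cav_t1, circle_radius, intersection_volume, matched).
#' @export
build_time_graph <- function(cavities_by_frame, frame_indices = NULL,
                             r_ic = 1.4, a = 0.2) {
  n_frames <- length(cavities_by_frame)
  if (is.null(frame_indices)) {
    frame_indices <- vapply(seq_len(n_frames), function(t) {
      cv <- cavities_by_frame[[t]]
      if (length(cv)) cv[[1]]$frame_index else t - 1L
    }, numeric(1))
  }
  nodes <- do.call(rbind, lapply(seq_len(n_frames), function(t) {
    cv <- cavities_by_frame[[t]]
    if (!length(cv)) return(NULL)
    data.frame(frame = frame_indices[t],
               cavity_id = vapply(cv, `[[`, numeric(1), "cavity_id"),
               volume = vapply(cv, cavity_volume, numeric(1), a = a))
  }))
  if (is.null(nodes))
    nodes <- data.frame(frame = numeric(0), cavity_id = numeric(0),
                        volume = numeric(0))
  nodes$identity <- NA_integer_
  edges <- do.call(rbind, lapply(seq_len(max(0L, n_frames - 1L)), function(t) {
    em <- map_cavities_between_frames(cavities_by_frame[[t]],
                                      cavities_by_frame[[t + 1L]], r_ic, a)
    if (!nrow(em)) return(NULL)
    cbind(frame_t = frame_indices[t], em)
  }))
  if (is.null(edges))
    edges <- data.frame(frame_t = numeric(0), cav_t = integer(0),
                        cav_t1 = integer(0), circle_radius = numeric(0),
                        intersection_volume = numeric(0))
  tg <- structure(list(nodes = nodes, edges = edges,
                       frame_indices = frame_indices,
                       r_ic = r_ic, a = a),
                  class = "cav_time_graph")
  assign_identity_numbers(tg)
}

#' @export
print.cav_time_graph <- function(x, ...) {
  cat(sprintf("<cav_time_graph> %d nodes over %d frames, %d edges\n",
              nrow(x$nodes), length(unique(x$nodes$frame)), nrow(x$edges)))
  invisible(x)
}

#' Assign identification numbers by greedy volume-sorted matching
#'
#' Cavities of the first frame are numbered consecutively in cavity order.
#' For each frame pair (t, t + 1) the bipartite correspondence edges are
#' sorted by intersection volume, largest first (ties broken by ascending
#' (identity at t, cavity id at t + 1)); edges are matched greedily,
#' skipping any edge with an already-matched endpoint. A matched cavity
#' inherits the identity of its partner; every unmatched cavity of t + 1
#' gets a fresh, never-used identity, so identities are unique within each
#' frame.
#'
#' @param tg A `cav_time_graph`.
#' @return The graph with `nodes$identity` filled and `edges$matched` set.
#' @export
assign_identity_numbers <- function(tg) {
  nodes <- tg$nodes
  edges <- tg$edges
  if (!nrow(nodes)) {
    tg$nodes <- nodes; return(tg)
  }
  frames <- sort(unique(nodes$frame))
  first <- nodes$frame == frames[1]
  ord <- order(nodes$cavity_id[first])
  nodes$identity[first][ord] <- seq_len(sum(first))
  next_id <- sum(first) + 1L
  edges$matched <- rep(FALSE, nrow(edges))
  for (fi in seq_len(length(frames) - 1L)) {
    t0 <- frames[fi]; t1 <- frames[fi + 1L]
    sel <- which(edges$frame_t == t0)
    id_of <- function(cav) nodes$identity[nodes$frame == t0 &
                                            nodes$cavity_id == cav]
    if (length(sel)) {
      ids_t <- vapply(edges$cav_t[sel], function(cv) {
        v <- id_of(cv); if (length(v)) v else NA_integer_
      }, numeric(1))
      keep <- !is.na(ids_t)           # skip edges from removed nodes
      sel <- sel[keep]; ids_t <- ids_t[keep]
      o <- order(-edges$intersection_volume[sel], ids_t, edges$cav_t1[sel])
      matched_t <- integer(0); matched_t1 <- integer(0)
      for (k in o) {
        e <- sel[k]
        if (edges$cav_t[e] %in% matched_t ||
            edges$cav_t1[e] %in% matched_t1) next
        matched_t <- c(matched_t, edges$cav_t[e])
        matched_t1 <- c(matched_t1, edges$cav_t1[e])
        edges$matched[e] <- TRUE
        nodes$identity[nodes$frame == t1 &
                         nodes$cavity_id == edges$cav_t1[e]] <- ids_t[k]
      }
    }
    un <- which(nodes$frame == t1 & is.na(nodes$identity))
    un <- un[order(nodes$cavity_id[un])]
    for (u in un) {
      nodes$identity[u] <- next_id
      next_id <- next_id + 1L
    }
  }
  tg$nodes <- nodes
  tg$edges <- edges
  tg
}

#' Remove dead-end cavity chains from a time graph
#'
#' A dead end is a cavity that cannot be traced to the following frame.
#' Dead ends are removed and traced back in time until a split in the time
#' graph (a node retaining another forward edge) or the start of the traced
#' range is reached. Cavities alive through the final frame are retained:
#' no forward frame exists to demand a continuation.
#'
#' @param tg A `cav_time_graph` with identities assigned.
#' @return The pruned graph.
#' @export
remove_dead_ends <- function(tg) {
  nodes <- tg$nodes
  edges <- tg$edges
  if (!nrow(nodes)) return(tg)
  t_max <- max(nodes$frame)
  repeat {
    has_fwd <- mapply(function(f, cv)
      any(edges$frame_t == f & edges$cav_t == cv),
      nodes$frame, nodes$cavity_id)
    dead <- which(nodes$frame < t_max & !has_fwd)
    if (!length(dead)) break
    dead_keys <- paste(nodes$frame[dead], nodes$cavity_id[dead])
    nodes <- nodes[-dead, , drop = FALSE]
    if (nrow(edges)) {
      e_from <- paste(edges$frame_t, edges$cav_t)
      e_to <- paste(next_frame_of(tg, edges$frame_t), edges$cav_t1)
      edges <- edges[!(e_from %in% dead_keys) & !(e_to %in% dead_keys), ,
                     drop = FALSE]
    }
  }
  tg$nodes <- nodes
  tg$edges <- edges
  tg
}

prev_frame <- function(tg, f) {
  fr <- tg$frame_indices
  i <- match(f, fr)
  if (is.na(i) || i == 1L) NA else fr[i - 1L]
}

next_frame_of <- function(tg, f) {
  fr <- tg$frame_indices
  fr[match(f, fr) + 1L]
}

#' Forbid splits in a time graph
#'
#' Keeps, at each frame transition, only the greedily matched cavities of
#' frame t + 1 whose predecessors are themselves kept; unmatched cavities
#' reachable via split edges are dropped together with their descendants.
#' Cavities with no correspondence edge at all (genuinely new cavities)
#' start their own chains. The result is one simple path per identity.
#'
#' @param tg A `cav_time_graph` with identities assigned.
#' @return The pruned graph; only matched edges remain.
#' @export
forbid_splits <- function(tg) {
  nodes <- tg$nodes
  edges <- tg$edges
  if (!nrow(nodes)) return(tg)
  frames <- sort(unique(nodes$frame))
  kept <- paste(nodes$frame, nodes$cavity_id)[nodes$frame == frames[1]]
  for (fi in seq_len(length(frames) - 1L)) {
    t0 <- frames[fi]; t1 <- frames[fi + 1L]
    at_t1 <- which(nodes$frame == t1)
    for (u in at_t1) {
      cv <- nodes$cavity_id[u]
      inc <- edges$frame_t == t0 & edges$cav_t1 == cv
      if (!any(inc)) {                       # newborn: keep
        kept <- c(kept, paste(t1, cv)); next
      }
      m <- inc & edges$matched &
        paste(t0, edges$cav_t) %in% kept
      if (any(m)) kept <- c(kept, paste(t1, cv))
    }
  }
  keys <- paste(nodes$frame, nodes$cavity_id)
  nodes <- nodes[keys %in% kept, , drop = FALSE]
  e_from <- paste(edges$frame_t, edges$cav_t)
  e_to <- paste(next_frame_of(tg, edges$frame_t), edges$cav_t1)
  edges <- edges[edges$matched & e_from %in% kept & e_to %in% kept, ,
                 drop = FALSE]
  tg$nodes <- nodes
  tg$edges <- edges
  tg
}

#' Extract a dynamic path through the time graph
#'
#' A dynamic cavity is a chain of per-frame cavities connected by
#' correspondence edges, one node per frame. Given an ordered list of
#' selected nodes (at least start and end, optionally intermediate
#' selections), each leg is found by a depth-first search moving forward in
#' time, preferring branches with larger intersection volume.
#'
#' @param tg A `cav_time_graph`.
#' @param selections List of length-2 vectors `c(frame, cavity_id)` in
#'   strictly increasing frame order, or strings `"frame:cavity"`.
#' @return An object of class `cav_dynamic_path` with `found` (logical) and
#'   `nodes` (data frame frame, cavity_id, identity); `found = FALSE` with
#'   empty nodes when the selections are not connected.
#' @export
extract_dynamic_path <- function(tg, selections) {
  if (length(selections) < 2L) stop("need at least 2 selections")
  parse_sel <- function(s) {
    if (is.character(s)) as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    else as.numeric(s)
  }
  sels <- lapply(selections, parse_sel)
  fr <- vapply(sels, `[`, numeric(1), 1L)
  if (any(diff(fr) <= 0)) stop("selections must be in increasing frame order")
  path <- list(sels[[1]])
  for (leg in seq_len(length(sels) - 1L)) {
    seg <- dfs_leg(tg, sels[[leg]], sels[[leg + 1L]])
    if (is.null(seg))
      return(structure(list(found = FALSE,
                            nodes = data.frame(frame = numeric(0),
                                               cavity_id = numeric(0),
                                               identity = numeric(0))),
                       class = "cav_dynamic_path"))
    path <- c(path, seg[-1L])
  }
  m <- do.call(rbind, path)
  idy <- mapply(function(f, cv) {
    v <- tg$nodes$identity[tg$nodes$frame == f & tg$nodes$cavity_id == cv]
    if (length(v)) v else NA_integer_
  }, m[, 1], m[, 2])
  structure(list(found = TRUE,
                 nodes = data.frame(frame = m[, 1], cavity_id = m[, 2],
                                    identity = idy)),
            class = "cav_dynamic_path")
}

# DFS forward in time from `from` to `to`, larger intersection volume first
dfs_leg <- function(tg, from, to) {
  stack <- list(list(from))
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- cur[[length(cur)]]
    if (node[1] == to[1]) {
      if (node[2] == to[2]) return(cur)
      next
    }
    nxt <- which(tg$edges$frame_t == node[1] & tg$edges$cav_t == node[2])
    if (!length(nxt)) next
    nf <- next_frame_of(tg, node[1])
    # push smaller volumes first so larger volumes are explored first
    nxt <- nxt[order(tg$edges$intersection_volume[nxt])]
    for (e in nxt)
      stack[[length(stack) + 1L]] <- c(cur, list(c(nf, tg$edges$cav_t1[e])))
  }
  NULL
}

#' @export
print.cav_dynamic_path <- function(x, ...) {
  if (x$found)
    cat(sprintf("<cav_dynamic_path> %d nodes, frames %g..%g\n",
                nrow(x$nodes), min(x$nodes$frame), max(x$nodes$frame)))
  else cat("<cav_dynamic_path> no path\n")
  invisible(x)
}

#' Export a time graph
#'
#' JSON (nodes with frame, cavity id, identity, volume; edges with circle
#' radius and intersection volume) or GraphML via igraph.
#'
#' @param tg A `cav_time_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_time_graph_json <- function(tg, path) {
  jsonlite::write_json(list(nodes = tg$nodes, edges = tg$edges),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname export_time_graph_json
#' @export
export_time_graph_graphml <- function(tg, path) {
  ig <- time_graph_to_igraph(tg)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

time_graph_to_igraph <- function(tg) {
  nm <- paste(tg$nodes$frame, tg$nodes$cavity_id, sep = ":")
  ig <- igraph::make_empty_graph(n = length(nm), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = nm)
  ig <- igraph::set_vertex_attr(ig, "frame", value = tg$nodes$frame)
  ig <- igraph::set_vertex_attr(ig, "cavity", value = tg$nodes$cavity_id)
  ig <- igraph::set_vertex_attr(ig, "identity", value = tg$nodes$identity)
  ig <- igraph::set_vertex_attr(ig, "volume", value = tg$nodes$volume)
  if (nrow(tg$edges)) {
    from <- paste(tg$edges$frame_t, tg$edges$cav_t, sep = ":")
    to <- paste(next_frame_of(tg, tg$edges$frame_t), tg$edges$cav_t1,
                sep = ":")
    ig <- igraph::add_edges(ig, rbind(match(from, nm), match(to, nm)))
    ig <- igraph::set_edge_attr(ig, "circle_radius",
                                value = tg$edges$circle_radius)
    ig <- igraph::set_edge_attr(ig, "intersection_volume",
                                value = tg$edges$intersection_volume)
  }
  ig
}
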