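#' Run configuration for the batch pipeline
#'
#' Collects every tunable parameter of the per-frame pre-processing and the
#' tracing stage. Defaults follow the package-wide choices: probe radius
#' 1.4 A (a water-sized probe), occlusion threshold 0.15, cube side 0.2 A,
#' and r_ic equal to the probe radius.
#'
#' @param input Input path (multi-model PDB) or `NULL` when a trajectory
#'   object is passed to [run_preprocess()] directly.
#' @param output_dir Directory for cached per-frame results and exports.
#' @param probe_radius,occlusion_threshold,n_rays Filter parameters, see
#'   [filter_params()].
#' @param r_ic Minimal intersection-circle radius for tracing (A).
#' @param a Cube side length for volumes and grids (A).
#' @param seed Integer seed controlling perturbation and ray directions.
#' @param epsilon Perturbation amplitude (A).
#' @param bounding_margin Voronoi bounding-box margin (A).
#' @param max_clearance Vertex clearance bound passed to
#'   [compute_voronoi_graph()] (`Inf` = exhaustive).
#' @param frame_range Optional length-2 integer vector of time indices.
#' @param axis Direction for evolution profiles.
#' @param exclude_resid Residue names dropped when reading PDB input.
#' @param uniform_radius Optional single radius overriding per-element
#'   radii (useful for fixture sphere data).
#' @return An object of class `cav_run_config`.
#' @export
run_config <- function(input = NULL, output_dir = tempfile("cavitrace-"),
                       probe_radius = 1.4, occlusion_threshold = 0.15,
                       n_rays = 256L, r_ic = probe_radius, a = 0.2,
                       seed = 1L, epsilon = 1e-6, bounding_margin = 5,
                       max_clearance = Inf, frame_range = NULL,
                       axis = c(0, 0, 1), exclude_resid = NULL,
                       uniform_radius = NULL) {
  structure(list(input = input, output_dir = output_dir,
                 probe_radius = probe_radius,
                 occlusion_threshold = occlusion_threshold,
                 n_rays = as.integer(n_rays), r_ic = r_ic, a = a,
                 seed = as.integer(seed), epsilon = epsilon,
                 bounding_margin = bounding_margin,
                 max_clearance = max_clearance, frame_range = frame_range,
                 axis = axis, exclude_resid = exclude_resid,
                 uniform_radius = uniform_radius),
            class = "cav_run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys match the arguments of [run_config()];
#' unknown keys raise an error. Values given in `...` override the file.
#'
#' @param path YAML file path.
#' @param ... Overrides, as in [run_config()].
#' @return A `cav_run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

log_line <- function(config, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n", sep = "", file = file.path(config$output_dir, "run.log"),
      append = TRUE)
  invisible(msg)
}

#' Per-frame pre-processing: static paths and cavities
#'
#' For every frame of the trajectory: perturb the atom positions (seed
#' derived from the run seed and the frame's time index), compute the
#' Voronoi graph, filter it by occlusion and probe radius, split it into
#' path components, and build the cavity sphere sets. Results are cached
#' as one JSON file per frame so the tracing stage never recomputes them;
#' all parameters are logged. A failing frame is reported with its index
#' and the run continues with the remaining frames.
#'
#' @param config A [run_config()].
#' @param traj Optional [trajectory()]; when `NULL`, `config$input` is read
#'   with [read_multimodel_pdb()].
#' @return A cavity store: list with `dir`, `frames` (time indices) and
#'   `config`, invisibly usable by [run_trace()].
#' @export
run_preprocess <- function(config, traj = NULL) {
  if (is.null(traj)) {
    if (is.null(config$input)) stop("no input: supply `traj` or config$input")
    traj <- read_multimodel_pdb(config$input,
                                exclude_resid = config$exclude_resid)
  }
  if (!is.null(config$uniform_radius))
    traj$frames <- lapply(traj$frames, function(f) {
      f$radii[] <- config$uniform_radius; f
    })
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  frames <- traj$frames
  if (!is.null(config$frame_range)) {
    ti <- vapply(frames, `[[`, integer(1), "time_index")
    frames <- frames[ti >= config$frame_range[1] &
                       ti <= config$frame_range[2]]
    if (!length(frames)) {
      warning("empty frame range: no frames processed")
      return(invisible(structure(list(dir = config$output_dir,
                                      frames = integer(0), config = config),
                                 class = "cav_cavity_store")))
    }
  }
  for (nm in setdiff(names(config), c("axis", "exclude_resid")))
    log_line(config, "param %s = %s", nm,
             paste(format(config[[nm]]), collapse = " "))
  log_line(config, "package cavitrace %s",
           as.character(utils::packageVersion("cavitrace")))
  done <- integer(0)
  for (f in frames) {
    ti <- f$time_index
    res <- tryCatch({
      pf <- perturb_positions(f, config$epsilon,
                              frame_seed(config$seed, ti))
      g <- compute_voronoi_graph(pf, config$bounding_margin,
                                 max_clearance = config$max_clearance)
      fg <- filter_graph(g, pf, filter_params(config$probe_radius,
                                              config$occlusion_threshold,
                                              config$n_rays, config$seed))
      comps <- connected_components(fg)
      cavs <- build_cavities(comps, fg, pf, config$probe_radius)
      export_cavities_json(cavs, frame_cache_path(config$output_dir, ti))
      log_line(config, "frame %d: %d cavities", ti, length(cavs))
      TRUE
    }, error = function(e) {
      warning(sprintf("frame %d failed: %s", ti, conditionMessage(e)))
      log_line(config, "frame %d FAILED: %s", ti, conditionMessage(e))
      FALSE
    })
    if (res) done <- c(done, ti)
  }
  invisible(structure(list(dir = config$output_dir, frames = done,
                           config = config),
                      class = "cav_cavity_store"))
}

frame_cache_path <- function(dir, time_index)
  file.path(dir, sprintf("cavities_frame_%05d.json", time_index))

#' Load a cavity store written by [run_preprocess()]
#'
#' @param dir Store directory.
#' @return A `cav_cavity_store`.
#' @export
load_cavity_store <- function(dir) {
  files <- sort(list.files(dir, "^cavities_frame_[0-9]+\\.json$"))
  frames <- as.integer(sub("cavities_frame_([0-9]+)\\.json", "\\1", files))
  structure(list(dir = dir, frames = frames, config = NULL),
            class = "cav_cavity_store")
}

store_cavities <- function(store) {
  lapply(store$frames, function(ti)
    read_cavities_json(frame_cache_path(store$dir, ti)))
}

#' Tracing stage: time graph, identities and exports
#'
#' Builds the time graph from a cavity store, assigns identification
#' numbers, optionally removes dead ends and/or forbids splits, and writes
#' the exports: `volumes.csv` (frame, cavity_id, identity_id, volume_A3,
#' water_capacity), `timeline.csv` + `events.csv`, `evolution.csv`,
#' `time_graph.graphml`, `time_graph.json`, and optionally a residence
#' grid `residence.dx`.
#'
#' @param config A [run_config()].
#' @param store A cavity store from [run_preprocess()] or
#'   [load_cavity_store()].
#' @param drop_dead_ends Apply [remove_dead_ends()].
#' @param forbid_splits Apply [forbid_splits()].
#' @param residence Write `residence.dx` with the residence probability of
#'   all cavities over the traced range.
#' @param residence_identity Optional identity number restricting the
#'   residence grid to one traced cavity.
#' @return The `cav_time_graph`, invisibly.
#' @export
run_trace <- function(config, store, drop_dead_ends = FALSE,
                      forbid_splits = FALSE, residence = FALSE,
                      residence_identity = NULL) {
  if (!length(store$frames)) stop("cavity store is empty")
  gaps <- setdiff(seq(min(store$frames), max(store$frames)), store$frames)
  if (length(gaps))
    stop("missing frames in store: ", paste(gaps, collapse = ", "))
  cavs <- store_cavities(store)
  tg <- build_time_graph(cavs, frame_indices = store$frames,
                         r_ic = config$r_ic, a = config$a)
  if (drop_dead_ends) tg <- remove_dead_ends(tg)
  if (forbid_splits) tg <- forbid_splits(tg)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  vols <- tg$nodes[order(tg$nodes$frame, tg$nodes$cavity_id), ]
  utils::write.csv(
    data.frame(frame_index = vols$frame, cavity_id = vols$cavity_id,
               identity_id = vols$identity, volume_A3 = vols$volume,
               water_capacity = water_capacity(vols$volume)),
    file.path(out, "volumes.csv"), row.names = FALSE)
  export_timeline_csv(split_merge_timeline(tg), out)
  export_evolution_csv(evolution_profile(tg, cavs, config$axis), out)
  export_time_graph_graphml(tg, file.path(out, "time_graph.graphml"))
  export_time_graph_json(tg, file.path(out, "time_graph.json"))
  if (residence) {
    sets <- residence_sets(tg, cavs, residence_identity)
    rg <- residence_probability(sets, a = config$a,
                                frame_range = range(store$frames))
    export_grid_dx(rg, file.path(out, "residence.dx"))
  }
  log_line(config, "trace: %d nodes, %d edges, %d identities",
           nrow(tg$nodes), nrow(tg$edges),
           length(unique(tg$nodes$identity)))
  invisible(tg)
}

# per-frame sphere sets for the residence grid, optionally restricted to
# one identity; empty frames contribute zero occupancy
residence_sets <- function(tg, cavs, identity = NULL) {
  lapply(seq_along(cavs), function(fi) {
    f <- tg$frame_indices[fi]
    sel <- tg$nodes$frame == f
    if (!is.null(identity)) sel <- sel & tg$nodes$identity == identity
    ids <- tg$nodes$cavity_id[sel]
    keep <- Filter(function(cv) cv$cavity_id %in% ids, cavs[[fi]])
    if (!length(keep)) matrix(numeric(0), 0L, 4L)
    else do.call(rbind, lapply(keep, `[[`, "spheres"))
  })
}
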