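# deterministic, near-uniform point set on the unit sphere (Fibonacci
# lattice); no RNG so fixtures regenerate bit-identically
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * (seq_len(n) - 1L)
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Four-atom tetrahedral cage fixture
#'
#' Four equal spheres at the vertices of a regular tetrahedron. The Voronoi
#' diagram has exactly one interior vertex, at the centroid, with clearance
#' equal to the tetrahedron circumradius minus the atom radius:
#' edge_length * sqrt(3/8) - atom_radius. The closed-form value is attached
#' as the `ground_truth` attribute.
#'
#' @param edge_length Tetrahedron edge length in Angstrom.
#' @param atom_radius Sphere radius in Angstrom.
#' @return A [sphere_frame()] with attribute `ground_truth` (list with
#'   `clearance` and `center`).
#' @export
make_tetra_cage <- function(edge_length = 2, atom_radius = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v <- v * edge_length / (2 * sqrt(2))
  fr <- sphere_frame(v, rep(atom_radius, 4L))
  attr(fr, "ground_truth") <- list(
    clearance = edge_length * sqrt(3 / 8) - atom_radius,
    center = c(0, 0, 0))
  fr
}

#' Spherical shell pocket fixture
#'
#' Atoms on a spherical shell enclosing a cavity of approximately known
#' volume, optionally with a circular mouth opening around the +z pole. A
#' mouth angle of 0 gives a fully closed cage whose interior receives no
#' ambient light.
#'
#' @param shell_radius Radius of the shell the atom centers sit on (A).
#' @param atom_radius Atom sphere radius (A).
#' @param atom_count Number of lattice points on the full shell before the
#'   mouth is cut; their spacing must stay below 2 * atom_radius for a
#'   leak-free shell, otherwise an error is raised.
#' @param mouth_angle Half-angle of the mouth cone in degrees (0 = closed).
#' @return A [sphere_frame()] with attribute `ground_truth` (interior
#'   radius, approximate interior volume, mouth angle).
#' @export
make_shell_pocket <- function(shell_radius = 6, atom_radius = 1.5,
                              atom_count = 120L, mouth_angle = 0) {
  spacing <- sqrt(4 * pi * shell_radius^2 / atom_count)
  if (spacing >= 2 * atom_radius)
    stop(sprintf(
      "atom spacing %.2f A too coarse for leak-free shell (needs < %.2f A)",
      spacing, 2 * atom_radius))
  pts <- fibonacci_sphere(atom_count) * shell_radius
  if (mouth_angle > 0) {
    cosang <- pts[, 3] / shell_radius
    pts <- pts[cosang < cos(mouth_angle * pi / 180), , drop = FALSE]
  }
  fr <- sphere_frame(pts, rep(atom_radius, nrow(pts)))
  ir <- shell_radius - atom_radius
  attr(fr, "ground_truth") <- list(
    interior_radius = ir,
    interior_volume = 4 / 3 * pi * ir^3,
    mouth_angle = mouth_angle, spacing = spacing)
  fr
}

#' Drifting channel tube fixture
#'
#' An atom-lined straight tube along z spanning the fixture box, drifting
#' laterally by a constant offset per frame. The clearance on the tube axis
#' equals `bottleneck_radius`, so a probe with r_p below that value sees a
#' single path component spanning the tube in every frame.
#'
#' @param length Tube length in Angstrom.
#' @param bottleneck_radius Clearance on the axis (A); the atom rings sit
#'   at radius bottleneck_radius + atom_radius.
#' @param n_frames Number of trajectory frames.
#' @param drift Lateral (x) displacement per frame (A).
#' @param atom_radius Atom sphere radius (A).
#' @param ring_spacing Axial distance between atom rings (A).
#' @return A [trajectory()] with attribute `ground_truth` (axis, length,
#'   bottleneck radius).
#' @export
make_channel_tube <- function(length = 14, bottleneck_radius = 2,
                              n_frames = 3L, drift = 0.2,
                              atom_radius = 1, ring_spacing = 1.4) {
  wall_r <- bottleneck_radius + atom_radius
  zs <- seq(-length / 2, length / 2, by = ring_spacing)
  n_ring <- ceiling(2 * pi * wall_r / (1.5 * atom_radius))
  base <- do.call(rbind, lapply(seq_along(zs), function(k) {
    ang <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring +
      (k %% 2L) * pi / n_ring              # stagger alternate rings
    cbind(wall_r * cos(ang), wall_r * sin(ang), zs[k])
  }))
  frames <- lapply(seq_len(n_frames), function(t) {
    cen <- base
    cen[, 1] <- cen[, 1] + drift * (t - 1L)
    sphere_frame(cen, rep(atom_radius, nrow(cen)), time_index = t - 1L)
  })
  tr <- trajectory(frames)
  attr(tr, "ground_truth") <- list(axis = c(0, 0, 1), length = length,
                                   bottleneck_radius = bottleneck_radius)
  tr
}

#' Splitting-dumbbell trajectory with scripted events
#'
#' Two pocket volumes inside a closed capsule-shaped cage, joined through a
#' central constriction ring whose free radius follows a per-frame
#' schedule. While the constriction stays at or above the probe radius the
#' two pockets form one cavity; once it drops below, the cavity splits in
#' two. The ground-truth event script is derived from the schedule and the
#' probe radius alone, never from the algorithms under test.
#'
#' @param n_frames Number of frames; must match the schedule length.
#' @param neck_radius_schedule Per-frame free radius of the constriction
#'   (A). The default crosses the probe radius 1.4 A between frames 4 and
#'   5, producing a split at frame 5; pass the reverse for a merge.
#' @param probe_radius Probe radius the script is written for (A).
#' @param capsule_radius Inner cage radius (A).
#' @param capsule_half_length Half-length of the cylindrical cage part (A).
#' @param atom_radius Cage atom radius (A).
#' @return List with `trajectory` (a [trajectory()]), `event_script` (data
#'   frame: frame, event) and `params`.
#' @export
make_splitting_dumbbell <- function(n_frames = 10L,
                                    neck_radius_schedule =
                                      c(2.0, 1.9, 1.8, 1.7, 1.5,
                                        1.2, 1.0, 0.8, 0.65, 0.5),
                                    probe_radius = 1.4,
                                    capsule_radius = 4,
                                    capsule_half_length = 4,
                                    atom_radius = 1.2) {
  if (length(neck_radius_schedule) != n_frames)
    stop("`neck_radius_schedule` must have one value per frame")
  Rc <- capsule_radius; hl <- capsule_half_length; ra <- atom_radius
  spacing <- 1.5 * ra
  # cylindrical wall rings
  zs <- seq(-hl, hl, by = 1.6)
  n_ring <- ceiling(2 * pi * Rc / spacing)
  wall <- do.call(rbind, lapply(seq_along(zs), function(k) {
    ang <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring + (k %% 2L) * pi / n_ring
    cbind(Rc * cos(ang), Rc * sin(ang), zs[k])
  }))
  # hemispherical caps
  n_cap <- ceiling(2 * pi * Rc^2 / spacing^2)
  hemi <- fibonacci_sphere(2L * n_cap)
  hemi <- hemi[hemi[, 3] > 0.12, , drop = FALSE] * Rc  # leave junction to rings
  caps <- rbind(cbind(hemi[, 1], hemi[, 2], hemi[, 3] + hl),
                cbind(hemi[, 1], hemi[, 2], -hemi[, 3] - hl))
  # constriction ring at z = 0 (count fixed across frames)
  rho_max <- max(neck_radius_schedule) + ra
  n_neck <- ceiling(2 * pi * rho_max / (1.25 * ra))
  neck_ring <- function(rho) {
    ang <- 2 * pi * (seq_len(n_neck) - 1L) / n_neck
    cbind(rho * cos(ang), rho * sin(ang), 0)
  }
  frames <- lapply(seq_len(n_frames), function(t) {
    cen <- rbind(wall, caps, neck_ring(neck_radius_schedule[t] + ra))
    sphere_frame(cen, rep(ra, nrow(cen)), time_index = t - 1L)
  })
  open <- neck_radius_schedule >= probe_radius
  ev <- list()
  for (t in seq_len(n_frames - 1L)) {
    if (open[t] && !open[t + 1L])
      ev[[length(ev) + 1L]] <- data.frame(frame = t, event = "split")
    if (!open[t] && open[t + 1L])
      ev[[length(ev) + 1L]] <- data.frame(frame = t, event = "merge")
  }
  script <- if (length(ev)) do.call(rbind, ev)
  else data.frame(frame = integer(0), event = character(0))
  list(trajectory = trajectory(frames), event_script = script,
       params = list(n_frames = n_frames,
                     neck_radius_schedule = neck_radius_schedule,
                     probe_radius = probe_radius,
                     capsule_radius = Rc, capsule_half_length = hl,
                     atom_radius = ra))
}

#' Write a fixture to disk
#'
#' Emits a fixture trajectory as a multi-model PDB plus a JSON sidecar with
#' the construction parameters and, when present, the ground-truth event
#' script, so the batch pipeline can consume it end to end.
#'
#' @param fixture A [trajectory()], [sphere_frame()], or the list returned
#'   by [make_splitting_dumbbell()].
#' @param dir Output directory.
#' @param name Base file name.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fixture, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- if (inherits(fixture, "cav_trajectory")) fixture
  else if (inherits(fixture, "cav_frame")) trajectory(list(fixture))
  else fixture$trajectory
  pdb <- file.path(dir, paste0(name, ".pdb"))
  write_multimodel_pdb(traj, pdb)
  side <- list(ground_truth = attr(traj, "ground_truth"))
  if (is.list(fixture) && !inherits(fixture, c("cav_trajectory", "cav_frame"))) {
    side$params <- fixture$params
    side$event_script <- fixture$event_script
  }
  js <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA)
  invisible(c(pdb = pdb, json = js))
}
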