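#' Create a single-frame set of atom spheres
#'
#' A frame is the basic geometric input of the package: atom centers and van
#' der Waals radii for one time step of a trajectory, in Angstrom.
#'
#' @param centers Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param radii Numeric vector of van der Waals radii (Angstrom), one per
#'   atom; all must be positive.
#' @param time_index Integer time-step index (0-based, non-negative).
#' @param time_ps Optional physical time of the frame in picoseconds.
#' @return An object of class `cav_frame` with elements `centers`, `radii`,
#'   `time_index` and `time_ps`.
#' @export
sphere_frame <- function(centers, radii, time_index = 0L, time_ps = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L)
    stop("`centers` must be an n x 3 matrix")
  storage.mode(centers) <- "double"
  radii <- as.numeric(radii)
  if (length(radii) != nrow(centers))
    stop("`radii` must have one entry per row of `centers`")
  if (!all(is.finite(centers)))
    stop("all center coordinates must be finite")
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("all radii must be finite and > 0")
  time_index <- as.integer(time_index)
  if (is.na(time_index) || time_index < 0L)
    stop("`time_index` must be a non-negative integer")
  dimnames(centers) <- NULL
  structure(list(centers = centers, radii = radii,
                 time_index = time_index, time_ps = time_ps),
            class = "cav_frame")
}

#' @export
print.cav_frame <- function(x, ...) {
  cat(sprintf("<cav_frame> %d spheres, time_index %d\n",
              nrow(x$centers), x$time_index))
  invisible(x)
}

#' Assemble frames into a trajectory
#'
#' @param frames List of [sphere_frame()] objects with identical atom counts
#'   and strictly increasing `time_index`.
#' @param atom_labels Optional data frame of per-atom records (element,
#'   residue, atom name), one row per atom index.
#' @return An object of class `cav_trajectory`.
#' @export
trajectory <- function(frames, atom_labels = NULL) {
  if (!length(frames)) stop("`frames` must not be empty")
  if (!all(vapply(frames, inherits, logical(1), "cav_frame")))
    stop("all elements of `frames` must be cav_frame objects")
  counts <- vapply(frames, function(f) nrow(f$centers), integer(1))
  if (length(unique(counts)) != 1L)
    stop("all frames must have the same number of spheres")
  ti <- vapply(frames, function(f) f$time_index, integer(1))
  if (any(diff(ti) <= 0L))
    stop("frame time_index values must be strictly increasing")
  if (!is.null(atom_labels) && nrow(atom_labels) != counts[1])
    stop("`atom_labels` must have one row per atom")
  structure(list(frames = frames, atom_labels = atom_labels),
            class = "cav_trajectory")
}

#' @export
print.cav_trajectory <- function(x, ...) {
  cat(sprintf("<cav_trajectory> %d frames x %d spheres\n",
              length(x$frames), nrow(x$frames[[1]]$centers)))
  invisible(x)
}

#' Packaged van der Waals radius table
#'
#' Loads the element-to-radius table shipped with the package (a standard
#' van der Waals set in Angstrom) and attaches a fallback radius used for
#' elements missing from the table.
#'
#' @param fallback Radius in Angstrom assigned to unknown elements.
#' @return An object of class `cav_radius_table`: a list with `radii` (named
#'   numeric vector, element symbols upper-case) and `fallback`.
#' @export
vdw_radius_table <- function(fallback = 1.5) {
  path <- system.file("extdata", "vdw_radii.csv", package = "cavitrace",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  radii <- stats::setNames(tab$radius, toupper(tab$element))
  if (any(radii <= 0.5) || any(radii >= 3.0))
    stop("packaged radius table is corrupt: radii must lie in (0.5, 3.0)")
  if (fallback <= 0.5 || fallback >= 3.0)
    stop("`fallback` must lie in (0.5, 3.0) Angstrom")
  structure(list(radii = radii, fallback = fallback),
            class = "cav_radius_table")
}

#' Look up van der Waals radii by element symbol
#'
#' @param elements Character vector of element symbols (case-insensitive).
#' @param table A [vdw_radius_table()].
#' @return Numeric vector of radii; unknown elements get the table's
#'   fallback radius with a warning.
#' @export
vdw_radius <- function(elements, table = vdw_radius_table()) {
  el <- toupper(trimws(elements))
  r <- unname(table$radii[el])
  miss <- is.na(r)
  if (any(miss)) {
    warning(sprintf("unknown element(s) %s: using fallback radius %.2f A",
                    paste(unique(el[miss]), collapse = ", "),
                    table$fallback))
    r[miss] <- table$fallback
  }
  r
}

# element symbol from a PDB atom name when the element column is absent:
# strip digits and primes, drop a leading digit, take one or two letters
guess_element <- function(atom_names) {
  nm <- gsub("[0-9']", "", toupper(trimws(atom_names)))
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "SE", "NI", "CU")
  ifelse(nm %in% two, nm, substr(nm, 1L, 1L))
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL block becomes one frame. Radii are assigned from the element
#' column (PDB columns 77-78), falling back to an atom-name heuristic and
#' finally to the radius table's fallback value.
#'
#' @param path Path to a PDB file containing one or more MODEL blocks.
#' @param radii A [vdw_radius_table()].
#' @param exclude_resid Optional character vector of residue names to drop
#'   (e.g. `"HOH"` to exclude waters).
#' @param exclude_hydrogens Drop hydrogen atoms when `TRUE`.
#' @return A [trajectory()] whose `atom_labels` carry element, residue and
#'   atom-name records.
#' @export
read_multimodel_pdb <- function(path, radii = vdw_radius_table(),
                                exclude_resid = NULL,
                                exclude_hydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_model_consistency(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  keep <- rep(TRUE, nrow(atoms))
  el <- toupper(trimws(atoms$elesy))
  noel <- is.na(el) | el == ""
  el[noel] <- guess_element(atoms$elety[noel])
  if (!is.null(exclude_resid))
    keep <- keep & !(atoms$resid %in% exclude_resid)
  if (exclude_hydrogens)
    keep <- keep & el != "H"
  if (!any(keep)) stop("no atoms left after exclusion filters")
  r <- vdw_radius(el[keep], radii)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_frames <- nrow(xyz)
  idx <- which(keep)
  cols <- as.vector(rbind(3L * (idx - 1L) + 1L, 3L * (idx - 1L) + 2L,
                          3L * idx))
  frames <- lapply(seq_len(n_frames), function(m) {
    cen <- matrix(xyz[m, cols], ncol = 3L, byrow = TRUE)
    sphere_frame(cen, r, time_index = m - 1L)
  })
  labels <- data.frame(element = el[keep], resid = atoms$resid[keep],
                       resno = atoms$resno[keep], elety = atoms$elety[keep],
                       stringsAsFactors = FALSE)
  trajectory(frames, atom_labels = labels)
}

# hard error when MODEL blocks disagree in atom count, naming the offender
check_model_consistency <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) < 2L) return(invisible(TRUE))
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  block <- findInterval(seq_along(lines), model_starts)
  counts <- tabulate(block[is_atom], nbins = length(model_starts))
  if (length(unique(counts)) != 1L) {
    bad <- which(counts != counts[1])[1]
    model_no <- suppressWarnings(
      as.integer(trimws(substr(lines[model_starts[bad]], 7L, 80L))))
    stop(sprintf(
      "inconsistent atom counts between MODELs: MODEL %s has %d atoms, expected %d",
      ifelse(is.na(model_no), as.character(bad), model_no),
      counts[bad], counts[1]))
  }
  invisible(TRUE)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  n <- nrow(traj$frames[[1]]$centers)
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.vector(t(f$centers))))
  lab <- traj$atom_labels
  if (is.null(lab))
    lab <- data.frame(element = rep("C", n), resid = rep("UNK", n),
                      resno = rep(1L, n), elety = paste0("C", seq_len(n)),
                      stringsAsFactors = FALSE)
  bio3d::write.pdb(file = path, xyz = xyz, resno = lab$resno,
                   resid = lab$resid, eleno = seq_len(n), elety = lab$elety,
                   elesy = lab$element)
  invisible(path)
}

#' Read a plain "x y z r" sphere list as a frame
#'
#' Fixture-oriented alternative input: one whitespace-separated line per
#' sphere with columns x, y, z, radius (Angstrom).
#'
#' @param path File path.
#' @param time_index Time index to assign to the frame.
#' @return A [sphere_frame()].
#' @export
read_sphere_list <- function(path, time_index = 0L) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("x", "y", "z", "r"))
  sphere_frame(as.matrix(tab[, 1:3]), tab$r, time_index = time_index)
}

#' @rdname read_sphere_list
#' @param frame A [sphere_frame()] to write.
#' @export
write_sphere_list <- function(frame, path) {
  utils::write.table(cbind(frame$centers, frame$radii), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# run `expr` under a fixed RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-frame seed derived from the global seed so frames are independently
# reproducible; kept within the 32-bit integer range
frame_seed <- function(seed, time_index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(time_index)) %%
               .Machine$integer.max)
}

#' Break exact degeneracies by a tiny random displacement
#'
#' Voronoi computation requires spheres in general position: more than four
#' spheres tangent to one common empty sphere make the diagram degenerate.
#' Each atom center is displaced by an independent random vector drawn
#' uniformly from the ball of radius `epsilon`, which is chosen small enough
#' that the displacement is irrelevant for the structure analysis.
#'
#' @param frame A [sphere_frame()].
#' @param epsilon Maximum displacement length in Angstrom (> 0).
#' @param seed Integer seed; the same seed always yields the same output.
#' @return The perturbed frame (radii unchanged).
#' @export
perturb_positions <- function(frame, epsilon = 1e-6, seed = 1L) {
  if (!is.finite(epsilon) || epsilon <= 0) stop("`epsilon` must be > 0")
  n <- nrow(frame$centers)
  disp <- with_local_seed(seed, {
    d <- matrix(stats::rnorm(3L * n), ncol = 3L)
    len <- sqrt(rowSums(d^2))
    len[len == 0] <- 1
    d / len * (epsilon * stats::runif(n)^(1 / 3))
  })
  frame$centers <- frame$centers + disp
  frame
}

#' @rdname perturb_positions
#' @param traj A [trajectory()]; each frame is perturbed with a seed derived
#'   from `seed` and the frame's `time_index`.
#' @export
perturb_trajectory <- function(traj, epsilon = 1e-6, seed = 1L) {
  traj$frames <- lapply(traj$frames, function(f)
    perturb_positions(f, epsilon, frame_seed(seed, f$time_index)))
  traj
}
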