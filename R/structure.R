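# Structure and Trajectory containers. A Structure is a single conformation
# (atom table + coordinates); a Trajectory is an ordered set of frames sharing
# one atom table, each frame stamped with a simulation time in ps.

#' Create a molecular Structure
#'
#' A `Structure` holds one conformation: an ordered atom table (name, element,
#' 1-based residue index, residue name, chain id, mass in Da) and Cartesian
#' coordinates in Angstrom.
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`, `resname`,
#'   `chain`, `x`, `y`, `z`; optional `mass` (assigned from the packaged
#'   element-mass table when absent).
#' @param title optional title string.
#' @return an object of class `Structure`.
#' @export
structure_new <- function(atoms, title = "") {
  required <- c("name", "element", "resid", "resname", "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) < 1L) stop("a Structure needs at least one atom")
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (anyNA(atoms$mass) || any(atoms$mass <= 0)) {
    stop("all atom masses must be known and positive")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(r)) {
      stop("residue indices must be non-decreasing within chain '", ch, "'")
    }
  }
  obj <- list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
              title = title)
  class(obj) <- "Structure"
  obj
}

#' Coordinates of a Structure as an n x 3 matrix
#'
#' @param x a `Structure`.
#' @return numeric matrix (Angstrom), one row per atom.
#' @export
coords <- function(x) {
  UseMethod("coords")
}

#' @export
coords.Structure <- function(x) {
  unname(as.matrix(x$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a Structure
#'
#' @param x a `Structure`.
#' @param xyz n x 3 numeric matrix.
#' @return the modified `Structure`.
#' @export
set_coords <- function(x, xyz) {
  stopifnot(inherits(x, "Structure"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(x$atoms) || ncol(xyz) != 3L) {
    stop("replacement coordinates must be ", nrow(x$atoms), " x 3")
  }
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  x$atoms$x <- xyz[, 1]
  x$atoms$y <- xyz[, 2]
  x$atoms$z <- xyz[, 3]
  x
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", if (nzchar(x$title)) x$title else "<untitled>", "\n")
  cat("  atoms:   ", nrow(x$atoms), "\n")
  cat("  residues:", length(unique(paste(x$atoms$chain, x$atoms$resid))), "\n")
  cat("  chains:  ", paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

#' Create a Trajectory
#'
#' A `Trajectory` is an ordered series of coordinate frames over a fixed atom
#' table, with strictly increasing time stamps in ps.
#'
#' @param atoms atom table (as in [structure_new()]) shared by all frames.
#' @param frames list of n x 3 coordinate matrices (Angstrom).
#' @param times numeric vector of time stamps (ps), strictly increasing.
#' @param title optional title string.
#' @return an object of class `Trajectory`.
#' @export
trajectory_new <- function(atoms, frames, times, title = "") {
  if (length(frames) < 1L) stop("a Trajectory needs at least one frame")
  if (length(frames) != length(times)) {
    stop("number of frames and time stamps differ")
  }
  n <- nrow(atoms)
  for (k in seq_along(frames)) {
    frames[[k]] <- unname(as.matrix(frames[[k]]))
    if (nrow(frames[[k]]) != n || ncol(frames[[k]]) != 3L) {
      stop("frame ", k, " is not ", n, " x 3")
    }
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("time stamps must be strictly increasing")
  }
  ref <- structure_new(cbind(atoms[, setdiff(names(atoms), c("x", "y", "z"))],
                             data.frame(x = frames[[1]][, 1],
                                        y = frames[[1]][, 2],
                                        z = frames[[1]][, 3])),
                       title = title)
  obj <- list(atoms = ref$atoms, frames = frames, times = as.numeric(times),
              title = title)
  class(obj) <- "Trajectory"
  obj
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  length(traj$frames)
}

#' Extract one frame of a Trajectory as a Structure
#'
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return a `Structure` with the frame's coordinates.
#' @export
frame_structure <- function(traj, i) {
  stopifnot(inherits(traj, "Trajectory"))
  if (i < 1L || i > length(traj$frames)) stop("frame index out of range")
  at <- traj$atoms
  at$x <- traj$frames[[i]][, 1]
  at$y <- traj$frames[[i]][, 2]
  at$z <- traj$frames[[i]][, 3]
  structure_new(at, title = sprintf("%s (frame %d, t=%g ps)",
                                    traj$title, i, traj$times[i]))
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", if (nzchar(x$title)) x$title else "<untitled>", "\n")
  cat("  atoms: ", nrow(x$atoms), "\n")
  cat("  frames:", length(x$frames), "\n")
  cat(sprintf("  time:   %g .. %g ps\n", x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}
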