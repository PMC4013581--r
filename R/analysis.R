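# Post-trajectory analyses: RMSD time series, the dynamical cross-correlation
# matrix (DCCM) of per-residue displacement vectors, hydrogen-bond occupancy
# under geometric criteria, hydrophobic contacts (carbon-carbon distance
# below a strict cutoff), and mass-center distance series between annotated
# segments.

.resolve_selection <- function(atoms, selection) {
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  if (is.numeric(selection)) {
    sel <- as.integer(selection)
    if (any(sel < 1L) || any(sel > nrow(atoms))) {
      stop("selection index out of range")
    }
    return(sel)
  }
  stop("selection must be NULL or atom indices")
}

#' Best-fit RMSD time series of a trajectory against a reference
#'
#' @param traj a `Trajectory`.
#' @param reference a `Structure` (or n x 3 matrix) with matching selection.
#' @param selection atom indices (default: all atoms).
#' @param mass_weighted weight the fit and RMSD by atom masses (default).
#' @return data.frame with columns `time_ps`, `rmsd`.
#' @export
rmsd_series <- function(traj, reference, selection = NULL,
                        mass_weighted = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  sel <- .resolve_selection(traj$atoms, selection)
  Y <- .as_xyz(reference)
  if (nrow(Y) == nrow(traj$atoms)) Y <- Y[sel, , drop = FALSE]
  if (nrow(Y) != length(sel)) stop("selection size does not match reference")
  w <- if (mass_weighted) traj$atoms$mass[sel] else NULL
  r <- vapply(traj$frames, function(X) {
    rmsd(X[sel, , drop = FALSE], Y, weights = w)
  }, numeric(1))
  data.frame(time_ps = traj$times, rmsd = r)
}

#' Dynamical cross-correlation matrix (DCCM)
#'
#' Computes the normalized covariance of per-site displacement vectors,
#' `C(i,j) = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`,
#' where `dr_i(t) = r_i(t) - <r_i>` and the angle brackets average over
#' frames. With `fit = TRUE` (default) each frame is first superposed onto
#' the mean structure, and the mean/fit cycle is iterated once (mean, fit,
#' recompute mean, refit), removing rigid-body motion before the covariance
#' is taken. Sites with zero displacement variance give masked (`NA`)
#' rows/columns with a warning.
#'
#' @param traj a `Trajectory`.
#' @param selection one atom per residue (default: all atoms, appropriate
#'   for bead models; for all-atom input pass the C-alpha indices).
#' @param fit superpose frames onto the mean structure first (default TRUE).
#' @return an object of class `DCCM`: the correlation matrix with attributes
#'   `n_frames`, `selection`, `fit`.
#' @export
compute_dccm <- function(traj, selection = NULL, fit = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  if (length(traj$frames) < 2L) stop("need at least 2 frames")
  sel <- .resolve_selection(traj$atoms, selection)
  w <- traj$atoms$mass[sel]
  F_ <- length(traj$frames)
  n <- length(sel)
  arr <- array(0, dim = c(F_, n, 3))
  for (t in seq_len(F_)) arr[t, , ] <- traj$frames[[t]][sel, , drop = FALSE]

  if (fit) {
    for (pass in 1:2) {
      mean_xyz <- apply(arr, c(2, 3), mean)
      for (t in seq_len(F_)) {
        sup <- kabsch_superpose(arr[t, , ], mean_xyz, weights = w)
        arr[t, , ] <- sup$transformed
      }
    }
  }
  mean_xyz <- apply(arr, c(2, 3), mean)
  dx <- arr[, , 1] - matrix(mean_xyz[, 1], F_, n, byrow = TRUE)
  dy <- arr[, , 2] - matrix(mean_xyz[, 2], F_, n, byrow = TRUE)
  dz <- arr[, , 3] - matrix(mean_xyz[, 3], F_, n, byrow = TRUE)
  num <- (crossprod(dx) + crossprod(dy) + crossprod(dz)) / F_
  v <- diag(num)
  zero_var <- v <= 0 | !is.finite(v)
  if (all(zero_var)) stop("all selected sites have zero variance")
  if (any(zero_var)) {
    warning(sum(zero_var), " site(s) with zero displacement variance; ",
            "their correlations are masked as NA", call. = FALSE)
  }
  denom <- sqrt(v)
  denom[zero_var] <- NA_real_
  C <- num / outer(denom, denom)
  C <- (C + t(C)) / 2
  diag(C)[!zero_var] <- 1
  resids <- traj$atoms$resid[sel]
  dimnames(C) <- list(resids, resids)
  structure(C, class = c("DCCM", "matrix"),
            n_frames = F_, selection = sel, fit = fit)
}

#' @export
print.DCCM <- function(x, ...) {
  cat("DCCM:", nrow(x), "sites,", attr(x, "n_frames"), "frames, fit =",
      attr(x, "fit"), "\n")
  off <- x[upper.tri(x)]
  cat(sprintf("  off-diagonal range: %.3f .. %.3f\n",
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Write a DCCM as a whitespace-delimited matrix
#'
#' Dense matrix with a residue-index header row and column.
#'
#' @param dccm a `DCCM`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_dccm <- function(dccm, path) {
  m <- as.matrix(unclass(dccm))
  df <- data.frame(residue = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hydrogen-bond geometric criteria
#'
#' @param dist_cutoff donor-acceptor heavy-atom distance cutoff (Angstrom).
#' @param angle_cutoff donor-H-acceptor angle cutoff (degrees); a bond
#'   requires angle >= this value.
#' @return an object of class `HBondCriteria`.
#' @export
hbond_criteria <- function(dist_cutoff = 3.5, angle_cutoff = 120) {
  if (dist_cutoff <= 0) stop("distance cutoff must be positive")
  if (angle_cutoff <= 0 || angle_cutoff > 180) {
    stop("angle cutoff must be in (0, 180]")
  }
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "HBondCriteria")
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For each donor/acceptor pair, the percentage of frames in which the
#' donor-acceptor distance is within `dist_cutoff` AND the donor-H-acceptor
#' angle of some hydrogen on the donor residue is at least `angle_cutoff`.
#' Occupancies are rounded to one decimal. Pairs whose donor residue has no
#' hydrogen atom are skipped with a warning.
#'
#' @param traj a `Trajectory` whose atom table includes hydrogens.
#' @param pairs data.frame with columns `donor_resid`, `donor_atom`,
#'   `acceptor_resid`, `acceptor_atom`.
#' @param criteria an [hbond_criteria()].
#' @return data.frame (`OccupancyTable`) with columns `donor`, `acceptor`,
#'   `occupancy` (percent).
#' @export
hbond_occupancy <- function(traj, pairs, criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "Trajectory"), inherits(criteria, "HBondCriteria"))
  at <- traj$atoms
  rows <- vector("list", nrow(pairs))
  cosmin <- cos(criteria$angle_cutoff * pi / 180)
  for (p in seq_len(nrow(pairs))) {
    di <- which(at$resid == pairs$donor_resid[p] &
                  at$name == pairs$donor_atom[p])
    ai <- which(at$resid == pairs$acceptor_resid[p] &
                  at$name == pairs$acceptor_atom[p])
    if (length(di) != 1L || length(ai) != 1L) {
      stop("pair ", p, ": donor or acceptor atom not found (or ambiguous)")
    }
    hi <- which(at$resid == pairs$donor_resid[p] &
                  toupper(at$element) == "H")
    if (length(hi) == 0L) {
      warning("pair ", p, " (residue ", pairs$donor_resid[p],
              "): donor has no hydrogen; pair skipped", call. = FALSE)
      next
    }
    hits <- vapply(traj$frames, function(X) {
      d <- X[di, ] - X[ai, ]
      if (sqrt(sum(d^2)) > criteria$dist_cutoff) return(FALSE)
      for (h in hi) {
        v1 <- X[di, ] - X[h, ]
        v2 <- X[ai, ] - X[h, ]
        ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        # angle >= cutoff <=> cos(angle) <= cos(cutoff)
        if (ca <= cosmin) return(TRUE)
      }
      FALSE
    }, logical(1))
    rows[[p]] <- data.frame(
      donor = sprintf("%s%d:%s", at$resname[di], at$resid[di], at$name[di]),
      acceptor = sprintf("%s%d:%s", at$resname[ai], at$resid[ai],
                         at$name[ai]),
      occupancy = round(100 * sum(hits) / length(hits), 1),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(donor = character(), acceptor = character(),
                      occupancy = numeric())
  }
  class(out) <- c("OccupancyTable", "data.frame")
  out
}

#' Hydrophobic contacts between residue pairs
#'
#' For each residue pair and frame, the minimum distance between carbon
#' atoms of the two residues, with a contact flag at `distance < cutoff`
#' (strict inequality). In bead models (element "X") the beads stand in for
#' the carbon atoms and the cutoff applies to bead-bead distances.
#'
#' @param x a `Trajectory` or a `Structure` (treated as one frame).
#' @param residue_pairs data.frame with columns `res_a`, `res_b` (residue
#'   indices).
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @return data.frame with columns `res_a`, `res_b`, `time_ps`, `min_dist`,
#'   `contact`.
#' @export
hydrophobic_contacts <- function(x, residue_pairs, cutoff = 4.5) {
  if (inherits(x, "Structure")) {
    x <- trajectory_new(x$atoms, list(coords(x)), 0, title = x$title)
  }
  stopifnot(inherits(x, "Trajectory"))
  at <- x$atoms
  carbon <- toupper(at$element) %in% c("C", "X")
  rows <- vector("list", nrow(residue_pairs))
  for (p in seq_len(nrow(residue_pairs))) {
    ia <- which(at$resid == residue_pairs$res_a[p] & carbon)
    ib <- which(at$resid == residue_pairs$res_b[p] & carbon)
    if (length(ia) == 0L || length(ib) == 0L) {
      stop("residue pair (", residue_pairs$res_a[p], ", ",
           residue_pairs$res_b[p], ") has no carbon atoms")
    }
    md <- vapply(x$frames, function(X) {
      A <- X[ia, , drop = FALSE]
      B <- X[ib, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
      sqrt(max(0, min(d2)))
    }, numeric(1))
    rows[[p]] <- data.frame(res_a = residue_pairs$res_a[p],
                            res_b = residue_pairs$res_b[p],
                            time_ps = x$times, min_dist = md,
                            contact = md < cutoff)
  }
  do.call(rbind, rows)
}

#' Mass-center distance series between segments
#'
#' Euclidean distance between the mass centers of two segments in every
#' frame; no superposition is applied (the distances are internal
#' coordinates, invariant under rigid motion of the frame).
#'
#' @param traj a `Trajectory`.
#' @param segments a `SegmentTable`.
#' @param pairs list of length-2 character vectors (segment name pairs), or
#'   a 2-column data.frame/matrix.
#' @return data.frame with columns `seg_a`, `seg_b`, `time_ps`, `dist`.
#' @export
segment_distance_series <- function(traj, segments, pairs) {
  stopifnot(inherits(traj, "Trajectory"), inherits(segments, "SegmentTable"))
  if (is.data.frame(pairs) || is.matrix(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, ]))
  }
  at <- traj$atoms
  rows <- lapply(pairs, function(pr) {
    sa <- which(at$resid %in% segment_residues(segments, pr[1]))
    sb <- which(at$resid %in% segment_residues(segments, pr[2]))
    if (length(sa) == 0L || length(sb) == 0L) {
      stop("segment pair (", pr[1], ", ", pr[2],
           ") resolves to an empty atom set")
    }
    d <- vapply(traj$frames, function(X) {
      ca <- mass_center(X, selection = sa, masses = at$mass)
      cb <- mass_center(X, selection = sb, masses = at$mass)
      sqrt(sum((ca - cb)^2))
    }, numeric(1))
    data.frame(seg_a = pr[1], seg_b = pr[2], time_ps = traj$times, dist = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
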