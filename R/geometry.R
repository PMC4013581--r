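# Rigid-body superposition and RMSD primitives. Everything downstream --
# the TMD restraint, RMSD time series, DCCM frame fitting -- goes through
# these functions.

.as_xyz <- function(x) {
  if (inherits(x, "Structure")) return(coords(x))
  m <- unname(as.matrix(x))
  if (ncol(m) != 3L) stop("coordinate set must be n x 3")
  m
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (mass-)weighted
#' RMSD between two index-matched coordinate sets, via SVD of the weighted
#' covariance matrix with the standard reflection correction (the axis of the
#' smallest singular value is flipped when the determinant is negative, so
#' the result is always a proper rotation).
#'
#' @param mobile n x 3 matrix (or `Structure`) to be moved.
#' @param reference n x 3 matrix (or `Structure`) to superpose onto.
#' @param weights per-atom positive weights, typically masses (Da). Default:
#'   equal weights.
#' @return a list of class `Superposition` with elements `rotation` (3 x 3,
#'   det +1), `translation` (length-3), `rmsd` (Angstrom, weighted), and
#'   `transformed` (the mobile set after superposition). The transform maps
#'   mobile points as `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  X <- .as_xyz(mobile)
  Y <- .as_xyz(reference)
  n <- nrow(X)
  if (nrow(Y) != n) stop("coordinate sets differ in atom count")
  if (n < 3L) stop("need at least 3 atoms to superpose")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    stop("weights must be positive, one per atom")
  }
  w <- weights / sum(weights)
  cx <- colSums(X * w)
  cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  H <- t(Xc * w) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (sum(sv$d > max(sv$d) * 1e-12) < 2L) {
    stop("degenerate (rank < 2) point set; superposition undefined")
  }
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Xr <- Xc %*% t(R)
  msd <- sum(w * rowSums((Xr - Yc)^2))
  out <- list(rotation = R,
              translation = as.numeric(cy - R %*% cx),
              rmsd = sqrt(max(msd, 0)),
              transformed = sweep(Xr, 2, cy, `+`))
  class(out) <- "Superposition"
  out
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Best-fit weighted RMSD between two coordinate sets
#'
#' @inheritParams kabsch_superpose
#' @param fit superpose first (default) or compute the raw in-place RMSD.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(mobile, reference, weights = NULL, fit = TRUE) {
  X <- .as_xyz(mobile)
  Y <- .as_xyz(reference)
  if (fit) {
    kabsch_superpose(X, Y, weights)$rmsd
  } else {
    n <- nrow(X)
    if (nrow(Y) != n) stop("coordinate sets differ in atom count")
    if (is.null(weights)) weights <- rep(1, n)
    w <- weights / sum(weights)
    sqrt(sum(w * rowSums((X - Y)^2)))
  }
}

#' Gradient of the best-fit weighted RMSD
#'
#' Analytic gradient of `rmsd(mobile, reference, weights)` with respect to
#' the mobile coordinates. At the optimal superposition the rotational
#' derivative terms vanish, leaving
#' `g_i = w_i (x_i - yhat_i) / (RMSD * sum(w))`
#' where `yhat` is the reference transformed into the mobile frame. Below
#' `eps` the RMSD is not differentiable and the gradient is clamped to zero
#' (forces stay finite at the end of a TMD schedule).
#'
#' @inheritParams kabsch_superpose
#' @param eps clamp threshold in Angstrom (default 1e-6).
#' @return list with `gradient` (n x 3, units 1/Angstrom-free: d RMSD / d x)
#'   and `rmsd`.
#' @export
rmsd_gradient <- function(mobile, reference, weights = NULL, eps = 1e-6) {
  X <- .as_xyz(mobile)
  Y <- .as_xyz(reference)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  sup <- kabsch_superpose(Y, X, weights)  # bring reference into mobile frame
  r <- sup$rmsd
  if (r < eps) {
    return(list(gradient = matrix(0, n, 3), rmsd = r))
  }
  yhat <- sup$transformed
  g <- (weights / sum(weights)) * (X - yhat) / r
  list(gradient = g, rmsd = r)
}

#' Mass center of a selection
#'
#' @param x a `Structure`, or an n x 3 coordinate matrix.
#' @param selection integer vector of atom indices (default: all atoms). For
#'   a `Structure` you may instead give residue indices via `residues`.
#' @param residues optional residue indices (Structure input only); atoms of
#'   those residues form the selection.
#' @param masses per-atom masses; taken from the Structure when available,
#'   otherwise equal masses.
#' @return length-3 numeric vector (Angstrom).
#' @export
mass_center <- function(x, selection = NULL, residues = NULL, masses = NULL) {
  if (inherits(x, "Structure")) {
    if (!is.null(residues)) {
      selection <- which(x$atoms$resid %in% residues)
    }
    if (is.null(masses)) masses <- x$atoms$mass
    xyz <- coords(x)
  } else {
    xyz <- .as_xyz(x)
    if (is.null(masses)) masses <- rep(1, nrow(xyz))
  }
  if (is.null(selection)) selection <- seq_len(nrow(xyz))
  if (length(selection) == 0L) stop("empty selection")
  m <- masses[selection]
  colSums(xyz[selection, , drop = FALSE] * m) / sum(m)
}
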