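# The targeted-MD restraint: a harmonic energy on the deviation between the
# current best-fit mass-weighted RMSD to the target structure and a
# prescribed target RMSD that decays linearly in time,
#   E_TMD = 1/2 * k * N * (RMSD(t) - RMSD0(t))^2,
# with k the per-atom force constant and N the number of restrained atoms.
# Forces follow from the analytic best-fit RMSD gradient.

#' Create a TMD restraint
#'
#' @param target target `Structure`.
#' @param k per-atom harmonic force constant, kcal/(mol A^2).
#' @param selection integer indices of restrained atoms (default: all).
#' @param rmsd_start target-RMSD value at `t_start` (Angstrom). Use `NA` to
#'   have the driver fill in the actual initial RMSD (so the restraint starts
#'   unstrained).
#' @param rmsd_end target-RMSD value at `t_end` (Angstrom, usually 0).
#' @param t_start,t_end schedule window (ps); between them the target RMSD
#'   interpolates linearly, after `t_end` it holds at `rmsd_end`, before
#'   `t_start` it holds at `rmsd_start`.
#' @param mass_weighted use masses as RMSD weights (default) or equal weights.
#' @return an object of class `TMDRestraint`.
#' @export
tmd_restraint <- function(target, k = 0.5, selection = NULL,
                          rmsd_start = NA_real_, rmsd_end = 0,
                          t_start = 0, t_end = 100, mass_weighted = TRUE) {
  stopifnot(inherits(target, "Structure"))
  if (is.null(selection)) selection <- seq_len(nrow(target$atoms))
  if (k <= 0) stop("k must be positive")
  if (length(selection) < 3L) stop("need at least 3 restrained atoms")
  if (t_end < t_start) stop("schedule end before start")
  selection <- as.integer(selection)
  obj <- list(target = target, k = k, selection = selection,
              N = length(selection), rmsd_start = rmsd_start,
              rmsd_end = rmsd_end, t_start = t_start, t_end = t_end,
              mass_weighted = mass_weighted,
              target_xyz = coords(target)[selection, , drop = FALSE],
              weights = if (mass_weighted) {
                target$atoms$mass[selection]
              } else {
                rep(1, length(selection))
              })
  class(obj) <- "TMDRestraint"
  obj
}

#' Scheduled target RMSD at time t
#'
#' @param restraint a `TMDRestraint` (with `rmsd_start` resolved).
#' @param t time in ps.
#' @return target RMSD value (Angstrom).
#' @export
tmd_schedule <- function(restraint, t) {
  stopifnot(inherits(restraint, "TMDRestraint"))
  r0 <- restraint$rmsd_start
  r1 <- restraint$rmsd_end
  if (is.na(r0)) stop("rmsd_start unresolved; set it or run via run_tmd()")
  ifelse(t <= restraint$t_start, r0,
         ifelse(t >= restraint$t_end, r1,
                r0 + (r1 - r0) * (t - restraint$t_start) /
                  (restraint$t_end - restraint$t_start)))
}

#' TMD restraint energy and forces
#'
#' Evaluates `E = 1/2 k N (RMSD(t) - RMSD0(t))^2` and its forces
#' `-k N (RMSD - RMSD0) dRMSD/dx` on the restrained atoms; unrestrained
#' atoms feel no force.
#'
#' @param X n x 3 coordinate matrix (or `Structure`) of the full system.
#' @param restraint a `TMDRestraint`.
#' @param t time in ps.
#' @return list with `energy` (kcal/mol), `forces` (n x 3), `rmsd` and
#'   `rmsd0` (Angstrom).
#' @export
tmd_energy <- function(X, restraint, t) {
  stopifnot(inherits(restraint, "TMDRestraint"))
  X <- .as_xyz(X)
  sel <- restraint$selection
  if (max(sel) > nrow(X)) stop("restraint selection exceeds atom count")
  gr <- rmsd_gradient(X[sel, , drop = FALSE], restraint$target_xyz,
                      weights = restraint$weights)
  rmsd0 <- tmd_schedule(restraint, t)
  dev <- gr$rmsd - rmsd0
  kN <- restraint$k * restraint$N
  F <- matrix(0, nrow(X), 3)
  F[sel, ] <- -kN * dev * gr$gradient
  list(energy = 0.5 * kN * dev^2, forces = F, rmsd = gr$rmsd, rmsd0 = rmsd0)
}
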