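# Coarse-grained dual-basin structure-based potential. One bead per residue;
# each basin is a structure-based (Go-like) potential around one reference
# conformer -- harmonic bonds, harmonic native-contact tethers, soft-core
# repulsion between non-native pairs -- and the two basins are blended with a
# log-sum-exp soft minimum so that both references are local minima of the
# total energy surface and a driven trajectory can pass smoothly between
# them.
#
# Units: kcal/mol, Angstrom, ps, Da throughout.

#' Build a dual-basin model over two end-state structures
#'
#' Pairs separated by at least two positions along the chain and closer than
#' `contact_cutoff` in a reference conformer are native contacts of that
#' basin (tethered harmonically at their reference distance); all other
#' nonbonded pairs feel a quadratic soft-core repulsion inside
#' `excluded_radius`. Consecutive beads are bonded at their per-basin
#' reference length. The two basin energies are combined as
#' `V = -(1/beta_mix) * log(exp(-beta_mix*V_open) + exp(-beta_mix*V_closed))`.
#'
#' @param open_ref,closed_ref index-matched `Structure`s (one bead per
#'   residue) defining the two basins.
#' @param k_bond bond force constant, kcal/(mol A^2).
#' @param k_contact native-contact force constant, kcal/(mol A^2).
#' @param k_rep soft-core repulsion constant, kcal/(mol A^2).
#' @param contact_cutoff native-contact cutoff, Angstrom.
#' @param excluded_radius soft-core excluded-volume radius, Angstrom.
#' @param beta_mix basin-mixing sharpness, 1/(kcal/mol).
#' @return an object of class `DualBasinModel`.
#' @export
build_dual_basin <- function(open_ref, closed_ref,
                             k_bond = 100, k_contact = 1.1, k_rep = 2,
                             contact_cutoff = 8, excluded_radius = 3.8,
                             beta_mix = 0.025) {
  stopifnot(inherits(open_ref, "Structure"), inherits(closed_ref, "Structure"))
  Xo <- coords(open_ref)
  Xc <- coords(closed_ref)
  n <- nrow(Xo)
  if (nrow(Xc) != n) stop("reference structures differ in atom count")
  if (n < 4L) stop("need at least 4 beads")
  if (contact_cutoff <= 0 || excluded_radius <= 0 || beta_mix <= 0) {
    stop("cutoffs and beta_mix must be positive")
  }

  pdist <- function(X, i, j) sqrt(rowSums((X[i, , drop = FALSE] -
                                             X[j, , drop = FALSE])^2))
  bi <- seq_len(n - 1L)
  bj <- bi + 1L
  b0o <- pdist(Xo, bi, bj)
  b0c <- pdist(Xc, bi, bj)
  if (contact_cutoff < max(b0o, b0c)) {
    stop("contact cutoff smaller than a bond length")
  }

  # all nonbonded pairs |i - j| >= 2
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- pairs[, 2] - pairs[, 1] >= 2L
  pi_ <- pairs[keep, 1]
  pj_ <- pairs[keep, 2]
  ro <- pdist(Xo, pi_, pj_)
  rc <- pdist(Xc, pi_, pj_)
  nat_o <- ro < contact_cutoff
  nat_c <- rc < contact_cutoff

  # precomputed scatter-add map: force on bead b = sum over interaction
  # endpoints (+ at i, - at j); one cumsum over a fixed sorted order per step
  all_idx <- c(pi_, bi, pj_, bj)
  ord <- order(all_idx)
  srt <- all_idx[ord]
  ends <- cumsum(rle(srt)$lengths)
  accum <- list(ord = ord, ends = ends, bins = srt[ends],
                n_pos = length(pi_) + length(bi))

  model <- list(
    n = n, masses = open_ref$atoms$mass, accum = accum,
    open_ref = open_ref, closed_ref = closed_ref,
    bond_i = bi, bond_j = bj, bond0_open = b0o, bond0_closed = b0c,
    pair_i = pi_, pair_j = pj_,
    native_open = nat_o, native_closed = nat_c,
    r0_open = ifelse(nat_o, ro, NA_real_),
    r0_closed = ifelse(nat_c, rc, NA_real_),
    k_bond = k_bond, k_contact = k_contact, k_rep = k_rep,
    contact_cutoff = contact_cutoff, excluded_radius = excluded_radius,
    beta_mix = beta_mix
  )
  class(model) <- "DualBasinModel"
  model
}

#' @export
print.DualBasinModel <- function(x, ...) {
  cat("DualBasinModel:", x$n, "beads\n")
  cat("  native contacts: open", sum(x$native_open),
      "/ closed", sum(x$native_closed), "\n")
  cat(sprintf("  k_bond %g, k_contact %g, k_rep %g kcal/(mol A^2); cutoff %g A; beta_mix %g\n",
              x$k_bond, x$k_contact, x$k_rep, x$contact_cutoff, x$beta_mix))
  invisible(x)
}

# Energy and forces of one basin. Returns list(V, coef_pairs, coef_bonds)
# where coef is dV/dr / r per interaction (used for force assembly).
.basin_terms <- function(model, r_pair, r_bond, basin) {
  if (basin == "open") {
    nat <- model$native_open; r0 <- model$r0_open; b0 <- model$bond0_open
  } else {
    nat <- model$native_closed; r0 <- model$r0_closed; b0 <- model$bond0_closed
  }
  kc <- model$k_contact; kr <- model$k_rep; sig <- model$excluded_radius
  coef <- numeric(length(r_pair))
  V <- 0
  if (any(nat)) {
    dr <- r_pair[nat] - r0[nat]
    V <- V + kc * sum(dr^2)
    coef[nat] <- 2 * kc * dr / r_pair[nat]
  }
  rep_on <- !nat & r_pair < sig
  if (any(rep_on)) {
    dr <- sig - r_pair[rep_on]
    V <- V + kr * sum(dr^2)
    coef[rep_on] <- -2 * kr * dr / r_pair[rep_on]
  }
  drb <- r_bond - b0
  V <- V + model$k_bond * sum(drb^2)
  coef_b <- 2 * model$k_bond * drb / r_bond
  list(V = V, coef_pairs = coef, coef_bonds = coef_b)
}

#' Dual-basin energy and forces at a configuration
#'
#' @param model a `DualBasinModel`.
#' @param X n x 3 coordinate matrix (or `Structure`).
#' @return list with `V` (total mixed energy, kcal/mol), `forces` (n x 3,
#'   kcal/(mol A)), `V_open`, `V_closed` (per-basin energies) and `w_open`
#'   (mixing weight of the open basin).
#' @export
dual_basin_energy <- function(model, X) {
  stopifnot(inherits(model, "DualBasinModel"))
  X <- .as_xyz(X)
  if (nrow(X) != model$n) stop("configuration has wrong bead count")
  dp <- X[model$pair_i, , drop = FALSE] - X[model$pair_j, , drop = FALSE]
  rp <- sqrt(rowSums(dp^2))
  db <- X[model$bond_i, , drop = FALSE] - X[model$bond_j, , drop = FALSE]
  rb <- sqrt(rowSums(db^2))
  if (any(rp < 1e-8) || any(rb < 1e-8)) {
    stop("overlapping beads: energy is not finite")
  }
  to <- .basin_terms(model, rp, rb, "open")
  tc <- .basin_terms(model, rp, rb, "closed")
  beta <- model$beta_mix
  vmin <- min(to$V, tc$V)
  eo <- exp(-beta * (to$V - vmin))
  ec <- exp(-beta * (tc$V - vmin))
  V <- vmin - log(eo + ec) / beta
  wo <- eo / (eo + ec)
  cp <- wo * to$coef_pairs + (1 - wo) * tc$coef_pairs
  cb <- wo * to$coef_bonds + (1 - wo) * tc$coef_bonds
  F <- matrix(0, model$n, 3)
  ac <- model$accum
  np <- ac$n_pos
  for (k in 1:3) {
    g <- c(cp * dp[, k], cb * db[, k])
    v <- c(g, -g)[ac$ord]
    cs <- cumsum(v)
    gs <- cs[ac$ends] - c(0, cs[ac$ends[-length(ac$ends)]])
    Fk <- numeric(model$n)
    Fk[ac$bins] <- gs
    F[, k] <- -Fk
  }
  list(V = V, forces = F, V_open = to$V, V_closed = tc$V, w_open = wo)
}
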