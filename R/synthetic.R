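# Synthetic inputs with known ground truth: a coarse-grained two-state toy
# protein (a serpentine sheet whose terminal strand packs on the sheet edge
# in the open state and folds across the sheet face in the closed state),
# trajectories with planted correlated/anticorrelated site motions,
# hydrogen-bond geometry fixtures with controlled occupancy, and a hollow
# shell for pocket validation.

.bead_atoms <- function(xyz, chain = "A", name = "CA", element = "X",
                        resname = "GLY") {
  n <- nrow(xyz)
  data.frame(name = name, element = element, resid = seq_len(n),
             resname = resname, chain = chain,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# walk a chain of unit direction vectors scaled to `bond` starting at origin
.walk_chain <- function(theta, phi, bond = 3.8) {
  u <- cbind(cos(theta) * cos(phi), sin(theta) * cos(phi), sin(phi))
  rbind(c(0, 0, 0), apply(u * bond, 2, cumsum))
}

# walk explicit (already unit-normalized) direction vectors
.walk_dirs <- function(u, bond = 3.8) {
  rbind(c(0, 0, 0), apply(u * bond, 2, cumsum))
}

#' Generate a two-state coarse-grained toy protein
#'
#' Builds a single-chain bead model (one bead per residue, 3.8 Angstrom
#' consecutive spacing, average residue mass) with two reference
#' conformations sharing topology. The core (about three quarters of the
#' chain) is a three-strand serpentine sheet, identical in both states, so
#' both conformers have a genuine tertiary contact network. In the open
#' conformer the terminal segment (the "β7/8 analog") makes an in-plane
#' turn and packs against the outer edge of the last core strand; in the
#' closed conformer it turns out of the sheet plane and folds into the
#' groove above the middle strand -- a strand-relocation rearrangement in
#' which every tail contact partner changes. Both conformers are clash-free
#' (nonbonded beads >= 4.0 Angstrom apart) and the open-closed backbone RMSD
#' is large (>= 6 Angstrom for the defaults). The segment table labels toy
#' analogs of the β1 strand, αA and αC helices, β6/4/5 sheet, β5-αC loop
#' and β7/8 sheet for the distance and network analyses.
#'
#' The seed adds a small perturbation to the step directions (shared by
#' both conformers, so the core stays identical; directions are
#' re-normalized, so bond lengths stay exactly 3.8 Angstrom). Identical
#' seeds give identical coordinates.
#'
#' @param n_residues chain length (>= 30).
#' @param seed integer seed.
#' @param tail_len residues in the relocating terminal segment (default 14).
#' @param turn_len steps forming each in-plane core turn (default 3).
#' @param tail_turn_len steps forming the tail's relocating turn (default 4).
#' @return an object of class `ToySystem`: list with `open`, `closed`
#'   (`Structure`s), `segments` (`SegmentTable`), `seed`, `params`.
#' @export
make_two_state_toy <- function(n_residues = 60, seed = 1, tail_len = 14,
                               turn_len = 3, tail_turn_len = 4) {
  if (n_residues < 30L) stop("n_residues must be at least 30")
  strand_len <- (n_residues - tail_len - 2L * turn_len - tail_turn_len) %/% 3L
  if (strand_len < 5L) {
    stop("chain too short for three core strands plus the tail segment")
  }
  set.seed(as.integer(seed %% 2147483647))
  bond <- 3.8
  n_steps <- n_residues - 1L

  # core: strand (+x), U-turn (+pi), strand (-x), U-turn (-pi), strand (+x)
  s1 <- seq_len(strand_len - 1L)
  t1 <- strand_len - 1L + seq_len(turn_len)
  s2 <- max(t1) + seq_len(strand_len)
  t2 <- max(s2) + seq_len(turn_len)
  s3 <- max(t2) + seq_len(strand_len)
  tt <- max(s3) + seq_len(tail_turn_len)     # tail turn
  s4 <- (max(tt) + 1L):n_steps               # tail strand
  dth <- numeric(n_steps)
  dth[t1] <- pi / turn_len
  dth[t2] <- -pi / turn_len
  th_core <- cumsum(dth)
  base <- cbind(cos(th_core), sin(th_core), 0)

  u_open <- base
  u_closed <- base
  jturn <- seq_len(tail_turn_len)
  ang <- (pi / tail_turn_len) * jturn
  # open tail: tight in-plane U-turn (same diameter as the core turns, so
  # the strand packs along the outer edge of the last core strand); any
  # spare turn steps continue straight along the tail direction
  th_tail_open <- th_core[max(s3)] + (pi / turn_len) * pmin(jturn, turn_len)
  u_open[tt, ] <- cbind(cos(th_tail_open), sin(th_tail_open), 0)
  u_open[s4, ] <- matrix(c(cos(max(th_tail_open)), sin(max(th_tail_open)),
                           0), length(s4), 3, byrow = TRUE)
  # closed tail: U-turn in a plane tilted out of the sheet, spanned by +x
  # and a unit vector leaning across the sheet (-y) and upward (+z), so the
  # strand drops into the groove over the far side of the sheet face --
  # every tail contact partner changes between the two states
  e2 <- c(0, -1.5, 1) / sqrt(3.25)
  u_closed[tt, ] <- outer(cos(ang), c(1, 0, 0)) + outer(sin(ang), e2)
  u_closed[s4, ] <- matrix(c(-1, 0, 0), length(s4), 3, byrow = TRUE)

  # shared seeded jitter, then renormalize so bonds stay exactly `bond`
  jit <- matrix(stats::rnorm(n_steps * 3, 0, 0.015), n_steps, 3)
  renorm <- function(u) u / sqrt(rowSums(u^2))
  open_xyz <- .walk_dirs(renorm(u_open + jit), bond)
  closed_xyz <- .walk_dirs(renorm(u_closed + jit), bond)

  open_s <- structure_new(.bead_atoms(open_xyz), title = "toy open state")
  closed_s <- structure_new(.bead_atoms(closed_xyz),
                            title = "toy closed state")

  check_clashes <- function(X, label) {
    n <- nrow(X)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    nb <- idx[idx[, 2] - idx[, 1] >= 2L, , drop = FALSE]
    d <- sqrt(rowSums((X[nb[, 1], ] - X[nb[, 2], ])^2))
    if (min(d) < 4.0) {
      stop("generated ", label, " conformer has nonbonded beads at ",
           round(min(d), 2), " A (< 4.0)")
    }
  }
  check_clashes(open_xyz, "open")
  check_clashes(closed_xyz, "closed")

  # residue blocks (steps k..l place residues k..l+1)
  r_s1 <- c(1L, strand_len)
  r_s2 <- c(min(s2) + 1L, max(s2) + 1L)
  r_t2 <- c(min(t2) + 1L, max(t2))
  r_s3 <- c(min(s3) + 1L, max(s3) + 1L)
  r_s4 <- c(min(s4) + 1L, n_residues)
  s <- .seg_names
  half1 <- max(2L, strand_len %/% 2L)
  segments <- segment_table(list(
    .entry(paste(s$b1, "toy"), "strand", c(r_s1[1], half1)),
    .entry(paste(s$aC, "toy"), "helix", c(half1 + 1L, r_s1[2])),
    .entry(paste(s$aA, "toy"), "helix", r_s2),
    .entry(paste(s$loop5C, "toy"), "loop", r_t2),
    .entry(paste(s$b645, "toy"), "sheet-group", r_s3),
    .entry(paste(s$b78, "toy"), "sheet-group", r_s4)
  ))

  obj <- list(open = open_s, closed = closed_s, segments = segments,
              seed = seed,
              params = list(n_residues = n_residues, tail_len = tail_len,
                            turn_len = turn_len, strand_len = strand_len,
                            bond = bond))
  class(obj) <- "ToySystem"
  obj
}

#' @export
print.ToySystem <- function(x, ...) {
  cat("ToySystem:", x$params$n_residues, "residues, seed", x$seed, "\n")
  cat(sprintf("  open vs closed backbone RMSD: %.2f A\n",
              rmsd(x$open, x$closed, weights = x$open$atoms$mass)))
  invisible(x)
}

#' Trajectory with planted correlated site motions
#'
#' Sites sit on a widely spaced line; per frame, each planted block adds a
#' shared 3D latent displacement to its first site set and `sign` times the
#' same latent to its second set, plus independent Gaussian noise on every
#' site. With the default latent and noise scales the expected correlation
#' magnitude inside a planted block is
#' `latent_sd^2 / (latent_sd^2 + noise_sd^2) = 0.8`, and background
#' correlations vanish in expectation.
#'
#' @param n_sites number of sites.
#' @param n_frames number of frames (>= 10).
#' @param blocks list of planted couplings, each
#'   `list(a = sites, b = sites, sign = +1 or -1)`; sites must not be reused
#'   across blocks.
#' @param noise_sd per-site independent noise scale (Angstrom).
#' @param latent_sd shared latent motion scale (Angstrom).
#' @param seed integer seed.
#' @return a `Trajectory`.
#' @export
make_correlated_trajectory <- function(n_sites, n_frames, blocks = list(),
                                       noise_sd = 0.5, latent_sd = 1,
                                       seed = 1) {
  if (n_frames < 10L) stop("need at least 10 frames")
  used <- unlist(lapply(blocks, function(b) c(b$a, b$b)))
  if (anyDuplicated(used)) stop("planted blocks overlap")
  if (length(used) && max(used) > n_sites) stop("block site out of range")
  set.seed(as.integer(seed %% 2147483647))
  base <- cbind(10 * seq_len(n_sites), 0, 0)
  disp <- array(stats::rnorm(n_frames * n_sites * 3, 0, noise_sd),
                dim = c(n_frames, n_sites, 3))
  for (b in blocks) {
    sgn <- if (is.null(b$sign)) 1 else b$sign
    z <- matrix(stats::rnorm(n_frames * 3, 0, latent_sd), n_frames, 3)
    for (s in b$a) disp[, s, ] <- disp[, s, ] + z
    for (s in b$b) disp[, s, ] <- disp[, s, ] + sgn * z
  }
  frames <- lapply(seq_len(n_frames), function(t) base + disp[t, , ])
  trajectory_new(.bead_atoms(base), frames, seq_len(n_frames),
                 title = "planted-correlation trajectory")
}

#' Hydrogen-bond geometry fixture with controlled occupancy
#'
#' Builds a donor/hydrogen/acceptor triad trajectory in which the default
#' geometric criteria (donor-acceptor distance <= 3.5 Angstrom, donor-H-
#' acceptor angle >= 120 degrees) hold in exactly
#' `round(target * n_frames / 100)` frames; which frames satisfy them is a
#' deterministic function of the seed.
#'
#' @param occupancy_target target occupancy in percent (0..100).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return list with `trajectory` (a `Trajectory` containing atoms N, H of
#'   residue 1 and O of residue 2), `pairs` (one-row data.frame for
#'   [hbond_occupancy()]), and `n_satisfied` (ground truth frame count).
#' @export
make_hbond_fixture <- function(occupancy_target, n_frames = 100, seed = 1) {
  if (occupancy_target < 0 || occupancy_target > 100) {
    stop("occupancy target must be in [0, 100]")
  }
  set.seed(as.integer(seed %% 2147483647))
  n_good <- round(occupancy_target * n_frames / 100)
  good <- sort(sample.int(n_frames, n_good))
  atoms <- data.frame(
    name = c("N", "H", "O"), element = c("N", "H", "O"),
    resid = c(1L, 1L, 2L), resname = c("ALA", "ALA", "SER"),
    chain = "A",
    x = c(0, 1, 2.9), y = 0, z = 0, stringsAsFactors = FALSE)
  frames <- lapply(seq_len(n_frames), function(t) {
    ax <- if (t %in% good) 2.9 else 6.0  # far acceptor breaks the distance
    matrix(c(0, 0, 0, 1, 0, 0, ax, 0, 0), 3, 3, byrow = TRUE)
  })
  traj <- trajectory_new(atoms, frames, seq_len(n_frames),
                         title = sprintf("hbond fixture (%.1f%%)",
                                         occupancy_target))
  pairs <- data.frame(donor_resid = 1L, donor_atom = "N",
                      acceptor_resid = 2L, acceptor_atom = "O",
                      stringsAsFactors = FALSE)
  list(trajectory = traj, pairs = pairs, n_satisfied = n_good)
}

#' Hollow spherical shell fixture for pocket validation
#'
#' Atoms on a Fibonacci sphere of the given radius enclose a single interior
#' cavity whose probe-accessible volume approaches the continuum value
#' `(4/3) * pi * (radius - r_atom - probe)^3` as the shell gets denser (the
#' probe-accessible region bulges slightly into the angular gaps between
#' discrete atoms; at the default density the bias is about +6%).
#'
#' @param n_atoms number of shell atoms (default 150).
#' @param radius shell radius in Angstrom (default 8).
#' @param element element symbol for the shell atoms (default "C",
#'   radius 1.70 Angstrom).
#' @return a `Structure`.
#' @export
make_shell_fixture <- function(n_atoms = 150, radius = 8, element = "C") {
  i <- seq(0, n_atoms - 1)
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / (n_atoms - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  structure_new(data.frame(
    name = element, element = element, resid = seq_len(n_atoms),
    resname = "SPH", chain = "A",
    x = radius * r * cos(ga * i), y = radius * r * sin(ga * i),
    z = radius * z, stringsAsFactors = FALSE),
    title = sprintf("hollow shell (n=%d, R=%g A)", n_atoms, radius))
}
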