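test_that("RMSD series vanishes for copies and rigid motions of the reference", {
  set.seed(31)
  base <- matrix(rnorm(36), 12, 3)
  at <- make_beads(base)$atoms
  frames <- list(base, base, base)
  tr <- trajectory_new(at, frames, 1:3)
  expect_equal(rmsd_series(tr, base)$rmsd, rep(0, 3), tolerance = 1e-12)

  rot_frames <- lapply(1:4, function(i) {
    sweep(base %*% t(random_rotation()), 2, rnorm(3), `+`)
  })
  tr2 <- trajectory_new(at, rot_frames, 1:4)
  expect_lte(max(rmsd_series(tr2, base)$rmsd), 1e-9)
})

test_that("RMSD series equals frame-by-frame superposition calls", {
  set.seed(32)
  base <- matrix(rnorm(30), 10, 3)
  at <- make_beads(base)$atoms
  frames <- lapply(1:5, function(i) base + matrix(rnorm(30, 0, 0.3 * i), 10, 3))
  tr <- trajectory_new(at, frames, 1:5)
  got <- rmsd_series(tr, base)$rmsd
  manual <- vapply(frames, function(X) {
    kabsch_superpose(X, base, at$mass)$rmsd
  }, numeric(1))
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("DCCM reproduces hand-computed correlations and the +/-1 limits", {
  # 3-site, 4-frame table evaluated by the brute-force formula oracle
  frames <- list(
    rbind(c(0, 0, 0), c(10, 0, 0), c(20, 1, 0)),
    rbind(c(1, 0, 0), c(10, 1, 0), c(20, 0, 1)),
    rbind(c(0, 1, 0), c(11, 0, 0), c(20, 0, 0)),
    rbind(c(1, 1, 0), c(11, 1, 0), c(21, 1, 1)))
  at <- make_beads(frames[[1]])$atoms
  tr <- trajectory_new(at, frames, 1:4)
  C <- compute_dccm(tr, fit = FALSE)
  expect_equal(unclass(unname(C)), oracle_dccm(frames), tolerance = 1e-12, ignore_attr = TRUE)

  # perfectly co-moving and counter-moving sites
  set.seed(33)
  z <- matrix(rnorm(60), 20, 3)
  co <- lapply(seq_len(20), function(t) {
    rbind(c(0, 0, 0) + z[t, ], c(10, 0, 0) + z[t, ], c(20, 0, 0) - z[t, ])
  })
  tr2 <- trajectory_new(at, co, 1:20)
  C2 <- compute_dccm(tr2, fit = FALSE)
  expect_equal(C2[1, 2], 1, tolerance = 1e-12)
  expect_equal(C2[1, 3], -1, tolerance = 1e-12)
  expect_equal(unname(diag(C2)), rep(1, 3))
  expect_true(isSymmetric(unclass(C2)))
  expect_lte(max(abs(C2)), 1 + 1e-9)
})

test_that("frame fitting removes rigid-body motion without inventing correlations", {
  # frames differ only by rigid motions on top of independent per-site
  # noise; after fitting, the correlations must match those of the same
  # noise without any rigid motion. (The comparison is against that
  # motion-free baseline because finite-frame sampling noise alone puts
  # individual entries well above 0.05; the rigid-fit itself removes six
  # degrees of freedom and leaves only an O(1/n) residual.)
  set.seed(34)
  n <- 60
  base <- cbind(10 * seq_len(n), 0, 0)
  noise <- lapply(1:200, function(t) matrix(rnorm(3 * n, 0, 0.5), n, 3))
  at <- make_beads(base)$atoms
  plain <- trajectory_new(at, lapply(noise, function(d) base + d), 1:200)
  moved <- trajectory_new(at, lapply(noise, function(d) {
    sweep((base + d) %*% t(random_rotation()), 2, rnorm(3, 0, 5), `+`)
  }), 1:200)
  C_plain <- compute_dccm(plain, fit = FALSE)
  C_fit <- compute_dccm(moved, fit = TRUE)
  delta <- abs(C_fit - C_plain)
  expect_lte(mean(delta[upper.tri(delta)]), 0.05)
  expect_lte(max(delta), 0.15)
  # without fitting, the rigid motions would dominate everything
  C_nofit <- compute_dccm(moved, fit = FALSE)
  expect_gt(max(abs(C_nofit - C_plain)), 0.5)
})

test_that("DCCM rejects degenerate inputs and masks zero-variance sites", {
  base <- cbind(1:4 * 8, 0, 0)
  at <- make_beads(base)$atoms
  expect_error(compute_dccm(trajectory_new(at, list(base), 1)),
               "at least 2 frames")
  frozen <- trajectory_new(at, list(base, base, base), 1:3)
  expect_error(suppressWarnings(compute_dccm(frozen, fit = FALSE)),
               "zero variance")
  # one frozen site among moving ones -> masked row/column, warning
  set.seed(35)
  frames <- lapply(1:30, function(t) {
    d <- matrix(rnorm(12, 0, 0.5), 4, 3)
    d[2, ] <- 0
    base + d
  })
  tr <- trajectory_new(at, frames, 1:30)
  expect_warning(C <- compute_dccm(tr, fit = FALSE), "masked")
  expect_true(all(is.na(C[2, -2])))
  expect_false(anyNA(C[-2, -2]))
})

test_that("hydrogen-bond occupancy counts criterion-passing frames exactly", {
  fx <- make_hbond_fixture(50, n_frames = 100, seed = 36)
  tab <- hbond_occupancy(fx$trajectory, fx$pairs)
  expect_equal(tab$occupancy, 50.0)
  expect_equal(hbond_occupancy(make_hbond_fixture(0, 50, 1)$trajectory,
                               fx$pairs)$occupancy, 0.0)
  expect_equal(hbond_occupancy(make_hbond_fixture(100, 50, 1)$trajectory,
                               fx$pairs)$occupancy, 100.0)
})

test_that("occupancy is invariant under frame reordering", {
  fx <- make_hbond_fixture(37, n_frames = 80, seed = 37)
  tr <- fx$trajectory
  set.seed(38)
  perm <- sample(n_frames(tr))
  shuffled <- trajectory_new(tr$atoms, tr$frames[perm], seq_along(perm))
  expect_equal(hbond_occupancy(shuffled, fx$pairs)$occupancy,
               hbond_occupancy(tr, fx$pairs)$occupancy)
})

test_that("pairs without a donor hydrogen are skipped with a warning", {
  fx <- make_hbond_fixture(50, n_frames = 20, seed = 39)
  bad_pairs <- data.frame(donor_resid = 2L, donor_atom = "O",
                          acceptor_resid = 1L, acceptor_atom = "N")
  expect_warning(tab <- hbond_occupancy(fx$trajectory, bad_pairs),
                 "no hydrogen")
  expect_equal(nrow(tab), 0L)
})

test_that("hydrophobic contacts use a strict 4.5 A carbon-carbon cutoff", {
  two_c <- function(d) {
    structure_new(data.frame(name = c("C1", "C2"), element = "C",
                             resid = 1:2, resname = "LEU", chain = "A",
                             x = c(0, d), y = 0, z = 0))
  }
  expect_true(hydrophobic_contacts(two_c(4.49),
                                   data.frame(res_a = 1, res_b = 2))$contact)
  expect_false(hydrophobic_contacts(two_c(4.50),
                                    data.frame(res_a = 1, res_b = 2))$contact)
})

test_that("per-frame contact minima match an all-pairs oracle and are symmetric", {
  set.seed(40)
  at <- data.frame(name = rep(c("CA", "CB", "CG"), 3),
                   element = "C",
                   resid = rep(1:3, each = 3), resname = "LEU", chain = "A",
                   x = 0, y = 0, z = 0)
  frames <- lapply(1:6, function(t) matrix(rnorm(27, 0, 4), 9, 3))
  tr <- trajectory_new(at, frames, 1:6)
  got <- hydrophobic_contacts(tr, data.frame(res_a = 1, res_b = 3))
  swapped <- hydrophobic_contacts(tr, data.frame(res_a = 3, res_b = 1))
  manual <- vapply(frames, function(X) {
    min(as.matrix(stats::dist(X))[1:3, 7:9])
  }, numeric(1))
  expect_equal(got$min_dist, manual, tolerance = 1e-12)
  expect_equal(swapped$min_dist, got$min_dist)
  expect_equal(swapped$contact, got$contact)

  no_c <- at
  no_c$element <- c(rep("C", 6), rep("N", 3))
  tr2 <- trajectory_new(no_c, frames, 1:6)
  expect_error(hydrophobic_contacts(tr2, data.frame(res_a = 1, res_b = 3)),
               "no carbon")
})

test_that("segment mass-center distances are internal coordinates", {
  at <- data.frame(name = "CA", element = "X", resid = 1:2, resname = "GLY",
                   chain = "A", x = c(0, 7), y = 0, z = 0)
  segs <- segment_table(list(
    list(name = "a", class = "strand", ranges = list(c(1L, 1L))),
    list(name = "b", class = "strand", ranges = list(c(2L, 2L)))))
  frames <- lapply(1:4, function(t) cbind(c(0, 7) + t, t, -2 * t))
  tr <- trajectory_new(at, frames, 1:4)
  out <- segment_distance_series(tr, segs, list(c("a", "b")))
  expect_equal(out$dist, rep(7, 4), tolerance = 1e-12)
  expect_error(segment_distance_series(tr, segs, list(c("a", "zz"))),
               "unknown segment")
})

test_that("segment distances trend between their end-state values along a transition", {
  toy <- make_two_state_toy(60, seed = 5)
  Xo <- coords(toy$open)
  Xc <- coords(toy$closed)
  # linear morph standing in for a transition path
  frames <- lapply(seq(0, 1, length.out = 21), function(a) {
    (1 - a) * Xo + a * Xc
  })
  tr <- trajectory_new(toy$open$atoms, frames, 1:21)
  nm <- names(toy$segments)
  tail_seg <- nm[grepl("7/8", nm)]
  helix_seg <- grep("^αC", nm, value = TRUE)
  out <- segment_distance_series(tr, toy$segments,
                                 list(c(tail_seg, helix_seg)))
  # endpoint values computed directly from the reference structures
  d_end <- function(X) {
    sa <- which(toy$open$atoms$resid %in%
                  segment_residues(toy$segments, tail_seg))
    sb <- which(toy$open$atoms$resid %in%
                  segment_residues(toy$segments, helix_seg))
    m <- toy$open$atoms$mass
    sqrt(sum((colSums(X[sa, ] * m[sa]) / sum(m[sa]) -
                colSums(X[sb, ] * m[sb]) / sum(m[sb]))^2))
  }
  expect_equal(out$dist[1], d_end(Xo), tolerance = 1e-9)
  expect_equal(out$dist[21], d_end(Xc), tolerance = 1e-9)
  # monotone trend between the endpoint values
  expect_true(all(diff(out$dist) < 0) || all(diff(out$dist) > 0))
})
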