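# Shared helpers: small structure builders and independent oracles.
# Oracles here are deliberately written without reusing package internals.

make_beads <- function(xyz, element = "X", name = "CA") {
  structure_new(data.frame(
    name = name, element = element, resid = seq_len(nrow(xyz)),
    resname = "GLY", chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

rotation_z <- function(angle) {
  matrix(c(cos(angle), -sin(angle), 0,
           sin(angle), cos(angle), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_rotation(q / sqrt(sum(q^2)))
}

quat_rotation <- function(q) {
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}

# brute-force best-fit weighted RMSD: numerical minimization over rotations
# parameterized by quaternions (multi-start + Nelder-Mead refinement),
# independent of the SVD route under test
oracle_rmsd <- function(X, Y, w = NULL, n_starts = 200) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  wn <- w / sum(w)
  Xc <- sweep(X, 2, colSums(X * wn))
  Yc <- sweep(Y, 2, colSums(Y * wn))
  f <- function(q) {
    R <- quat_rotation(q / sqrt(sum(q^2)))
    sqrt(sum(wn * rowSums((Xc %*% t(R) - Yc)^2)))
  }
  qs <- matrix(stats::rnorm(4 * n_starts), n_starts, 4)
  vals <- apply(qs, 1, f)
  best <- Inf
  for (b in order(vals)[1:3]) {
    o <- stats::optim(qs[b, ], f,
                      control = list(reltol = 1e-15, maxit = 5000))
    best <- min(best, o$value)
  }
  best
}

# direct double-loop evaluation of the displacement-vector correlation
# (no fitting), used as the DCCM formula oracle
oracle_dccm <- function(frames) {
  F_ <- length(frames)
  n <- nrow(frames[[1]])
  mean_xyz <- Reduce(`+`, frames) / F_
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0; vi <- 0; vj <- 0
      for (t in seq_len(F_)) {
        di <- frames[[t]][i, ] - mean_xyz[i, ]
        dj <- frames[[t]][j, ] - mean_xyz[j, ]
        num <- num + sum(di * dj)
        vi <- vi + sum(di^2)
        vj <- vj + sum(dj^2)
      }
      C[i, j] <- (num / F_) / sqrt((vi / F_) * (vj / F_))
    }
  }
  C
}

# default desk-scale toy system + model, shared across simulator tests
toy_fixture <- function(seed = 1) {
  toy <- make_two_state_toy(60, seed = seed)
  list(toy = toy, model = build_dual_basin(toy$open, toy$closed))
}

short_protocol <- function(prod = 8, dt = 0.01, stride = 10, ...) {
  sim_protocol(min_stages = list(c(100, 50), c(25, 50), c(0, 100)),
               heat_duration = 1, equil_duration = 1, prod_duration = prod,
               dt = dt, stride = stride, ...)
}
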