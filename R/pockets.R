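# Probe-based pocket/cavity measurement on a Cartesian grid. Voxels inside
# an atom's van der Waals radius are protein; voxels whose center is within
# probe_radius of an atom surface cannot host the probe center; solvent is
# flood-filled from the box boundary through probe-accessible space; the
# remaining probe-accessible components are pockets/cavities, ranked by
# volume. Volumes are voxel counts x spacing^3, areas exposed-face counts x
# spacing^2. This is a grid flood-fill algorithm (LIGSITE/POCKET family),
# not an alpha-shape method; the algorithm family is recorded in the result
# metadata.

# sweep-based flood fill (6-connectivity): propagate `reach` through `open`
# voxels with forward/backward sweeps along each axis until stable
.flood_fill <- function(reach, open) {
  dims <- dim(open)
  repeat {
    before <- sum(reach)
    for (i in 2:dims[1]) {
      reach[i, , ] <- reach[i, , ] | (reach[i - 1L, , ] & open[i, , ])
    }
    for (i in (dims[1] - 1L):1) {
      reach[i, , ] <- reach[i, , ] | (reach[i + 1L, , ] & open[i, , ])
    }
    for (j in 2:dims[2]) {
      reach[, j, ] <- reach[, j, ] | (reach[, j - 1L, ] & open[, j, ])
    }
    for (j in (dims[2] - 1L):1) {
      reach[, j, ] <- reach[, j, ] | (reach[, j + 1L, ] & open[, j, ])
    }
    for (k in 2:dims[3]) {
      reach[, , k] <- reach[, , k] | (reach[, , k - 1L] & open[, , k])
    }
    for (k in (dims[3] - 1L):1) {
      reach[, , k] <- reach[, , k] | (reach[, , k + 1L] & open[, , k])
    }
    if (sum(reach) == before) break
  }
  reach
}

# 26-connected component labels of the TRUE voxels of `mask` (BFS over
# linear indices with precomputed neighbor offsets)
.label_components <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  labels <- integer(length(mask))
  if (length(idx) == 0L) return(list(labels = labels, n = 0L))
  # neighbor offsets in linear indexing
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  ar <- arrayInd(idx, dims)
  pos_key <- (ar[, 3] - 1L) * (dims[1] * dims[2]) +
    (ar[, 2] - 1L) * dims[1] + ar[, 1]
  lookup <- integer(prod(dims))
  lookup[pos_key] <- seq_along(idx)
  comp <- integer(length(idx))
  ncomp <- 0L
  for (s in seq_along(idx)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      cur <- queue
      queue <- integer()
      cc <- ar[cur, , drop = FALSE]
      for (o in seq_len(nrow(off))) {
        nb <- cc
        nb[, 1] <- nb[, 1] + off[o, 1]
        nb[, 2] <- nb[, 2] + off[o, 2]
        nb[, 3] <- nb[, 3] + off[o, 3]
        ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
        if (!any(ok)) next
        key <- (nb[ok, 3] - 1L) * (dims[1] * dims[2]) +
          (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
        tgt <- lookup[key]
        tgt <- tgt[tgt > 0L]
        tgt <- tgt[comp[tgt] == 0L]
        if (length(tgt)) {
          comp[tgt] <- ncomp
          queue <- c(queue, tgt)
        }
      }
      queue <- unique(queue)
    }
  }
  labels[idx] <- comp
  list(labels = labels, n = ncomp)
}

#' Measure pockets and cavities of a structure on a grid
#'
#' Grid-based probe analysis: voxels within an atom's element radius are
#' protein; voxels whose center lies closer than `probe_radius` to the
#' nearest atom surface are inaccessible to the probe center; solvent is
#' flood-filled from the box boundary through probe-accessible space; the
#' probe-accessible connected components not reachable from the boundary are
#' the pockets/cavities, ranked by volume (descending). Lining residues are
#' those with an atom whose surface comes within `probe_radius` + one voxel
#' of a component voxel.
#'
#' @param structure a `Structure` (>= 4 atoms).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param grid_spacing voxel edge, Angstrom, in (0.1, 1].
#' @param radii named per-element radius table (Angstrom); defaults to the
#'   packaged Bondi-style table (C 1.70, N 1.55, O 1.52, S 1.80; bead 3.4).
#' @return an object of class `PocketResult`: data.frame with columns
#'   `pocket`, `volume`, `area`, `n_voxels`, `lining_residues`
#'   (comma-separated), plus attributes `probe_radius`, `grid_spacing`,
#'   `algorithm`, and `voxels` (list of n x 3 voxel-center matrices per
#'   pocket, for visualization).
#' @export
measure_pockets <- function(structure, probe_radius = 1.4,
                            grid_spacing = 0.5, radii = NULL) {
  stopifnot(inherits(structure, "Structure"))
  X <- coords(structure)
  if (nrow(X) < 4L) stop("need at least 4 atoms")
  if (grid_spacing <= 0.1 || grid_spacing > 1) {
    stop("grid spacing must be in (0.1, 1]")
  }
  rv <- element_radius(structure$atoms$element)
  if (!is.null(radii)) {
    custom <- radii[toupper(structure$atoms$element)]
    rv[!is.na(custom)] <- custom[!is.na(custom)]
  }
  if (anyNA(rv)) stop("no radius for element(s): ",
                      paste(unique(structure$atoms$element[is.na(rv)]),
                            collapse = ", "))
  s <- grid_spacing
  margin <- 3 * (probe_radius + max(rv))
  lo <- apply(X, 2, min) - margin
  hi <- apply(X, 2, max) + margin
  gx <- seq(lo[1], hi[1], by = s)
  gy <- seq(lo[2], hi[2], by = s)
  gz <- seq(lo[3], hi[3], by = s)
  dims <- c(length(gx), length(gy), length(gz))

  protein <- array(FALSE, dims)
  blocked <- array(FALSE, dims)
  for (a in seq_len(nrow(X))) {
    rb <- rv[a] + probe_radius
    ix <- which(abs(gx - X[a, 1]) <= rb)
    iy <- which(abs(gy - X[a, 2]) <= rb)
    iz <- which(abs(gz - X[a, 3]) <= rb)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((gx[ix] - X[a, 1])^2, (gy[iy] - X[a, 2])^2, `+`),
                (gz[iz] - X[a, 3])^2, `+`)
    protein[ix, iy, iz] <- protein[ix, iy, iz] | (d2 <= rv[a]^2)
    blocked[ix, iy, iz] <- blocked[ix, iy, iz] | (d2 <= rb^2)
  }
  accessible <- !blocked
  seed <- array(FALSE, dims)
  seed[c(1, dims[1]), , ] <- TRUE
  seed[, c(1, dims[2]), ] <- TRUE
  seed[, , c(1, dims[3])] <- TRUE
  seed <- seed & accessible
  solvent <- .flood_fill(seed, accessible)
  pocketable <- accessible & !solvent

  lab <- .label_components(pocketable)
  rows <- list()
  voxel_sets <- list()
  if (lab$n > 0L) {
    labels <- array(lab$labels, dims)
    for (cmp in seq_len(lab$n)) {
      vox <- which(labels == cmp)
      nvox <- length(vox)
      ai <- arrayInd(vox, dims)
      # exposed faces: 6-neighbors outside the component
      faces <- 0L
      for (axis in 1:3) {
        for (dir in c(-1L, 1L)) {
          nb <- ai
          nb[, axis] <- nb[, axis] + dir
          inside <- nb[, axis] >= 1L & nb[, axis] <= dims[axis]
          faces <- faces + sum(!inside)
          if (any(inside)) {
            lin <- (nb[inside, 3] - 1L) * (dims[1] * dims[2]) +
              (nb[inside, 2] - 1L) * dims[1] + nb[inside, 1]
            faces <- faces + sum(labels[lin] != cmp)
          }
        }
      }
      centers <- cbind(gx[ai[, 1]], gy[ai[, 2]], gz[ai[, 3]])
      # lining residues: atom surface within probe + 1 voxel of a component
      # voxel center
      lining <- integer()
      for (a in seq_len(nrow(X))) {
        reach <- rv[a] + probe_radius + s
        dmin2 <- min(colSums((t(centers) - X[a, ])^2))
        if (dmin2 <= reach^2) lining <- c(lining, structure$atoms$resid[a])
      }
      rows[[cmp]] <- data.frame(
        volume = nvox * s^3, area = faces * s^2, n_voxels = nvox,
        lining_residues = paste(sort(unique(lining)), collapse = ","),
        stringsAsFactors = FALSE)
      voxel_sets[[cmp]] <- centers
    }
    out <- do.call(rbind, rows)
    ord <- order(-out$volume)
    out <- out[ord, , drop = FALSE]
    voxel_sets <- voxel_sets[ord]
    out <- cbind(pocket = seq_len(nrow(out)), out)
    rownames(out) <- NULL
  } else {
    out <- data.frame(pocket = integer(), volume = numeric(),
                      area = numeric(), n_voxels = integer(),
                      lining_residues = character())
  }
  attr(out, "probe_radius") <- probe_radius
  attr(out, "grid_spacing") <- s
  attr(out, "algorithm") <- "grid flood-fill (probe-accessible components)"
  attr(out, "voxels") <- voxel_sets
  class(out) <- c("PocketResult", "data.frame")
  out
}

#' @export
print.PocketResult <- function(x, ...) {
  cat("PocketResult:", nrow(x), "pocket(s); probe",
      attr(x, "probe_radius"), "A, spacing", attr(x, "grid_spacing"), "A\n")
  if (nrow(x)) {
    print.data.frame(x[, c("pocket", "volume", "area", "n_voxels")],
                     row.names = FALSE)
  }
  invisible(x)
}

#' Write pocket voxels as a pseudo-atom PDB point cloud
#'
#' @param result a `PocketResult`.
#' @param path output path.
#' @param pocket pocket rank to dump (default 1).
#' @return invisibly, `path`.
#' @export
write_pocket_voxels <- function(result, path, pocket = 1) {
  vox <- attr(result, "voxels")
  if (pocket > length(vox)) stop("no such pocket")
  v <- vox[[pocket]]
  st <- structure_new(data.frame(
    name = "DUM", element = "H", resid = 1L, resname = "PKT", chain = "P",
    x = v[, 1], y = v[, 2], z = v[, 3], stringsAsFactors = FALSE),
    title = sprintf("pocket %d voxel centers", pocket))
  write_pdb(st, path)
}

#' Match pockets across two structures by lining-residue overlap
#'
#' Utility for pairing "topologically equivalent" pockets of two conformers:
#' the Jaccard index of the lining-residue sets.
#'
#' @param a,b `PocketResult`s.
#' @return data.frame with columns `pocket_a`, `pocket_b`, `jaccard`,
#'   ordered by decreasing overlap.
#' @export
match_pockets <- function(a, b) {
  parse_l <- function(x) lapply(strsplit(x$lining_residues, ","), as.integer)
  la <- parse_l(a)
  lb <- parse_l(b)
  rows <- list()
  for (i in seq_along(la)) {
    for (j in seq_along(lb)) {
      u <- union(la[[i]], lb[[j]])
      jac <- if (length(u)) length(intersect(la[[i]], lb[[j]])) / length(u)
      else 0
      rows[[length(rows) + 1L]] <- data.frame(pocket_a = i, pocket_b = j,
                                              jaccard = jac)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(pocket_a = integer(), pocket_b = integer(),
                      jaccard = numeric()))
  }
  out[order(-out$jaccard), ]
}
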