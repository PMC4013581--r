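# End-to-end orchestration: equilibrate both end states, scan TMD force
# constants, run bidirectional TMD, extract and re-equilibrate intermediate
# conformations, and run the analysis suite. All outputs land under one run
# directory keyed by a hash of the configuration; completed stages (marked
# by .done files) are skipped on rerun with an unchanged config.

#' Pipeline configuration
#'
#' @param out_dir output directory root.
#' @param seed global seed; per-run seeds are derived deterministically.
#' @param n_residues toy-system size.
#' @param protocol a [sim_protocol()] used for every dynamics run.
#' @param k_scan TMD force constants to scan (kcal/(mol A^2)).
#' @param k_criterion convergence criterion for the scan: a k passes when the
#'   final backbone RMSD to the target is below this value (Angstrom).
#' @param tmd_k force constant for the production TMD runs; `NULL` picks the
#'   smallest passing k from the scan.
#' @param extract_fracs fractions of the TMD schedule at which intermediate
#'   conformations are extracted (in (0,1)).
#' @param reequil_duration production length (ps) of the intermediate
#'   re-equilibration CMD runs.
#' @param network_threshold correlation threshold for the segment network.
#' @param contact_cutoff hydrophobic-contact cutoff (Angstrom).
#' @param pocket_spacing grid spacing for pocket measurement (Angstrom).
#' @param run_occupancy run hydrogen-bond occupancy analysis; off by default
#'   because the coarse-grained toy has no hydrogens (enable for all-atom
#'   input trajectories).
#' @return an object of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_residues = 60,
                            protocol = sim_protocol(),
                            k_scan = c(0.2, 0.5, 0.8, 1.0),
                            k_criterion = 2.0, tmd_k = NULL,
                            extract_fracs = c(0.35, 0.65, 0.95),
                            reequil_duration = 10,
                            network_threshold = 0.5,
                            contact_cutoff = 4.5,
                            pocket_spacing = 0.5,
                            run_occupancy = FALSE) {
  if (any(extract_fracs <= 0 | extract_fracs >= 1)) {
    stop("extraction fractions must be in (0, 1)")
  }
  if (any(k_scan <= 0)) stop("k-scan values must be positive")
  obj <- list(out_dir = out_dir, seed = seed, n_residues = n_residues,
              protocol = protocol, k_scan = k_scan,
              k_criterion = k_criterion, tmd_k = tmd_k,
              extract_fracs = extract_fracs,
              reequil_duration = reequil_duration,
              network_threshold = network_threshold,
              contact_cutoff = contact_cutoff,
              pocket_spacing = pocket_spacing,
              run_occupancy = run_occupancy)
  class(obj) <- "PipelineConfig"
  obj
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), "out_dir")], tmp)
  unname(tools::md5sum(tmp))
}

#' Select the TMD force constant from a scan
#'
#' The smallest k whose final RMSD to the target is below the criterion.
#'
#' @param scan data.frame with columns `k` and `final_rmsd`.
#' @param criterion convergence criterion (Angstrom, default 2.0).
#' @return the selected k, or `NA` when no k passes.
#' @export
select_force_constant <- function(scan, criterion = 2.0) {
  if (nrow(scan) == 0L) stop("empty scan")
  pass <- scan$k[scan$final_rmsd < criterion]
  if (length(pass) == 0L) return(NA_real_)
  min(pass)
}

.stage <- function(dir, name, hash, fn) {
  marker <- file.path(dir, paste0(".done-", name, "-", hash))
  if (file.exists(marker)) {
    message("stage '", name, "': up to date, skipping")
    return(invisible(FALSE))
  }
  message("stage '", name, "': running")
  t0 <- Sys.time()
  tryCatch(fn(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("stage '%s': done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  file.create(marker)
  invisible(TRUE)
}

# time-average structure: mean of post-burn-in frames after superposition
# onto the final frame
.time_average <- function(traj, burn_frac = 0.5) {
  F_ <- length(traj$frames)
  keep <- seq.int(max(1L, ceiling(burn_frac * F_)), F_)
  ref <- traj$frames[[F_]]
  w <- traj$atoms$mass
  acc <- matrix(0, nrow(ref), 3)
  for (t in keep) {
    acc <- acc + kabsch_superpose(traj$frames[[t]], ref, w)$transformed
  }
  set_coords(frame_structure(traj, F_), acc / length(keep))
}

#' Run the full transition pipeline on the toy two-state system
#'
#' Stages: generate the toy system, minimize and equilibrate both end
#' states, scan TMD force constants (forward direction), run forward and
#' reverse TMD with the selected k, extract intermediates at the configured
#' schedule fractions and re-equilibrate them by short unbiased runs, then
#' write the analysis tables (RMSD series, DCCM, contacts, segment
#' distances, pockets per extracted conformation, segment network). A JSON
#' manifest records every parameter, seed and per-stage output.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest (also written to `manifest.json` in the
#'   run directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  hash <- .config_hash(config)
  dir_ <- file.path(config$out_dir, paste0("run-", substr(hash, 1, 8)))
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  pr <- config$protocol
  seed0 <- config$seed

  toy <- make_two_state_toy(config$n_residues, seed = seed0)
  model <- build_dual_basin(toy$open, toy$closed)
  p <- function(...) file.path(dir_, ...)

  manifest <- list(config_hash = hash, seed = seed0,
                   n_residues = config$n_residues,
                   k_scan = config$k_scan,
                   extract_fracs = config$extract_fracs,
                   stages = list())

  .stage(dir_, "toy", hash, function() {
    write_pdb(toy$open, p("toy_open.pdb"))
    write_pdb(toy$closed, p("toy_closed.pdb"))
    write_segments(toy$segments, p("toy_segments.txt"))
  })
  manifest$stages$toy <- list(files = c("toy_open.pdb", "toy_closed.pdb",
                                        "toy_segments.txt"))

  .stage(dir_, "equilibrate", hash, function() {
    for (st in c("open", "closed")) {
      mini <- minimize(model, toy[[st]], stages = pr$min_stages,
                       reference = toy[[st]])
      write_pdb(mini, p(sprintf("min_%s.pdb", st)))
      eq <- run_cmd(model, mini, pr, seed = seed0 + match(st, c("open",
                                                                "closed")))
      write_trajectory(eq, p(sprintf("equil_%s.pdb", st)))
      write_run_log(eq, p(sprintf("equil_%s.log", st)))
      write_pdb(frame_structure(eq, n_frames(eq)),
                p(sprintf("equil_%s_final.pdb", st)))
    }
  })
  manifest$stages$equilibrate <- list(seeds = seed0 + 1:2)

  scan_file <- p("k_scan.tsv")
  .stage(dir_, "scan-k", hash, function() {
    start <- read_pdb(p("equil_open_final.pdb"))
    rows <- lapply(seq_along(config$k_scan), function(i) {
      k <- config$k_scan[i]
      tr <- run_tmd(model, start, toy$closed, k = k, protocol = pr,
                    seed = seed0 + 10 + i)
      data.frame(k = k,
                 final_rmsd = rmsd(tr$frames[[n_frames(tr)]],
                                   coords(toy$closed),
                                   weights = toy$closed$atoms$mass))
    })
    utils::write.table(do.call(rbind, rows), scan_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  scan <- utils::read.table(scan_file, header = TRUE, sep = "\t")
  k_sel <- if (is.null(config$tmd_k)) {
    select_force_constant(scan, config$k_criterion)
  } else {
    config$tmd_k
  }
  if (is.na(k_sel)) {
    stop("pipeline stage 'scan-k' failed: no force constant met the ",
         config$k_criterion, " A criterion", call. = FALSE)
  }
  manifest$stages$scan_k <- list(seeds = seed0 + 10 +
                                   seq_along(config$k_scan),
                                 table = "k_scan.tsv", k_selected = k_sel)

  .stage(dir_, "tmd", hash, function() {
    runs <- list(forward = list(read_pdb(p("equil_open_final.pdb")),
                                toy$closed),
                 reverse = list(read_pdb(p("equil_closed_final.pdb")),
                                toy$open))
    for (nm in names(runs)) {
      tr <- run_tmd(model, runs[[nm]][[1]], runs[[nm]][[2]], k = k_sel,
                    protocol = pr,
                    seed = seed0 + 20 + match(nm, names(runs)))
      write_trajectory(tr, p(sprintf("tmd_%s.pdb", nm)))
      write_run_log(tr, p(sprintf("tmd_%s.log", nm)))
    }
  })
  manifest$stages$tmd <- list(seeds = seed0 + 21:22, k = k_sel)

  .stage(dir_, "intermediates", hash, function() {
    fw <- read_trajectory(p("tmd_forward.pdb"))
    t0 <- pr$heat_duration + pr$equil_duration
    t1 <- t0 + 0.8 * pr$prod_duration  # run_tmd default schedule span
    for (i in seq_along(config$extract_fracs)) {
      tx <- t0 + config$extract_fracs[i] * (t1 - t0)
      idx <- which.min(abs(fw$times - tx))
      conf <- frame_structure(fw, idx)
      write_pdb(conf, p(sprintf("intermediate_%d.pdb", i)))
      re <- run_cmd(model, conf,
                    sim_protocol(min_stages = pr$min_stages,
                                 heat_duration = 0, equil_duration = 0,
                                 prod_duration = config$reequil_duration,
                                 dt = pr$dt, stride = pr$stride,
                                 temperature = pr$temperature),
                    seed = seed0 + 30 + i)
      write_pdb(.time_average(re), p(sprintf("intermediate_%d_avg.pdb", i)))
    }
  })
  manifest$stages$intermediates <-
    list(seeds = seed0 + 30 + seq_along(config$extract_fracs),
         n = length(config$extract_fracs))

  .stage(dir_, "analyze", hash, function() {
    fw <- read_trajectory(p("tmd_forward.pdb"))
    fw$atoms$mass <- toy$open$atoms$mass
    segs <- toy$segments
    sn <- names(segs)
    utils::write.table(rmsd_series(fw, toy$closed), p("rmsd_series.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dc <- compute_dccm(fw)
    write_dccm(dc, p("dccm.tsv"))
    pick <- function(pat) sn[grepl(pat, sn)][1]
    pair_names <- list(c(pick("β1"), pick("^αA")),     # strand vs first helix
                       c(pick("7/8"), pick("^αC")),    # relocating sheet vs helix
                       c(pick("6/4/5"), pick("^αC")))  # core sheet vs helix
    utils::write.table(segment_distance_series(fw, segs, pair_names),
                       p("segment_distances.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    core <- segment_residues(segs, pick("^αA"))
    tailr <- segment_residues(segs, pick("7/8"))
    rp <- data.frame(res_a = rep(core, length.out = length(tailr)),
                     res_b = tailr)
    utils::write.table(hydrophobic_contacts(fw, rp,
                                            cutoff = config$contact_cutoff),
                       p("contacts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (config$run_occupancy) {
      fx <- make_hbond_fixture(98.8, 1000, seed = seed0)
      utils::write.table(hbond_occupancy(fx$trajectory, fx$pairs),
                         p("occupancy.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    net <- build_segment_network(dc, segs,
                                 threshold = config$network_threshold)
    write_network(net, p("network.tsv"), dot_path = p("network.dot"))
    structs <- c(list(open = toy$open, closed = toy$closed),
                 stats::setNames(
                   lapply(seq_along(config$extract_fracs), function(i) {
                     read_pdb(p(sprintf("intermediate_%d_avg.pdb", i)))
                   }),
                   sprintf("intermediate_%d",
                           seq_along(config$extract_fracs))))
    pk <- lapply(names(structs), function(nm) {
      res <- measure_pockets(structs[[nm]],
                             grid_spacing = config$pocket_spacing)
      if (nrow(res)) cbind(conformation = nm, as.data.frame(res))
      else NULL
    })
    pk <- do.call(rbind, pk)
    if (is.null(pk)) {
      pk <- data.frame(conformation = character(), pocket = integer(),
                       volume = numeric(), area = numeric())
    }
    utils::write.table(pk, p("pockets.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  manifest$stages$analyze <- list(
    files = c("rmsd_series.tsv", "dccm.tsv", "segment_distances.tsv",
              "contacts.tsv", "network.tsv", "network.dot", "pockets.tsv",
              if (config$run_occupancy) "occupancy.tsv"))

  manifest$n_runs <- list(k_scan = length(config$k_scan), tmd = 2L,
                          intermediates = length(config$extract_fracs))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
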