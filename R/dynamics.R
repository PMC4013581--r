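# Staged minimization and Langevin (BAOAB) dynamics for the coarse-grained
# dual-basin model: heating ramp, thermostatted equilibration/production, and
# the targeted-MD driver that adds the scheduled RMSD restraint.
#
# Unit conventions: coordinates A, time ps, energy kcal/mol, mass Da.
# Acceleration in A/ps^2 is force[kcal/(mol A)] / mass[Da] * 418.4; the
# Boltzmann constant is 0.0019872041 kcal/(mol K).

.KB <- 0.0019872041
.ACC <- 418.4

#' Simulation protocol
#'
#' Mirrors the staged protocol of an explicit-solvent MD setup at
#' coarse-grained desk scale: restrained minimization ladder, linear heating
#' with a weak-coupling time constant (mapped to Langevin friction
#' `1/coupling`), unrestrained equilibration, then production.
#'
#' @param min_stages list of `c(restraint_strength, max_steps)` minimization
#'   stages; the default ladder relaxes positional restraints
#'   100, 75, 50, 25 kcal/(mol A^2) and ends with an unrestrained stage.
#' @param heat_start,heat_end heating start/end temperatures (K).
#' @param heat_duration heating duration (ps).
#' @param coupling thermostat coupling time (ps); Langevin friction is
#'   `1/coupling`.
#' @param equil_duration unrestrained equilibration (ps).
#' @param prod_duration production (ps).
#' @param dt integration step (ps). The coarse-grained default is 0.01 ps;
#'   stability against the stiffest bond is checked at startup.
#' @param stride sampling stride in steps for frames and log rows.
#' @param temperature equilibration/production temperature (K).
#' @return an object of class `SimProtocol`.
#' @export
sim_protocol <- function(min_stages = list(c(100, 200), c(75, 200),
                                           c(50, 200), c(25, 200),
                                           c(0, 400)),
                         heat_start = 0, heat_end = 300, heat_duration = 10,
                         coupling = 0.2, equil_duration = 10,
                         prod_duration = 200, dt = 0.01, stride = 20,
                         temperature = 300) {
  if (dt <= 0) stop("time step must be positive")
  if (any(c(heat_duration, equil_duration, prod_duration) < 0)) {
    stop("durations must be non-negative")
  }
  if (any(c(heat_start, heat_end, temperature) < 0)) {
    stop("temperatures must be non-negative")
  }
  obj <- list(min_stages = min_stages, heat_start = heat_start,
              heat_end = heat_end, heat_duration = heat_duration,
              coupling = coupling, equil_duration = equil_duration,
              prod_duration = prod_duration, dt = dt,
              stride = as.integer(stride), temperature = temperature)
  class(obj) <- "SimProtocol"
  obj
}

#' Staged energy minimization
#'
#' Steepest descent with backtracking line search. Each stage adds a harmonic
#' positional restraint `k_pos * sum |x - x_ref|^2` of the stated strength
#' toward the reference structure; a stage with strength 0 is unrestrained.
#' The returned structure never has higher model energy than the input.
#'
#' @param model a `DualBasinModel`.
#' @param start starting `Structure`.
#' @param stages list of `c(restraint_strength, max_steps)`; default from
#'   [sim_protocol()].
#' @param reference `Structure` the positional restraints pull toward
#'   (default: `start`).
#' @param tol gradient max-norm convergence threshold, kcal/(mol A).
#' @return the minimized `Structure`; attribute `"energy_trace"` holds a
#'   data.frame of per-stage start/end model energies.
#' @export
minimize <- function(model, start, stages = sim_protocol()$min_stages,
                     reference = start, tol = 1e-4) {
  stopifnot(inherits(model, "DualBasinModel"), inherits(start, "Structure"))
  if (length(stages) == 0L) stop("need at least one minimization stage")
  X <- coords(start)
  Xref <- coords(reference)
  ev <- dual_basin_energy(model, X)
  if (!is.finite(ev$V)) stop("non-finite energy at start (overlapping beads?)")
  trace <- data.frame(stage = integer(), k_pos = numeric(),
                      V_start = numeric(), V_end = numeric())
  for (s in seq_along(stages)) {
    k_pos <- stages[[s]][1]
    max_steps <- stages[[s]][2]
    etot <- function(X) {
      e <- dual_basin_energy(model, X)
      list(V = e$V + k_pos * sum((X - Xref)^2),
           F = e$forces - 2 * k_pos * (X - Xref), V_model = e$V)
    }
    cur <- etot(X)
    v0 <- cur$V_model
    alpha <- 1e-3
    for (it in seq_len(max_steps)) {
      g <- cur$F
      gmax <- max(abs(g))
      if (gmax < tol) break
      repeat {
        Xn <- X + alpha * g
        nxt <- tryCatch(etot(Xn), error = function(e) NULL)
        if (!is.null(nxt) && nxt$V < cur$V) break
        alpha <- alpha / 2
        if (alpha < 1e-12) break
      }
      if (alpha < 1e-12) break
      X <- Xn
      cur <- nxt
      alpha <- min(alpha * 1.5, 1)
    }
    trace <- rbind(trace, data.frame(stage = s, k_pos = k_pos,
                                     V_start = v0, V_end = cur$V_model))
  }
  out <- set_coords(start, X)
  attr(out, "energy_trace") <- trace
  out
}

# Maxwell-Boltzmann velocities (A/ps) for masses m at temperature T
.mb_velocities <- function(masses, temperature) {
  n <- length(masses)
  if (temperature <= 0) return(matrix(0, n, 3))
  sd <- sqrt(.KB * temperature * .ACC / masses)
  matrix(stats::rnorm(3 * n), n, 3) * sd
}

# Core BAOAB loop shared by run_cmd and run_tmd. `restraint` may be NULL
# (conventional MD) or a TMDRestraint with rmsd_start resolved.
.integrate <- function(model, X, protocol, seed, restraint = NULL,
                       record_all = FALSE) {
  set.seed(as.integer(seed %% 2147483647))
  dt <- protocol$dt
  m <- model$masses
  gamma <- if (protocol$coupling > 0) 1 / protocol$coupling else 0

  # bond-oscillation stability check: dt must resolve the stiffest mode
  omega_max <- sqrt(2 * max(model$k_bond, model$k_contact, model$k_rep) *
                      .ACC / min(m))
  if (dt * omega_max > 1.5) {
    stop(sprintf("time step %g ps unstable: stiffest mode period %.4g ps",
                 dt, 2 * pi / omega_max))
  }

  n_heat <- round(protocol$heat_duration / dt)
  n_equil <- round(protocol$equil_duration / dt)
  n_prod <- round(protocol$prod_duration / dt)
  n_tot <- n_heat + n_equil + n_prod
  prod_t0 <- (n_heat + n_equil) * dt

  temp_at <- function(step) {
    if (step <= n_heat && n_heat > 0) {
      protocol$heat_start +
        (protocol$heat_end - protocol$heat_start) * step / n_heat
    } else {
      protocol$temperature
    }
  }

  # a restraint with unresolved rmsd_start is inactive until its schedule
  # starts; at that moment the start value anchors to the actual RMSD so the
  # restraint switches on unstrained
  tmd_eval <- function(X, t) {
    if (is.null(restraint)) return(NULL)
    if (is.na(restraint$rmsd_start)) {
      if (t < restraint$t_start) return(NULL)
      sel <- restraint$selection
      w <- if (restraint$mass_weighted) {
        restraint$target$atoms$mass[sel]
      } else {
        NULL
      }
      restraint$rmsd_start <<- rmsd(X[sel, , drop = FALSE],
                                    coords(restraint$target)[sel, ,
                                                             drop = FALSE],
                                    weights = w)
    }
    tmd_energy(X, restraint, t)
  }

  V <- .mb_velocities(m, temp_at(0))
  ev <- dual_basin_energy(model, X)
  if (!is.finite(ev$V)) stop("non-finite energy at start")
  tmd <- tmd_eval(X, 0)
  Ftot <- ev$forces + if (is.null(tmd)) 0 else tmd$forces

  frames <- list()
  times <- numeric()
  log <- vector("list", 0L)
  vscale <- .ACC / m

  push_log <- function(step, t, Vpot, etmd, r, r0) {
    ke <- 0.5 * sum(m * rowSums(V^2)) / .ACC
    Tk <- 2 * ke / (3 * model$n * .KB)
    log[[length(log) + 1L]] <<- data.frame(
      step = step, time_ps = t, T_K = Tk, V = Vpot,
      E_TMD = etmd, E_total = Vpot + etmd + ke, KE = ke,
      RMSD = r, RMSD0 = r0)
  }
  push_log(0L, 0, ev$V,
           if (is.null(tmd)) 0 else tmd$energy,
           if (is.null(tmd)) NA_real_ else tmd$rmsd,
           if (is.null(tmd)) NA_real_ else tmd$rmsd0)

  for (step in seq_len(n_tot)) {
    t <- step * dt
    # B: half kick
    V <- V + 0.5 * dt * Ftot * vscale
    # A: half drift
    X <- X + 0.5 * dt * V
    # O: thermostat
    if (gamma > 0) {
      Tset <- temp_at(step)
      c1 <- exp(-gamma * dt)
      c2 <- sqrt((1 - c1^2) * .KB * Tset * .ACC / m)
      V <- c1 * V + matrix(stats::rnorm(3 * model$n), model$n, 3) * c2
    }
    # A: half drift
    X <- X + 0.5 * dt * V
    # B: half kick with new forces
    ev <- dual_basin_energy(model, X)
    tmd <- tmd_eval(X, t)
    Ftot <- ev$forces + if (is.null(tmd)) 0 else tmd$forces
    V <- V + 0.5 * dt * Ftot * vscale

    if (!is.finite(ev$V) || abs(ev$V) > 1e9) {
      stop(sprintf("unstable integration at step %d (V = %g); reduce dt",
                   step, ev$V))
    }
    if (step %% protocol$stride == 0L || step == n_tot) {
      in_prod <- step > n_heat + n_equil
      push_log(step, t, ev$V,
               if (is.null(tmd)) 0 else tmd$energy,
               if (is.null(tmd)) NA_real_ else tmd$rmsd,
               if (is.null(tmd)) NA_real_ else tmd$rmsd0)
      if (in_prod || record_all) {
        frames[[length(frames) + 1L]] <- X
        times <- c(times, t)
      }
    }
  }
  if (length(frames) == 0L) {  # zero-length production: keep final state
    frames <- list(X)
    times <- n_tot * dt
  }
  list(frames = frames, times = times, log = do.call(rbind, log),
       prod_t0 = prod_t0, final = X)
}

#' Conventional (unbiased) Langevin dynamics
#'
#' BAOAB Langevin integration with a linear heating ramp, equilibration and
#' production phases per the protocol. With `coupling = 0` (or `Inf`
#' friction disabled) the thermostat is off and the integrator reduces to
#' velocity Verlet. Identical seed and protocol give a bit-identical
#' trajectory.
#'
#' @param model a `DualBasinModel`.
#' @param start starting `Structure` (minimized recommended).
#' @param protocol a [sim_protocol()].
#' @param seed integer random seed.
#' @param record_all record frames in all phases, not just production.
#' @return a `Trajectory` of production frames (element `log` holds the
#'   tab-separatable run log: step, time_ps, T_K, V, E_TMD, E_total, KE,
#'   RMSD, RMSD0).
#' @export
run_cmd <- function(model, start, protocol = sim_protocol(), seed = 1,
                    record_all = FALSE) {
  stopifnot(inherits(model, "DualBasinModel"), inherits(start, "Structure"))
  res <- .integrate(model, coords(start), protocol, seed,
                    record_all = record_all)
  traj <- trajectory_new(start$atoms, res$frames, res$times,
                         title = paste0("CMD: ", start$title))
  traj$log <- res$log
  traj
}

#' Targeted molecular dynamics
#'
#' Runs [run_cmd()] dynamics plus the scheduled RMSD restraint. Heating and
#' equilibration are unrestrained; at the start of production the target
#' RMSD anchors to the actual best-fit RMSD to the target at that moment
#' (so the restraint switches on unstrained), decays linearly to zero over
#' the first `schedule_frac` of the production window, and holds at zero
#' for the remainder (a settling period, as in a transition run followed by
#' equilibration at the target).
#'
#' @param model a `DualBasinModel`.
#' @param start,target index-matched `Structure`s.
#' @param k per-atom TMD force constant, kcal/(mol A^2).
#' @param protocol a [sim_protocol()].
#' @param seed integer random seed.
#' @param selection restrained atom indices (default: all beads, the
#'   coarse-grained meaning of "all backbone atoms").
#' @param schedule_frac fraction of the production window over which the
#'   target RMSD decays to zero.
#' @param mass_weighted mass-weighted RMSD in the restraint (default).
#' @return a `Trajectory`; element `log` holds the per-frame tracking table
#'   (time, RMSD to target, scheduled RMSD0, E_TMD, energies).
#' @export
run_tmd <- function(model, start, target, k = 0.5,
                    protocol = sim_protocol(), seed = 1, selection = NULL,
                    schedule_frac = 0.8, mass_weighted = TRUE) {
  stopifnot(inherits(model, "DualBasinModel"), inherits(start, "Structure"),
            inherits(target, "Structure"))
  if (nrow(start$atoms) != nrow(target$atoms)) {
    stop("start and target structures are not index-matched")
  }
  if (is.null(selection)) selection <- seq_len(nrow(start$atoms))
  t0 <- protocol$heat_duration + protocol$equil_duration
  restraint <- tmd_restraint(target, k = k, selection = selection,
                             rmsd_start = NA_real_, rmsd_end = 0,
                             t_start = t0,
                             t_end = t0 + schedule_frac * protocol$prod_duration,
                             mass_weighted = mass_weighted)
  res <- .integrate(model, coords(start), protocol, seed,
                    restraint = restraint)
  traj <- trajectory_new(start$atoms, res$frames, res$times,
                         title = paste0("TMD: ", start$title, " -> ",
                                        target$title))
  traj$log <- res$log
  traj$restraint <- restraint
  traj
}

#' Write a run log as a tab-separated table
#'
#' @param traj a `Trajectory` from [run_cmd()]/[run_tmd()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_log <- function(traj, path) {
  if (is.null(traj$log)) stop("trajectory carries no run log")
  utils::write.table(traj$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
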