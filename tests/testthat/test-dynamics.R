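test_that("identical seed and protocol give bit-identical trajectories", {
  fx <- toy_fixture()
  pr <- short_protocol()
  t1 <- run_cmd(fx$model, fx$toy$open, pr, seed = 21)
  t2 <- run_cmd(fx$model, fx$toy$open, pr, seed = 21)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$log, t2$log)
  t3 <- run_cmd(fx$model, fx$toy$open, pr, seed = 22)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("with the thermostat off the integrator conserves energy", {
  fx <- toy_fixture()
  set.seed(23)
  start <- set_coords(fx$toy$open,
                      coords(fx$toy$open) + matrix(rnorm(180, 0, 0.2), 60, 3))
  pr <- sim_protocol(heat_duration = 0, equil_duration = 0,
                     prod_duration = 3, dt = 0.001, coupling = 0,
                     stride = 50, temperature = 0)
  tr <- run_cmd(fx$model, start, pr, seed = 23)
  E <- tr$log$E_total
  expect_lte(max(abs(E - E[1])) / abs(E[1]), 1e-3)
})

test_that("a cold start at a basin minimum stays there", {
  fx <- toy_fixture()
  pr <- sim_protocol(heat_start = 0, heat_end = 0, heat_duration = 0,
                     equil_duration = 0, prod_duration = 4,
                     temperature = 0, stride = 20)
  tr <- run_cmd(fx$model, fx$toy$open, pr, seed = 24)
  drift <- rmsd(tr$frames[[n_frames(tr)]], coords(fx$toy$open),
                weights = fx$toy$open$atoms$mass)
  expect_lte(drift, 1e-3)
})

test_that("the thermostat holds the kinetic temperature at the set-point", {
  fx <- toy_fixture()
  pr <- sim_protocol(heat_duration = 4, equil_duration = 4,
                     prod_duration = 30, stride = 10)
  tr <- run_cmd(fx$model, fx$toy$open, pr, seed = 25)
  prod <- tr$log[tr$log$time_ps > 8, ]
  expect_lt(abs(mean(prod$T_K) - 300) / 300, 0.05)
})

test_that("minimization is monotone, fixes basin minima, and obeys stiff restraints", {
  fx <- toy_fixture()
  # fixed point: starting at a minimum stays there
  mini0 <- minimize(fx$model, fx$toy$open, stages = list(c(0, 100)))
  expect_lte(max(abs(coords(mini0) - coords(fx$toy$open))), 1e-4)

  set.seed(26)
  pert <- set_coords(fx$toy$open,
                     coords(fx$toy$open) + matrix(rnorm(180, 0, 0.3), 60, 3))
  mini <- minimize(fx$model, pert,
                   stages = list(c(100, 100), c(75, 100), c(50, 100),
                                 c(25, 100), c(0, 200)))
  tr <- attr(mini, "energy_trace")
  expect_equal(nrow(tr), 5L)
  expect_true(all(diff(tr$V_end) <= 1e-9))  # per-stage model energy falls
  expect_lt(dual_basin_energy(fx$model, coords(mini))$V,
            dual_basin_energy(fx$model, coords(pert))$V)

  # stiff positional restraint pins the output to the reference
  stiff <- minimize(fx$model, pert, stages = list(c(1e6, 300)),
                    reference = fx$toy$open)
  expect_lte(max(abs(coords(stiff) - coords(fx$toy$open))), 0.01)
})

test_that("unstable time steps are rejected up front", {
  fx <- toy_fixture()
  pr <- short_protocol(dt = 0.1)
  expect_error(run_cmd(fx$model, fx$toy$open, pr, seed = 1), "unstable")
})

test_that("TMD runs log the schedule and drive toward the target under stiff bias", {
  fx <- toy_fixture()
  pr <- short_protocol(prod = 15)
  tr <- run_tmd(fx$model, fx$toy$open, fx$toy$closed, k = 10,
                protocol = pr, seed = 27)
  expect_true(all(c("RMSD", "RMSD0", "E_TMD") %in% names(tr$log)))
  sched <- tr$log[!is.na(tr$log$RMSD0), ]
  expect_gt(nrow(sched), 5)
  # the scheduled target RMSD decays monotonically to zero
  expect_true(all(diff(sched$RMSD0) <= 1e-9))
  expect_equal(sched$RMSD0[nrow(sched)], 0)
  final <- rmsd(tr$frames[[n_frames(tr)]], coords(fx$toy$closed),
                weights = fx$toy$closed$atoms$mass)
  expect_lte(final, 0.5)
})

test_that("energy accounting separates potential, bias, and kinetic terms", {
  fx <- toy_fixture()
  pr <- short_protocol(prod = 4)
  tr <- run_tmd(fx$model, fx$toy$open, fx$toy$closed, k = 0.5,
                protocol = pr, seed = 28)
  lg <- tr$log
  expect_equal(lg$E_total, lg$V + lg$E_TMD + lg$KE, tolerance = 1e-9)
})

test_that("the restraint keeps the driven transition near its schedule", {
  fx <- toy_fixture()
  pr <- sim_protocol()
  lag_at <- function(k, seed) {
    tr <- run_tmd(fx$model, fx$toy$open, fx$toy$closed, k = k,
                  protocol = pr, seed = seed)
    dec <- tr$log[!is.na(tr$log$RMSD0) & tr$log$RMSD0 > 0, ]
    max(abs(dec$RMSD - dec$RMSD0))
  }
  # stiff restraints track within the schedule's design width; at the
  # production force constant the transient excursion at the basin crossing
  # stays bounded
  expect_lte(lag_at(1.0, 51), 1.0)
  expect_lte(lag_at(0.5, 52), 1.5)
})
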