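test_that("the Metropolis rule accepts downhill always and uphill never at
           vanishing temperature", {
  set.seed(1)
  for (i in 1:50) expect_true(metropolis_accept(-abs(stats::rnorm(1)), 1))
  for (i in 1:50) expect_false(metropolis_accept(abs(stats::rnorm(1)) + 0.1,
                                                 1e-12))
  expect_false(metropolis_accept(NaN, 1))
  expect_false(metropolis_accept(Inf, 1))
})

test_that("a two-state Metropolis chain reproduces the Boltzmann
           occupancy ratio", {
  dE <- 1.1; kT <- 0.8
  set.seed(99)
  state <- 0L  # energies 0 and dE
  occ <- integer(2)
  n <- 1e5
  for (i in seq_len(n)) {
    prop <- 1L - state
    d <- if (prop == 1L) dE else -dE
    if (metropolis_accept(d, kT)) state <- prop
    occ[state + 1L] <- occ[state + 1L] + 1L
  }
  ratio <- occ[2] / occ[1]
  expected <- exp(-dE / kT)
  # binomial standard error on the occupancy fraction
  p <- expected / (1 + expected)
  se_p <- sqrt(p * (1 - p) / n)
  se_ratio <- se_p / (1 - p)^2
  expect_lt(abs(ratio - expected), 3 * se_ratio)
})

test_that("migration is deterministic in the seed and keeps honest books", {
  pk <- mc_pocket()
  modes <- pocket_modes(pk)
  ann <- pk$annotations
  cfg <- mc_config(seed = 42, max_steps = 600,
                   gate_limit = ann$chi_open, snapshot_every = 3)
  t1 <- run_migration(pk$structure, pk$ligand, ann$start_pose, modes, cfg,
                      pk$params)
  t2 <- run_migration(pk$structure, pk$ligand, ann$start_pose, modes, cfg,
                      pk$params)
  expect_identical(t1$states, t2$states)
  expect_gte(t1$acceptance_rate, 0)
  expect_lte(t1$acceptance_rate, 1)
  expect_equal(t1$states$sep_com[1] <= cfg$t_max, TRUE)
  # every stored snapshot's energy re-evaluates from its scene
  for (sn in t1$snapshots[seq(1, length(t1$snapshots), length.out = 5)]) {
    e <- reevaluate_snapshot(pk$structure, pk$ligand, modes, cfg,
                             pk$params, sn)
    expect_equal(e, sn$energy, tolerance = 1e-9)
  }
})

test_that("accepted states only ever lower the energy or pass a thermal
           coin flip; rejected steps keep the state", {
  pk <- mc_pocket()
  ann <- pk$annotations
  cfg <- mc_config(seed = 5, max_steps = 300, gate_limit = ann$chi_open)
  tr <- run_migration(pk$structure, pk$ligand, ann$start_pose,
                      pocket_modes(pk), cfg, pk$params)
  st <- tr$states
  rejected <- which(st$accepted == 0)
  rejected <- rejected[rejected > 1]
  # a rejected step leaves energy and separation unchanged
  expect_true(all(abs(st$energy[rejected] - st$energy[rejected - 1]) < 1e-12))
  expect_true(all(abs(st$sep_com[rejected] - st$sep_com[rejected - 1]) < 1e-12))
})

test_that("energy-separation profile conserves counts and flags an
           engineered dwell", {
  pk <- mc_pocket()
  ann <- pk$annotations
  cfg <- mc_config(seed = 11, max_steps = 1500, gate_limit = ann$chi_open)
  tr <- run_migration(pk$structure, pk$ligand, ann$start_pose,
                      pocket_modes(pk), cfg, pk$params)
  prof <- energy_distance_profile(tr)
  expect_equal(sum(prof$count), sum(tr$states$accepted))
  expect_error(energy_distance_profile(list()), "no trajectories")
  # a synthetic trajectory with a deep, heavily visited station at 8 A
  fake <- structure(list(states = data.frame(
    step = 1:200,
    energy = c(rep(-1, 50), rep(-6, 100), rep(-1, 50)),
    sep_com = c(seq(0, 7.4, length.out = 50), rep(8.2, 100),
                seq(9, 14, length.out = 50)),
    sep_c4 = 0, accepted = 1)), class = "Trajectory")
  pf <- energy_distance_profile(fake)
  expect_true(any(pf$dwell & pf$sep_lo == 8))
})

test_that("one-state trajectories produce a single-bin profile", {
  fake <- structure(list(states = data.frame(step = 1, energy = -2,
                                             sep_com = 1.3, sep_c4 = 0,
                                             accepted = 1)),
                    class = "Trajectory")
  pf <- energy_distance_profile(fake)
  expect_equal(nrow(pf), 1)
  expect_equal(pf$count, 1L)
})
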