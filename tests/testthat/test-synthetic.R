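test_that("generators are pure functions of their seed", {
  p1 <- make_toy_pocket(toy_pocket_spec(seed = 7), certify = "none")
  p2 <- make_toy_pocket(toy_pocket_spec(seed = 7), certify = "none")
  expect_identical(coords(p1$structure), coords(p2$structure))
  expect_identical(p1$structure$atoms$polar_strength,
                   p2$structure$atoms$polar_strength)
  p3 <- make_toy_pocket(toy_pocket_spec(seed = 8), certify = "none")
  expect_false(identical(coords(p1$structure), coords(p3$structure)))
  d1 <- make_kinetic_dataset(seed = 5)
  expect_identical(d1, make_kinetic_dataset(seed = 5))
  s1 <- make_spr_dataset(KD = 1e-4, seed = 5)
  expect_identical(s1, make_spr_dataset(KD = 1e-4, seed = 5))
  # generators do not disturb the session RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(make_kinetic_dataset(seed = 9))
  expect_identical(stats::runif(1), before)
})

test_that("pocket certificates hold for the default spec and random seeds", {
  pk <- default_pocket()   # built with certify = "fast": construction
  expect_s3_class(pk, "ToyPocket")
  expect_true(certify_pocket(pk, level = "fast"))
  for (sd in c(101, 202, 303, 404)) {
    expect_no_error(make_toy_pocket(toy_pocket_spec(seed = sd),
                                    certify = "fast"))
  }
})

test_that("gate removal opens the straight exit corridor and reference
           gates seal the barrier slab", {
  pk <- default_pocket()
  no_gate <- pocket_without_gates(pk)
  cc <- vapply(seq(0, pk$spec$pocket_depth + 2.5, by = 0.5), function(z) {
    clash_count(no_gate, pk$ligand,
                new_pose(pk$annotations$corridor_rotation, c(0, 0, z)),
                pk$params)
  }, numeric(1))
  expect_true(all(cc == 0))
  # reference gates: an exhaustive pose grid in the barrier slab always
  # clashes
  g <- seq(-3, 3, by = 0.6)
  mc <- exoegress:::min_clash_over_grid(
    pk, pk$annotations$barrier_z + c(-0.5, 0, 0.5),
    list(x = g, y = g), exoegress:::scan_orientations(45))
  expect_gte(mc, 1)
})

test_that("the ligand sits clash-free at the -1 site with the stated well
           depth", {
  pk <- default_pocket()
  expect_equal(clash_count(pk$structure, pk$ligand,
                           pk$annotations$start_pose, pk$params), 0)
  # polar calibration: isolating the polar term at the start pose gives
  # minus the requested -1 well depth
  p0 <- pk$params; p0$epsilon <- 1e-12
  e_pol <- interaction_energy(pk$structure, pk$ligand,
                              pk$annotations$start_pose, p0)
  expect_equal(e_pol, -pk$spec$minus1_well_depth, tolerance = 1e-6)
  # and the cavity station carries the cavity well depth
  cav_pose <- new_pose(pk$annotations$corridor_rotation,
                       pk$annotations$cavity_center)
  e_cav <- interaction_energy(pk$structure, pk$ligand, cav_pose, p0)
  expect_equal(e_cav, -pk$spec$cavity_well_depth, tolerance = 1e-6)
})

test_that("kinetic datasets follow the assay design", {
  d <- make_kinetic_dataset(Vmax = 2, KM = 1.5, Ki = 2.55, noise_cv = 0)
  expect_equal(sort(unique(d$S)), seq(0.8, 6.6, length.out = 6))
  expect_equal(sort(unique(d$I)), seq(0.4, 3, length.out = 6) * 2.55)
  expect_equal(nrow(d), 6 * 6 * 2)
  # noise-free half saturation
  d2 <- make_kinetic_dataset(Vmax = 1, KM = 2, Ki = 3, S_grid = 2,
                             I_grid = c(0, 1, 2), noise_cv = 0)
  expect_equal(d2$v[d2$I == 0], c(0.5, 0.5))
  expect_error(make_kinetic_dataset(S_grid = c(-1, 2)), "positive")
})

test_that("toy pocket PDB export is parseable and two-chain", {
  pk <- default_pocket()
  f <- tempfile(fileext = ".pdb")
  write_toy_pocket(pk, f)
  s <- read_pdb(f)
  expect_setequal(unique(s$atoms$chain), c("R", "L"))
  expect_equal(sum(s$atoms$chain == "L"), nrow(pk$ligand$beads))
})

test_that("invalid pocket specifications are rejected", {
  expect_error(toy_pocket_spec(pocket_depth = -1))
  expect_error(toy_pocket_spec(channel_length = 20, pocket_depth = 13))
  # channel_radius must stay below the ligand circumscribed radius
  expect_error(make_toy_pocket(toy_pocket_spec(channel_radius = 3),
                               certify = "none"), "circumscribed")
})
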