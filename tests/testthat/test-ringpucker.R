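hexagon <- function(z = rep(0, 6), radius = 1.45) {
  ang <- 2 * pi * (0:5) / 6
  cbind(radius * cos(ang), radius * sin(ang), z)
}

test_that("planar ring has vanishing amplitude", {
  cp <- cremer_pople(hexagon())
  expect_lt(cp$Q, 1e-10)
  expect_equal(classify_conformer(cp), "planar")
})

test_that("ideal chair follows the closed form: theta at a pole and
           Q = sqrt(6) z0", {
  z0 <- 0.25
  cp <- cremer_pople(hexagon(z0 * (-1)^(0:5)))
  expect_equal(cp$Q, sqrt(6) * z0, tolerance = 1e-12)
  expect_true(abs(cp$theta - 0) < 1e-9 || abs(cp$theta - 180) < 1e-9)
  expect_equal(cp$theta, 0, tolerance = 1e-9)  # this pattern is the 4C1 pole
  cp2 <- cremer_pople(hexagon(-z0 * (-1)^(0:5)))
  expect_equal(cp2$theta, 180, tolerance = 1e-9)
})

test_that("pure q2 displacement patterns sit on the equator", {
  # boat-type pattern with no q3 component
  z <- 0.3 * cos(4 * pi * (0:5) / 6)
  cp <- cremer_pople(hexagon(z))
  expect_equal(cp$theta, 90, tolerance = 1e-6)
})

test_that("puckering coordinates satisfy the Cartesian identity and are
           invariant under rigid motion", {
  set.seed(3)
  for (lab in c("4C1", "1S3", "B3O", "OH1", "E3")) {
    ring <- ring_coords(make_ring_ligand(lab))
    cp <- cremer_pople(ring)
    expect_equal(cp$qx^2 + cp$qy^2 + cp$qz^2, cp$Q^2, tolerance = 1e-10)
    R <- random_rotation(); t <- stats::rnorm(3, sd = 5)
    cp2 <- cremer_pople(sweep(ring %*% t(R), 2, t, `+`))
    expect_equal(cp2$Q, cp$Q, tolerance = 1e-10)
    expect_equal(cp2$theta, cp$theta, tolerance = 1e-7)
    expect_equal(cp2$phi, cp$phi, tolerance = 1e-6)
  }
})

test_that("cyclic relabeling by two positions shifts phi by 240 degrees and
           keeps theta", {
  ring <- ring_coords(make_ring_ligand("1S3"))
  cp <- cremer_pople(ring)
  cp2 <- cremer_pople(ring[c(3:6, 1:2), ])
  expect_equal(cp2$Q, cp$Q, tolerance = 1e-10)
  expect_equal(cp2$theta, cp$theta, tolerance = 1e-7)
  expect_equal((cp2$phi - cp$phi) %% 360, 240, tolerance = 1e-5)
})

test_that("classification recovers every canonical conformer and handles
           near-pole cases", {
  labs <- c("4C1", "1C4", "1S3", "3S1", "1S5", "5S1", "OS2", "2SO",
            "B3O", "3OB", "B14", "14B", "B25", "25B",
            "OE", "EO", "1E", "E1", "3E", "E3",
            "OH1", "1HO", "3H4", "4H3", "5HO", "OH5")
  for (lab in labs) {
    lg <- make_ring_ligand(lab)
    cp <- cremer_pople(ring_coords(lg))
    expect_equal(classify_conformer(cp), lab)
    expect_equal(cp$Q, 0.55, tolerance = 0.02)
  }
  near_pole <- list(Q = 0.5, theta = 2, phi = 123)
  expect_equal(classify_conformer(near_pole), "4C1")
  expect_equal(classify_conformer(list(Q = 0, theta = 0, phi = 0)),
               "planar")
})

test_that("ring-bond geometry of generated ligands stays in range", {
  for (lab in c("4C1", "1S3", "planar")) {
    ring <- ring_coords(make_ring_ligand(lab))
    d <- sqrt(rowSums((ring - ring[c(2:6, 1), ])^2))
    expect_true(all(d >= 1.3 & d <= 1.7))
  }
  expect_error(make_ring_ligand("7Z9"), "unknown")
})

test_that("fel_extrema finds minima and the hand-computable saddle", {
  # 5x5 grid with two minima (value 0 and 1) and a known lowest crossing
  vals <- matrix(5, 5, 5)
  vals[2, 3] <- 0; vals[4, 3] <- 1   # two basins
  vals[3, 3] <- 2.5                  # the pass between them
  fel <- list(x = 1:5, y = 1:5, values = vals)
  ex <- fel_extrema(fel, basin_a = c(2, 3), basin_b = c(4, 3))
  expect_equal(ex$saddle_energy, 2.5)
  expect_equal(ex$barrier, 2.5)
  expect_equal(ex$barrier_from_b, 1.5)
  expect_true(nrow(ex$minima) >= 2)
  # single well: exactly one minimum below a tight depth threshold
  single <- list(x = seq(-2, 2, length.out = 41),
                 y = seq(-2, 2, length.out = 41))
  single$values <- outer(single$x, single$y,
                         function(a, b) a^2 + 2 * b^2)
  ex1 <- fel_extrema(single, depth_max = 0.5)
  expect_equal(nrow(ex1$minima), 1)
  expect_equal(ex1$minima$value[1], 0)
})
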