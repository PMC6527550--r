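test_that("Lennard-Jones pair energy matches the closed form", {
  p <- energy_params(epsilon = 0.5, sigma = 3.0, cutoff = 12)
  lig <- bead_ligand()
  at_r <- function(r) atoms_structure(c(r, 0, 0))
  expect_equal(interaction_energy(at_r(3.0), lig, params = p), 0,
               tolerance = 1e-12)
  expect_equal(interaction_energy(at_r(2^(1 / 6) * 3.0), lig, params = p),
               -0.5, tolerance = 1e-12)
  expect_equal(interaction_energy(at_r(13), lig, params = p), 0)
  expect_error(interaction_energy(at_r(0), lig, params = p), "singular")
})

test_that("interaction energy matches a term-by-term brute-force sum", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 30
    rec <- atoms_structure(matrix(stats::rnorm(3 * n, sd = 5), ncol = 3),
                           polar = stats::runif(n) < 0.3)
    lb <- data.frame(element = "C", name = "B",
                     x = stats::rnorm(5), y = stats::rnorm(5),
                     z = stats::rnorm(5),
                     polar = stats::runif(5) < 0.5,
                     stringsAsFactors = FALSE)
    lig <- new_ring_ligand(lb, ring_idx = integer(0))
    p <- energy_params(epsilon = 0.2, polar_strength = 1.1)
    # independent brute force, written directly from the definition
    e_ref <- 0
    for (i in 1:5) for (j in 1:n) {
      r <- sqrt(sum((as.numeric(lb[i, c("x", "y", "z")]) -
                       coords(rec)[j, ])^2))
      if (r >= p$cutoff) next
      sig <- (lig$beads$radius[i] + rec$atoms$radius[j]) * 2^(-1 / 6)
      e_ref <- e_ref + 4 * p$epsilon * ((sig / r)^12 - (sig / r)^6)
      if (lb$polar[i] && rec$atoms$polar[j]) {
        g <- if (r < p$r_hb) 1 else if (r >= p$r_hb_off) 0 else
          0.5 * (1 + cos(pi * (r - p$r_hb) / (p$r_hb_off - p$r_hb)))
        e_ref <- e_ref - p$polar_strength * g
      }
    }
    expect_equal(interaction_energy(rec, lig, params = p), e_ref,
                 tolerance = 1e-10)
  }
})

test_that("clash counting follows the overlap-factor rule", {
  p <- energy_params(overlap_factor = 0.7)
  lig <- bead_ligand(radius = 1.7)
  expect_equal(clash_count(atoms_structure(c(50, 0, 0)), lig, params = p), 0)
  # receptor atom at half the radius sum: inside the 0.7 threshold
  expect_equal(clash_count(atoms_structure(c(0.5 * 3.4, 0, 0)), lig,
                           params = p), 1)
  expect_equal(clash_count(atoms_structure(c(0.71 * 3.4, 0, 0)), lig,
                           params = p), 0)
})

test_that("cell-list neighbour search agrees with brute force", {
  set.seed(12)
  for (rep in 1:40) {
    A <- matrix(stats::rnorm(3 * sample(5:40, 1), sd = 8), ncol = 3)
    B <- matrix(stats::rnorm(3 * sample(5:60, 1), sd = 8), ncol = 3)
    cutoff <- stats::runif(1, 1, 10)
    br <- neighbor_pairs(A, B, cutoff, "brute")
    cl <- neighbor_pairs(A, B, cutoff, "cell")
    ob <- order(br$i, br$j); oc <- order(cl$i, cl$j)
    expect_equal(br$i[ob], cl$i[oc])
    expect_equal(br$j[ob], cl$j[oc])
    expect_equal(br$d[ob], cl$d[oc], tolerance = 1e-12)
  }
})

test_that("energy and clash count are invariant under global rigid motion", {
  set.seed(5)
  rec_xyz <- matrix(stats::rnorm(60, sd = 4), ncol = 3)
  rec <- atoms_structure(rec_xyz, polar = rep(c(TRUE, FALSE), 10))
  lig <- make_ring_ligand("4C1")
  p <- energy_params(epsilon = 0.1)
  e0 <- interaction_energy(rec, lig, params = p)
  c0 <- clash_count(rec, lig, params = p)
  for (rep in 1:5) {
    R <- random_rotation(); t <- stats::rnorm(3, sd = 10)
    rec2 <- atoms_structure(sweep(rec_xyz %*% t(R), 2, t, `+`),
                            polar = rep(c(TRUE, FALSE), 10))
    lb2 <- lig
    lxyz <- as.matrix(lig$beads[, c("x", "y", "z")]) %*% t(R)
    lb2$beads$x <- lxyz[, 1] + t[1]
    lb2$beads$y <- lxyz[, 2] + t[2]
    lb2$beads$z <- lxyz[, 3] + t[3]
    expect_equal(interaction_energy(rec2, lb2, params = p), e0,
                 tolerance = 1e-9)
    expect_equal(clash_count(rec2, lb2, params = p), c0)
  }
})

test_that("energy is additive over non-interacting sub-scenes", {
  p <- energy_params(epsilon = 0.3, cutoff = 12)
  lig <- bead_ligand()
  near <- atoms_structure(rbind(c(4, 0, 0), c(0, 5, 0)))
  far <- atoms_structure(rbind(c(200, 0, 0), c(0, 205, 0)))
  both_xyz <- rbind(coords(near), coords(far))
  both <- atoms_structure(both_xyz)
  expect_equal(interaction_energy(both, lig, params = p),
               interaction_energy(near, lig, params = p) +
                 interaction_energy(far, lig, params = p),
               tolerance = 1e-12)
})

test_that("pose minimisation descends to the pair minimum", {
  p <- energy_params(epsilon = 0.5, sigma = 3.0)
  lig <- bead_ligand()
  rec <- atoms_structure(c(0, 0, 0))
  r_min <- 2^(1 / 6) * 3.0
  # start at the minimum: nothing moves
  m0 <- minimize_pose(rec, lig, new_pose(translation = c(r_min, 0, 0)),
                      params = p, grad_tol = 1e-4)
  expect_lt(separation(m0$pose$translation, c(r_min, 0, 0)), 1e-3)
  # start at 1.5 sigma: converge to the minimum distance
  m1 <- minimize_pose(rec, lig, new_pose(translation = c(4.5, 0, 0)),
                      params = p, max_steps = 500, grad_tol = 1e-5)
  expect_equal(separation(m1$pose$translation, c(0, 0, 0)), r_min,
               tolerance = 1e-3)
  expect_lte(m1$energy,
             interaction_energy(rec, lig,
                                new_pose(translation = c(4.5, 0, 0)), p))
  expect_equal(m1$energy, -0.5, tolerance = 1e-6)
})
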