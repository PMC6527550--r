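test_that("two-node network has the closed-form spectrum", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0))
  H <- build_anm_hessian(nodes, anm_config(cutoff = 15, gamma = 1))
  expect_equal(H[1:3, 4:6], -diag(c(1, 0, 0)))
  ms <- compute_modes(H, n_modes = 1)
  expect_equal(ms$n_rigid, 5)
  expect_equal(ms$eigenvalues, 2, tolerance = 1e-12)
  # with gamma = 2.5 the non-zero eigenvalue scales to 2 * gamma
  H2 <- build_anm_hessian(nodes, anm_config(cutoff = 15, gamma = 2.5))
  expect_equal(compute_modes(H2, 1)$eigenvalues, 5, tolerance = 1e-12)
})

test_that("hessian is symmetric with zero row-block sums and matches a
           naive double-loop construction", {
  set.seed(21)
  nodes <- matrix(stats::rnorm(90, sd = 4), ncol = 3)
  cfg <- anm_config(cutoff = 6, gamma = 1.3)
  H <- build_anm_hessian(nodes, cfg)
  expect_equal(H, t(H))
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    blocksum <- matrix(0, 3, 3)
    for (j in seq_len(n))
      blocksum <- blocksum + H[rows, (3 * j - 2):(3 * j)]
    expect_equal(blocksum, matrix(0, 3, 3), tolerance = 1e-12)
  }
  # independent naive construction
  H_ref <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- nodes[j, ] - nodes[i, ]
    d <- sqrt(sum(r^2))
    if (d >= cfg$cutoff) next
    blk <- -cfg$gamma * (r %o% r) / d^2
    H_ref[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- blk
    H_ref[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <-
      H_ref[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] - blk
  }
  expect_equal(H, H_ref, tolerance = 1e-12)
  expect_error(build_anm_hessian(rbind(c(0, 0, 0), c(0, 0, 0)), cfg),
               "coincident")
})

test_that("connected clouds have exactly six rigid modes spanning rigid
           motions, and eigenpairs match a dense-solver oracle", {
  set.seed(33)
  nodes <- matrix(stats::rnorm(60, sd = 3), ncol = 3)
  cfg <- anm_config(cutoff = 15, n_modes = 8)
  H <- build_anm_hessian(nodes, cfg)
  ms <- compute_modes(H, 8)
  expect_equal(ms$n_rigid, 6)
  # pure translation lies in the rigid null space
  tx <- rep(c(1, 0, 0), nrow(nodes)) / sqrt(nrow(nodes))
  resid <- tx - ms$rigid_vectors %*% (t(ms$rigid_vectors) %*% tx)
  expect_lt(sqrt(sum(resid^2)), 1e-8)
  # dense oracle: base eigen on the independently built Hessian
  eg <- eigen(H, symmetric = TRUE)
  lam <- sort(eg$values)
  expect_equal(ms$eigenvalues, lam[7:14], tolerance = 1e-8)
  # orthonormality of reported modes
  G <- t(ms$vectors) %*% ms$vectors
  expect_equal(G, diag(8), tolerance = 1e-8)
  # residual of the eigen equation
  for (k in 1:8) {
    r <- H %*% ms$vectors[, k] - ms$eigenvalues[k] * ms$vectors[, k]
    expect_lt(max(abs(r)), 1e-8 * max(1, ms$eigenvalues[k]))
  }
})

test_that("eigenvalues are invariant under global rotation of the input", {
  set.seed(9)
  nodes <- matrix(stats::rnorm(45, sd = 3), ncol = 3)
  cfg <- anm_config(cutoff = 8, n_modes = 5)
  ms1 <- compute_modes(build_anm_hessian(nodes, cfg), 5)
  R <- random_rotation()
  ms2 <- compute_modes(build_anm_hessian(nodes %*% t(R), cfg), 5)
  expect_equal(ms1$eigenvalues, ms2$eigenvalues, tolerance = 1e-8)
})

test_that("mode displacement honours the amplitude convention and is
           linear", {
  set.seed(14)
  xyz <- matrix(stats::rnorm(60, sd = 3), ncol = 3)
  s <- atoms_structure(xyz)
  ms <- anm_modes(s, anm_config(cutoff = 15, n_modes = 4))
  expect_identical(coords(displace_structure(s, ms, 1, 0)), coords(s))
  d22 <- displace_structure(s, ms, 1, 2.2)
  disp <- sqrt(rowSums((coords(d22) - coords(s))^2))
  expect_equal(max(disp), 2.2, tolerance = 1e-9)
  d44 <- displace_structure(s, ms, 1, 4.4)
  expect_equal(coords(d44) - coords(s), 2 * (coords(d22) - coords(s)),
               tolerance = 1e-9)
})

test_that("singleton clusters reproduce the plain residue ANM", {
  set.seed(50)
  xyz <- matrix(stats::rnorm(36, sd = 4), ncol = 3)
  s <- atoms_structure(xyz)
  m1 <- anm_modes(s, anm_config(cutoff = 15, n_modes = 4, cluster_size = 1))
  m2 <- anm_modes(s, anm_config(cutoff = 15, n_modes = 4, cluster_size = 1))
  expect_equal(m1$eigenvalues, m2$eigenvalues)
  # grouping into clusters of 3 coarsens the node set accordingly
  nd <- anm_nodes(s, cluster_size = 3)
  expect_equal(nrow(nd$xyz), 4)
  expect_equal(nd$xyz[1, ], colMeans(xyz[1:3, ]))
})
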