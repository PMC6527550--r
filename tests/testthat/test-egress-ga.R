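# NSGA-II exit-path search. The heavier rigid-vs-displaced contrast lives
# in the acceptance suite; here the search machinery itself is exercised on
# cheap configurations.

fast_ga <- function(seed = 1, ...) {
  ga_config(population = 24, generations = 30, seed = seed, ...)
}

test_that("the returned front is internally non-dominated and
           deterministic in the seed", {
  pk <- default_pocket()
  ann <- pk$annotations
  fr1 <- evolve_exit_paths(pk$structure, pk$ligand, ann$start_pose,
                           "rigid", fast_ga(3), pk$params)
  clash <- vapply(fr1, `[[`, numeric(1), "total_clash")
  reach <- vapply(fr1, `[[`, numeric(1), "reach")
  # brute-force dominance check
  for (i in seq_along(fr1)) {
    dominated <- any(clash <= clash[i] & reach >= reach[i] &
                       (clash < clash[i] | reach > reach[i]))
    expect_false(dominated)
  }
  fr2 <- evolve_exit_paths(pk$structure, pk$ligand, ann$start_pose,
                           "rigid", fast_ga(3), pk$params)
  expect_equal(vapply(fr2, `[[`, numeric(1), "reach"), reach)
  expect_equal(vapply(fr2, `[[`, numeric(1), "total_clash"), clash)
})

test_that("path candidates respect the waypoint contract", {
  pk <- default_pocket()
  fr <- evolve_exit_paths(pk$structure, pk$ligand,
                          pk$annotations$start_pose, "rigid",
                          fast_ga(5), pk$params)
  for (cand in fr) {
    expect_equal(cand$separations[1], 0)
    expect_equal(length(cand$separations), 9)
    steps <- cand$genome$steps
    expect_true(all(sqrt(rowSums(steps^2)) <= 2.0 + 1e-9))
    expect_equal(cand$total_clash, sum(cand$clash_counts))
    expect_equal(cand$reach, max(cand$separations))
  }
})

test_that("with all receptor atoms deleted the search trivially attains
           clash-free maximal reach", {
  pk <- default_pocket()
  empty <- atoms_structure(c(500, 500, 500))  # single far-away atom
  fr <- evolve_exit_paths(empty, pk$ligand, pk$annotations$start_pose,
                          "rigid", fast_ga(2, target_reach = 14),
                          pk$params)
  clash <- vapply(fr, `[[`, numeric(1), "total_clash")
  reach <- vapply(fr, `[[`, numeric(1), "reach")
  expect_true(any(clash == 0 & reach >= 14))
})

test_that("adding generations never worsens the best clash-free reach
           (elitism)", {
  pk <- default_pocket()
  ng <- pocket_without_gates(pk)
  best_cf <- function(gens) {
    fr <- evolve_exit_paths(ng, pk$ligand, pk$annotations$start_pose,
                            "rigid",
                            ga_config(population = 24, generations = gens,
                                      seed = 9), pk$params)
    clash <- vapply(fr, `[[`, numeric(1), "total_clash")
    reach <- vapply(fr, `[[`, numeric(1), "reach")
    if (any(clash == 0)) max(reach[clash == 0]) else -Inf
  }
  expect_gte(best_cf(24), best_cf(8))
})

test_that("a clashing start pose is refused", {
  pk <- default_pocket()
  bad <- new_pose(translation = c(4.8, 0, 3))   # inside the wall
  expect_error(evolve_exit_paths(pk$structure, pk$ligand, bad, "rigid",
                                 fast_ga(1), pk$params), "clash-free")
})

test_that("clash_vs_separation bins a hand-built path correctly", {
  mk <- function(separations, clashes) {
    structure(list(separations = separations, clash_counts = clashes,
                   total_clash = sum(clashes), reach = max(separations)),
              class = "PathCandidate")
  }
  front <- list(mk(c(0, 0.6, 1.4), c(0L, 2L, 1L)),
                mk(c(0, 0.7, 2.6), c(1L, 0L, 4L)))
  prof <- clash_vs_separation(front)
  # bin [0, 0.5): min(0, 1) = 0; bin [0.5, 1): min(2, 0) = 0;
  # bin [1, 1.5): 1; bin [2.5, 3): 4
  expect_equal(prof$min_clash[prof$sep_lo == 0.0], 0)
  expect_equal(prof$min_clash[prof$sep_lo == 0.5], 0)
  expect_equal(prof$min_clash[prof$sep_lo == 1.0], 1)
  expect_equal(prof$min_clash[prof$sep_lo == 2.5], 4)
  expect_error(clash_vs_separation(list()), "empty")
})

test_that("a zero-clash single path yields an all-zero profile", {
  cand <- structure(list(separations = c(0, 1, 2, 3),
                         clash_counts = rep(0L, 4), total_clash = 0L,
                         reach = 3), class = "PathCandidate")
  prof <- clash_vs_separation(list(cand))
  expect_true(all(prof$min_clash == 0))
})
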