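test_that("competitive rate law closed forms", {
  expect_equal(competitive_rate(S = 2, I = 0, Vmax = 1, KM = 2, Ki = 3),
               0.5)
  expect_equal(competitive_rate(S = 2, I = 3, Vmax = 1, KM = 2, Ki = 3),
               1 / 3)
  set.seed(2)
  for (i in 1:20) {
    S <- stats::runif(1, 0.1, 10); I <- stats::runif(1, 0, 10)
    Vmax <- stats::runif(1, 0.5, 5); KM <- stats::runif(1, 0.5, 5)
    Ki <- stats::runif(1, 0.5, 5)
    expect_equal(competitive_rate(S, I, Vmax, KM, Ki),
                 Vmax * S / (KM * (1 + I / Ki) + S))
  }
  # strictly decreasing in inhibitor
  v <- competitive_rate(2, c(0, 1, 2, 4), 1, 2, 3)
  expect_true(all(diff(v) < 0))
  expect_error(competitive_rate(2, 1, -1, 2, 3), "positive")
})

test_that("noise-free data identify the kinetic parameters and the Dixon
           intersection equals -Ki", {
  d <- make_kinetic_dataset(Vmax = 1, KM = 2, Ki = 2.55, noise_cv = 0,
                            seed = 1)
  fit <- fit_competitive_ki(d)
  expect_equal(unname(fit$params["Ki"]), 2.55, tolerance = 1e-6)
  expect_equal(unname(fit$params["KM"]), 2, tolerance = 1e-6)
  expect_equal(unname(fit$params["Vmax"]), 1, tolerance = 1e-6)
  expect_equal(fit$dixon_ki, 2.55, tolerance = 1e-6)
  expect_error(fit_competitive_ki(d[d$S == d$S[1], ]), "identifiable")
})

test_that("SPR steady-state fit recovers KD and the series has the stated
           design", {
  d <- make_spr_dataset(KD = 1.6e-4, Rmax = 80, n_conc = 9, noise_cv = 0,
                        seed = 3)
  expect_equal(min(d$C), 0.1 * 1.6e-4)
  expect_equal(max(d$C), 10 * 1.6e-4)
  expect_equal(sum(duplicated(d$C)), 1)  # one duplicated concentration
  fit <- fit_spr_kd(d)
  expect_equal(fit$KD, 1.6e-4, tolerance = 1e-6)
  expect_equal(fit$Rmax, 80, tolerance = 1e-4)
  # response at C = KD is half-maximal on noise-free data
  half <- d$Req[which.min(abs(d$C - 1.6e-4))]
  expect_equal(half, 40, tolerance = 1e-6)
  expect_error(make_spr_dataset(KD = 1e-4, n_conc = 3), "under-determined")
})

test_that("delta_g identities and monotonicity", {
  expect_equal(delta_g(1, 298.15), 0)
  expect_true(all(diff(delta_g(c(1e-6, 1e-4, 1e-2, 1), 298.15)) > 0))
  set.seed(6)
  for (i in 1:10) {
    K <- 10^stats::runif(1, -8, 2); Tk <- stats::runif(1, 273, 320)
    expect_equal(delta_g(K, Tk) + delta_g(1 / K, Tk), 0, tolerance = 1e-9)
    expect_equal(delta_g(K, Tk), 8.314 * Tk * log(K) / 1000)
  }
  expect_error(delta_g(-1), "positive")
})

test_that("the affinity report assigns temperatures by source and flags
           unknown tags", {
  rep <- table1_report()
  expect_equal(rep$table$T_kelvin,
               c(298.15, 298.15, rep(303.15, 5)))
  # AffinityResult invariant: delta_g consistent with K and T
  expect_equal(rep$table$delta_g,
               8.314 * rep$table$T_kelvin * log(rep$table$K) / 1000,
               tolerance = 1e-9)
  expect_error(table1_report(data.frame(ligand = "x", K = 1e-3,
                                        source = "ITC")), "unknown source")
  one <- table1_report(data.frame(ligand = "Glc", K = 0.16e-3,
                                  source = "SPR"))
  expect_equal(nrow(one$table), 1)
})

test_that("the nominal Ki is covered by the 95 percent interval in most
           noisy replicates", {
  hits <- 0
  n_sim <- 100
  for (sd in seq_len(n_sim)) {
    d <- make_kinetic_dataset(Vmax = 1, KM = 2, Ki = 2.55, noise_cv = 0.05,
                              seed = 4000 + sd)
    fit <- fit_competitive_ki(d)
    lo <- fit$params["Ki"] - 1.96 * fit$se["Ki"]
    hi <- fit$params["Ki"] + 1.96 * fit$se["Ki"]
    if (2.55 >= lo && 2.55 <= hi) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
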