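test_that("binding model constructors enforce the statistical identities", {
  m <- statistical_from_micro(1000)
  expect_equal(m$K1, 2000)
  expect_equal(m$K2, 500)
  expect_identical(m$K1 / m$K2, 4)
  expect_identical(m$alpha, 1)

  m0 <- statistical_from_micro(0)
  expect_equal(m0$K1, 0)
  expect_equal(m0$K2, 0)

  expect_error(statistical_from_micro(-1), "non-negative")
  expect_error(binding_model("2:1-full", K1 = 100), "K2")
  expect_error(binding_model("1:1", K1 = Inf), "finite")
  expect_error(binding_model("2:1-statistical", K1 = 10, k_micro = 5),
               "k_micro")
})

test_that("no-binding and empty-titrant limits are exact", {
  m <- binding_model("2:1-full", K1 = 0, K2 = 0)
  sp <- solve_speciation(m, 1e-5, 3e-5)
  expect_identical(sp$free_ligand, 3e-5)
  expect_identical(sp$free_receptor, 1e-5)
  expect_identical(sp$complex_RL, 0)
  expect_identical(sp$complex_RL2, 0)

  sp0 <- solve_speciation(statistical_from_micro(5e3), 1e-5, 0)
  expect_identical(sp0$free_receptor, 1e-5)
  expect_identical(sp0$free_ligand, 0)
  expect_identical(sp0$site_occupancy, 0)

  # zero receptor shortcut avoids the 0/0 mass balance
  spr <- solve_speciation(statistical_from_micro(5e3), 0, 2e-5)
  expect_identical(spr$free_ligand, 2e-5)
  expect_identical(spr$site_occupancy, 0)
})

test_that("2:1 free ligand matches the interval-bisection oracle", {
  m <- binding_model("2:1-full", K1 = 2000, K2 = 500)
  sp <- solve_speciation(m, 62.5e-6, 125e-6)
  p_oracle <- oracle_free_ligand(2000, 500, 62.5e-6, 125e-6)
  expect_rel_equal(sp$free_ligand, p_oracle, 1e-9)
})

test_that("mass balance holds to 1e-10 relative on random valid inputs", {
  set.seed(4821)
  n <- 2000L
  for (i in seq_len(n)) {
    K1 <- 10^stats::runif(1, 0, 8)
    K2 <- 10^stats::runif(1, 0, 8)
    Rt <- 10^stats::runif(1, -8, -2)
    Lt <- 10^stats::runif(1, -8, -2)
    sp <- solve_speciation(binding_model("2:1-full", K1 = K1, K2 = K2),
                           Rt, Lt)
    expect_true(all(c(sp$free_receptor, sp$free_ligand, sp$complex_RL,
                      sp$complex_RL2) >= 0))
    r_err <- abs(sp$free_receptor + sp$complex_RL + sp$complex_RL2 - Rt) / Rt
    l_err <- abs(sp$free_ligand + sp$complex_RL + 2 * sp$complex_RL2 - Lt) / Lt
    if (r_err > 1e-10 || l_err > 1e-10)
      fail(sprintf("mass balance violated at K1=%g K2=%g Rt=%g Lt=%g",
                   K1, K2, Rt, Lt))
  }
  succeed()
})

test_that("statistical 2:1 speciation equals independent 1:1 sites", {
  set.seed(99)
  for (i in 1:200) {
    k <- 10^stats::runif(1, 0, 8)
    Rt <- 10^stats::runif(1, -8, -2)
    Lt <- 10^stats::runif(1, -8, -2)
    sp <- solve_speciation(statistical_from_micro(k), Rt, Lt)
    p <- sp$free_ligand
    expect_rel_equal(sp$site_occupancy, k * p / (1 + k * p), 1e-9)
    # same free ligand as a 1:1 system with site_total = 2 Rt
    sp11 <- solve_speciation(binding_model("1:1", K1 = k), 2 * Rt, Lt)
    expect_rel_equal(sp$free_ligand, sp11$free_ligand, 1e-9)
    expect_rel_equal(sp$site_occupancy, sp11$site_occupancy, 1e-9)
  }
})

test_that("1:1 closed form agrees with bisection on its own mass balance", {
  set.seed(7)
  for (i in 1:200) {
    K <- 10^stats::runif(1, 0, 8)
    Rt <- 10^stats::runif(1, -8, -2)
    Lt <- 10^stats::runif(1, -8, -2)
    sp <- solve_speciation(binding_model("1:1", K1 = K), Rt, Lt)
    p_oracle <- oracle_free_ligand(K, 0, Rt, Lt)
    expect_rel_equal(sp$free_ligand, p_oracle, 1e-9)
  }
})

test_that("occupancies are invariant to concentration/constant rescaling", {
  set.seed(11)
  for (i in 1:50) {
    K1 <- 10^stats::runif(1, 1, 7); K2 <- 10^stats::runif(1, 1, 7)
    Rt <- 10^stats::runif(1, -7, -3); Lt <- 10^stats::runif(1, -7, -3)
    cc <- 10^stats::runif(1, -2, 2)
    a <- solve_speciation(binding_model("2:1-full", K1 = K1, K2 = K2), Rt, Lt)
    b <- solve_speciation(binding_model("2:1-full", K1 = K1 / cc, K2 = K2 / cc),
                          Rt * cc, Lt * cc)
    expect_rel_equal(b$site_occupancy, a$site_occupancy, 1e-9)
    expect_rel_equal(b$ligand_bound_fraction, a$ligand_bound_fraction, 1e-9)
  }
})

test_that("saturation curves are monotone and match the per-point oracle", {
  m <- statistical_from_micro(5000)
  grid <- c(0, 1, 2, 4, 8, 16)
  sat <- saturation_curve(m, 20e-6, grid)
  expect_identical(sat$site_occupancy[1], 0)
  expect_true(all(diff(sat$site_occupancy) >= 0))
  for (j in seq_along(grid)[-1]) {
    p <- oracle_free_ligand(m$K1, m$K2, 20e-6, grid[j] * 20e-6)
    occ <- 5000 * p / (1 + 5000 * p)
    expect_rel_equal(sat$site_occupancy[j], occ, 1e-9)
  }
  # strong binder saturates towards 1
  sat2 <- saturation_curve(statistical_from_micro(1e7), 20e-6,
                           c(1, 2, 4, 8, 64))
  expect_gt(sat2$site_occupancy[5], 0.99)
})

test_that("invalid speciation inputs raise domain errors", {
  m <- statistical_from_micro(1e4)
  expect_error(solve_speciation(m, -1e-6, 1e-6), "non-negative")
  expect_error(solve_speciation(m, 1e-6, NaN), "finite")
  expect_error(saturation_curve(m, 1e-6, c(-1, 2)), "non-negative")
  expect_error(solve_speciation("not a model", 1e-6, 1e-6), "binding_model")
})
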