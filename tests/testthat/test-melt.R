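test_that("symmetric sigmoid midpoint is recovered exactly", {
  d <- gen_melt(melt_design(T_half = 40, s = 1, noise_sd = 0))
  fit <- fit_melt(d)
  expect_lt(abs(fit$Tm - 40), 1e-3)
  expect_lt(abs(fit$Tm - fit$T_half), 1e-6)  # s = 1 collapse
})

test_that("asymmetric noiseless curves match the grid-interpolation oracle", {
  d <- gen_melt(melt_design(T_half = 40, width = 3, s = 2.5,
                            A_folded = 0, A_unfolded = -10, noise_sd = 0))
  fit <- suppressWarnings(fit_melt(d))
  tm_oracle <- oracle_tm_grid(0, -10, 40, 3, 2.5)
  expect_lt(abs(fit$Tm - tm_oracle), 0.01)
  expect_lt(abs(fit$s - 2.5), 1e-3)
  expect_lt(abs(fit$width - 3), 1e-3)
})

test_that("noisy Tm recovery is unbiased to 0.1 degC", {
  n_seed <- 25L  # reduced-size version of the acceptance Monte-Carlo
  truth <- tm_from_sigmoid(40, 3, 1.6)
  tm <- vapply(seq_len(n_seed), function(s) {
    d <- gen_melt(melt_design(T_half = 40, width = 3, s = 1.6,
                              noise_sd = 0.2, seed = 800 + s))
    fit_melt(d)$Tm
  }, numeric(1))
  expect_lt(abs(mean(tm) - truth), 0.1)
})

test_that("Tm is invariant under affine ellipticity transforms", {
  d <- gen_melt(melt_design(T_half = 43, width = 4, s = 1.8,
                            noise_sd = 0.1, seed = 5))
  f0 <- fit_melt(d)
  d2 <- melt_curve(d$temperatures, 3.7 * d$ellipticity - 12)
  f2 <- fit_melt(d2)
  expect_lt(abs(f2$Tm - f0$Tm), 1e-6)
  # negative scale flips the orientation but not the melting temperature
  d3 <- melt_curve(d$temperatures, -2 * d$ellipticity + 4)
  f3 <- fit_melt(d3, orientation = "folded_low")
  expect_lt(abs(f3$Tm - f0$Tm), 1e-6)
})

test_that("Tm is equivariant under temperature shifts", {
  d <- gen_melt(melt_design(T_half = 40, width = 3, s = 1.4,
                            noise_sd = 0.1, seed = 6))
  f0 <- fit_melt(d)
  dsh <- melt_curve(d$temperatures + 7.5, d$ellipticity)
  fsh <- fit_melt(dsh)
  expect_lt(abs(fsh$Tm - (f0$Tm + 7.5)), 1e-6)
})

test_that("linear baselines are fitted behind the flag", {
  Tv <- seq(5, 95, 0.2)
  pars_y <- (2 - 0.01 * Tv) + ((9 + 0.02 * Tv) - (2 - 0.01 * Tv)) /
    (1 + exp((Tv - 45) / 3))
  set.seed(31)
  d <- melt_curve(Tv, pars_y + rnorm(length(Tv), 0, 0.1))
  fit <- fit_melt(d, baseline = "linear")
  expect_lt(abs(fit$Tm - 45), 0.2)
  expect_gt(abs(fit$m_folded) + abs(fit$m_unfolded), 1e-4)
})

test_that("flat curves raise transition errors", {
  flat <- melt_curve(seq(5, 95, 1), rep(5, 91) + seq(0, 0.5, length.out = 91))
  expect_error(fit_melt(flat), class = "quadbind_transition_error")
})

test_that("fraction folded is the exact linear normalization", {
  expect_identical(fraction_folded(-10, -10, 0), 1)
  expect_identical(fraction_folded(0, -10, 0), 0)
  expect_identical(fraction_folded(-5, -10, 0), 0.5)
  # linearity and no clipping
  v <- seq(-12, 2, by = 0.5)
  th <- fraction_folded(v, -10, 0)
  expect_equal(th, (v - 0) / (-10 - 0))
  expect_gt(max(th), 1)  # value beyond the folded reference
  expect_error(fraction_folded(1, 5, 5), "differ")
})

test_that("melt_fit methods are coherent", {
  d <- gen_melt(melt_design(T_half = 40, s = 1.6, noise_sd = 0.2, seed = 9))
  fit <- fit_melt(d)
  expect_named(coef(fit), c("A_folded", "A_unfolded", "T_half", "width", "s"))
  expect_equal(length(residuals(fit)), 451L)
  expect_equal(fitted(fit) + residuals(fit), d$ellipticity)
  expect_equal(predict(fit, d$temperatures), fitted(fit), tolerance = 1e-8)
  expect_gt(fit$Tm_se, 0)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_s3_class(sims[[2]], "melt_curve")
  expect_output(print(summary(fit)), "Tm")
})
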