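make_series <- function(k = 5e3, delta_free = 7.300, delta_bound = 7.180,
                        Lt = 125e-6, eq = seq(0, 2, length.out = 12),
                        noise_sd = 0, seed = NULL) {
  Rt <- eq * Lt
  truth <- oracle_statistical_trace(k, Lt, Rt, delta_free, delta_bound)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    truth <- truth + stats::rnorm(length(truth), 0, noise_sd)
  }
  titration_series(Lt, eq, nuclei = list(PheH = truth))
}

test_that("predicted shifts reduce to delta_free with zero titrant", {
  s <- titration_series(125e-6, seq(0, 2, length.out = 12),
                        nuclei = list(PheH = rep(0, 12)))
  sh <- list(PheH = list(delta_free = 7.3, delta_bound_1 = 7.1))
  pred <- predict_shifts(statistical_from_micro(5e3), sh, s)
  expect_identical(pred$PheH[1], 7.3)  # bit-for-bit at zero titrant

  # null response: all shift parameters equal gives a flat trace
  sh_null <- list(PheH = list(delta_free = 7.3, delta_bound_1 = 7.3,
                              delta_bound_2 = 7.3))
  pred_null <- predict_shifts(binding_model("2:1-full", K1 = 2000, K2 = 500),
                              sh_null, s)
  expect_equal(pred_null$PheH, rep(7.3, 12))
})

test_that("predicted shifts equal the speciation-oracle weighted average", {
  eq <- c(0, 0.5)
  s <- titration_series(125e-6, eq, nuclei = list(PheH = rep(0, 2)))
  sh <- list(PheH = list(delta_free = 7.300, delta_bound_1 = 7.100,
                         delta_bound_2 = 7.100))
  pred <- predict_shifts(binding_model("2:1-full", K1 = 2000, K2 = 500),
                         sh, s)
  # point 2: RNA 62.5 uM, peptide 125 uM
  p <- oracle_free_ligand(2000, 500, 62.5e-6, 125e-6)
  bound_frac <- (125e-6 - p) / 125e-6
  expect_rel_equal(pred$PheH[2], 7.300 - 0.200 * bound_frac, 1e-9)
})

test_that("predicted isotherms are monotone for fixed-sign shift changes", {
  eq <- seq(0, 2, length.out = 15)
  s <- titration_series(125e-6, eq, nuclei = list(PheH = rep(0, 15)))
  for (m in list(binding_model("1:1", K1 = 4e3),
                 statistical_from_micro(4e3))) {
    pred <- predict_shifts(m, list(PheH = list(delta_free = 7.3,
                                               delta_bound_1 = 7.1)), s)
    expect_true(all(diff(pred$PheH) <= 0))
  }
})

test_that("noiseless statistical data are recovered almost exactly", {
  ser <- make_series()
  fit <- fit_titration(ser, model = "2:1-statistical")
  expect_lt(abs(fit$model$k_micro - 5e3) / 5e3, 1e-3)
  expect_lt(abs(fit$shifts$PheH$delta_free - 7.300), 1e-4)
  expect_lt(abs(fit$shifts$PheH$delta_bound_1 - 7.180), 1e-4)
  expect_false(fit$unidentifiable)
  expect_equal(fit$n_params, 3L)
  expect_equal(fit$n_points, 12L)
})

test_that("optimum is invariant to fitting on the K rather than log10 K scale", {
  ser <- make_series(noise_sd = 0.002, seed = 11)
  fit <- fit_titration(ser, model = "2:1-statistical")
  # independent 1-d minimisation on the natural-K scale, profiling the
  # shifts the same exact way but through the closed-form trace oracle
  rss_K <- function(K) {
    frac_bound <- 1 -
      oracle_statistical_trace(K, 125e-6, ser$equivalents * 125e-6, 1, 0)
    X <- cbind(1 - frac_bound, frac_bound)
    sum(stats::lm.fit(X, ser$nuclei$PheH)$residuals^2)
  }
  opt <- stats::optimize(rss_K, c(1e3, 3e4), tol = 1e-9)
  expect_lt(abs(opt$objective - fit$rss) / opt$objective, 1e-6)
  expect_lt(abs(opt$minimum - fit$model$k_micro) / fit$model$k_micro, 1e-4)
})

test_that("noisy recovery and CI coverage meet the Monte-Carlo bounds", {
  # reduced-size version of the acceptance study (full run in acceptance)
  n_seed <- 25L
  err <- numeric(n_seed); cover <- logical(n_seed)
  for (s in seq_len(n_seed)) {
    reps <- gen_titration(titration_design(seed = 7000 + s))
    fits <- lapply(reps, fit_titration)
    avg <- average_constants(fits)
    err[s] <- abs(avg$K - 5e3) / 5e3
    cover[s] <- abs(avg$K - 5e3) <= 1.96 * avg$se
  }
  expect_lt(stats::median(err), 0.10)
  expect_gte(sum(cover), ceiling(0.75 * n_seed))
})

test_that("flat traces are flagged unidentifiable", {
  ser <- titration_series(125e-6, seq(0, 2, length.out = 12),
                          nuclei = list(PheH = rep(7.3, 12) +
                                          seq(0, 1e-5, length.out = 12)))
  fit <- fit_titration(ser, model = "2:1-statistical")
  expect_true(fit$unidentifiable)
  expect_true(all(is.na(fit$standard_errors)))
})

test_that("fit preconditions are enforced", {
  short <- titration_series(125e-6, c(0, 0.5, 1, 1.5),
                            nuclei = list(PheH = c(7.3, 7.25, 7.22, 7.2)))
  expect_error(fit_titration(short), "at least 5")
  expect_error(titration_series(0, c(0, 1), nuclei = list(a = c(1, 2))),
               "positive")
  expect_error(titration_series(1e-4, c(0, 1, 1), nuclei = list(a = 1:3)),
               "strictly increasing")
})

test_that("AICc matches the hand formula and penalises parameters", {
  ser <- make_series(noise_sd = 0.002, seed = 1)
  fit <- fit_titration(ser, model = "2:1-statistical")
  n <- fit$n_points; p <- fit$n_params
  expect_equal(fit$aicc,
               n * log(fit$rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1))
  fit_full <- fit_titration(ser, model = "2:1-full")
  expect_equal(fit_full$n_params, 5L)  # 2 constants + 3 shifts per nucleus
})

test_that("titration_fit methods are coherent", {
  ser <- make_series(noise_sd = 0.002, seed = 3)
  fit <- fit_titration(ser)
  expect_named(coef(fit))
  expect_equal(length(residuals(fit)$PheH), 12L)
  expect_equal(fitted(fit)$PheH + residuals(fit)$PheH, ser$nuclei$PheH)
  pred <- predict(fit, newdata = c(0, 1, 2))
  expect_equal(pred$PheH[1], fit$shifts$PheH$delta_free)
  sims <- simulate(fit, nsim = 2, seed = 9, noise_sd = 0.002)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "titration_series")
  expect_output(print(summary(fit)), "Titration fit")
})
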