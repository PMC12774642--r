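# Independent numerical oracles, deliberately distinct from the package's
# own solvers.

# interval bisection on the monotone ligand mass balance
# h(p) = p + Rt*(K1 p + 2 K1 K2 p^2)/(1 + K1 p + K1 K2 p^2) - Lt
oracle_free_ligand <- function(K1, K2, Rt, Lt, iter = 200L) {
  if (Lt == 0) return(0)
  h <- function(p) {
    d <- 1 + K1 * p + K1 * K2 * p^2
    p + Rt * (K1 * p + 2 * K1 * K2 * p^2) / d - Lt
  }
  lo <- 0; hi <- Lt
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (h(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# half-signal crossing of the 5-parameter sigmoid by dense-grid linear
# interpolation
oracle_tm_grid <- function(Af, Au, Th, w, s, trange = c(5, 95),
                           n = 400001L) {
  Tg <- seq(trange[1], trange[2], length.out = n)
  y <- Au + (Af - Au) / (1 + exp((Tg - Th) / w))^s
  mid <- (Af + Au) / 2
  d <- y - mid
  i <- which(d[-1] * d[-n] <= 0)[1]
  Tg[i] + (Tg[i + 1] - Tg[i]) * d[i] / (d[i] - d[i + 1])
}

# noiseless traces for a statistical 2:1 titration, built from the
# independent-sites closed form (not from solve_speciation)
oracle_statistical_trace <- function(k, Lt, Rt_vec, delta_free, delta_bound) {
  vapply(Rt_vec, function(Rt) {
    site_total <- 2 * Rt
    # independent sites: free ligand solves p + site_total*k*p/(1+k*p) = Lt
    b <- 1 + k * (site_total - Lt)
    p <- if (b >= 0) 2 * Lt / (b + sqrt(b^2 + 4 * k * Lt)) else
      (sqrt(b^2 + 4 * k * Lt) - b) / (2 * k)
    bound_frac <- (Lt - p) / Lt
    delta_free + (delta_bound - delta_free) * bound_frac
  }, numeric(1))
}

expect_rel_equal <- function(object, expected, rel_tol) {
  scale <- pmax(abs(expected), .Machine$double.xmin)
  expect_lt(max(abs(object - expected) / scale), rel_tol)
}
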