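#' Predicted fast-exchange chemical shifts for a titration series
#'
#' Under fast exchange a single population-weighted resonance is observed
#' for the ligand (the peptide), so at every titration point
#' `delta_obs = (delta_free * [L] + delta_bound_1 * [RL] +
#' delta_bound_2 * 2 [RL2]) / L_total`, with the species concentrations
#' from [solve_speciation()]. With zero titrant the prediction is exactly
#' `delta_free`.
#'
#' @param model A [binding_model()].
#' @param shifts Named list, one element per nucleus of `series`, each a
#'   list or named vector with `delta_free`, `delta_bound_1` and (for the
#'   full 2:1 model) `delta_bound_2` in ppm. For the statistical model
#'   `delta_bound_2` is taken equal to `delta_bound_1` (one bound
#'   environment).
#' @param series A [titration_series()].
#' @return A named list of numeric vectors (ppm), one per nucleus.
#' @examples
#' s <- titration_series(125e-6, seq(0, 2, length.out = 12),
#'                       nuclei = list(PheH = rep(7.3, 12)))
#' predict_shifts(statistical_from_micro(5e3),
#'                list(PheH = c(delta_free = 7.3, delta_bound_1 = 7.18)), s)
#' @export
predict_shifts <- function(model, shifts, series) {
  assert_binding_model(model)
  if (!inherits(series, "titration_series"))
    stop("'series' must be a titration_series", call. = FALSE)
  frac <- speciation_fractions(model, series)
  out <- lapply(names(series$nuclei), function(nm) {
    sh <- shifts[[nm]]
    if (is.null(sh))
      stop(sprintf("no shift parameters supplied for nucleus '%s'", nm),
           call. = FALSE)
    sh <- as.list(sh)
    d_free <- sh$delta_free
    d_b1 <- sh$delta_bound_1
    d_b2 <- if (model$model_id == "2:1-statistical" || is.null(sh$delta_bound_2))
      d_b1 else sh$delta_bound_2
    if (is.null(d_free) || is.null(d_b1))
      stop("shift parameters need 'delta_free' and 'delta_bound_1'",
           call. = FALSE)
    as.numeric(frac %*% c(d_free, d_b1, d_b2))
  })
  names(out) <- names(series$nuclei)
  out
}

# n x 3 matrix of ligand mole fractions (free, in RL, in RL2) per point
speciation_fractions <- function(model, series) {
  Lt <- fixed_per_point(series)
  n <- length(series$equivalents)
  frac <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (Lt[i] <= 0) { frac[i, 1] <- 1; next }
    sp <- solve_speciation(model, series$titrant_total[i], Lt[i])
    frac[i, ] <- c(sp$free_ligand, sp$complex_RL, 2 * sp$complex_RL2) / Lt[i]
  }
  frac
}

fixed_per_point <- function(series) {
  if (!is.null(series$fixed_per_point)) series$fixed_per_point
  else rep(series$fixed_species_total, length(series$equivalents))
}

#' Fit a binding model to an NMR titration series
#'
#' Globally fits one set of equilibrium constants (shared across nuclei)
#' and per-nucleus shift parameters to the observed chemical-shift traces
#' by least squares. Constants are optimised in log10 space after a coarse
#' grid search over `log10 K = 1..8`; at each candidate the shift
#' parameters, which enter the prediction linearly, are profiled out by
#' exact linear projection (QR), so the nonlinear search is over one
#' (1:1, statistical 2:1) or two (full 2:1) dimensions only.
#'
#' Standard errors come from the Jacobian of the residuals at the optimum
#' (`sigma^2 (J'J)^-1`); the corrected Akaike information criterion is
#' `AICc = n log(rss/n) + 2p + 2p(p+1)/(n-p-1)`. Traces whose total
#' excursion is below `noise_sd` are flagged unidentifiable and reported
#' without confidence intervals.
#'
#' @param series A [titration_series()] (>= 5 points, >= 1 nucleus).
#' @param model Model identifier: `"2:1-statistical"`, `"1:1"` or
#'   `"2:1-full"`.
#' @param noise_sd Shift noise scale (ppm) used only to flag flat,
#'   unidentifiable traces. Default 0.002 ppm.
#' @param log10K_grid Coarse initialisation grid for log10 of the
#'   association constant(s).
#' @return An object of class `"titration_fit"` with components `model`
#'   (fitted [binding_model()]), `shifts`, `standard_errors`, `covariance`,
#'   `rss`, `n_points`, `n_params`, `aicc`, `fitted`, `residuals`,
#'   `unidentifiable`, and the input `series`.
#' @seealso [compare_binding_models()], [average_constants()]
#' @export
fit_titration <- function(series,
                          model = c("2:1-statistical", "1:1", "2:1-full"),
                          noise_sd = 0.002, log10K_grid = 1:8) {
  model_id <- match.arg(model)
  if (!inherits(series, "titration_series"))
    stop("'series' must be a titration_series", call. = FALSE)
  n_pt <- length(series$equivalents)
  n_nuc <- length(series$nuclei)
  if (n_pt < 5L)
    stop("need at least 5 titration points to fit", call. = FALSE)

  n_const <- n_constants(model_id)
  n_shift <- if (model_id == "2:1-full") 3L else 2L
  n_par <- n_const + n_shift * n_nuc
  n_obs <- n_pt * n_nuc
  if (n_obs <= n_par)
    stop(structure(class = c("quadbind_fit_error", "error", "condition"),
                   list(message = "fewer observations than parameters",
                        call = NULL)))

  amp <- vapply(series$nuclei, function(y) diff(range(y)), numeric(1))
  unidentifiable <- all(amp < noise_sd)

  y <- series$nuclei
  make_model <- function(theta) {
    switch(model_id,
           "1:1" = binding_model("1:1", K1 = 10^theta[1]),
           "2:1-statistical" = statistical_from_micro(10^theta[1]),
           "2:1-full" = binding_model("2:1-full", K1 = 10^theta[1],
                                      K2 = 10^theta[2]))
  }
  # design matrix columns for the linear shift parameters
  design <- function(frac) {
    if (model_id == "2:1-full") frac
    else cbind(frac[, 1], frac[, 2] + frac[, 3])
  }
  profile_rss <- function(theta) {
    m <- make_model(theta)
    X <- design(speciation_fractions(m, series))
    sum(vapply(y, function(yy) {
      fit <- stats::lm.fit(X, yy)
      sum(fit$residuals^2)
    }, numeric(1)))
  }

  if (n_const == 1L) {
    g <- vapply(log10K_grid, function(l) profile_rss(l), numeric(1))
    l0 <- log10K_grid[which.min(g)]
    opt <- stats::optimize(profile_rss, c(l0 - 1.5, l0 + 1.5),
                           tol = 1e-10)
    theta <- opt$minimum
  } else {
    g <- vapply(log10K_grid, function(l) profile_rss(c(l, l - log10(4))),
                numeric(1))
    l0 <- log10K_grid[which.min(g)]
    opt <- stats::optim(c(l0, l0 - log10(4)), profile_rss,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    theta <- opt$par
  }

  m_hat <- make_model(theta)
  X <- design(speciation_fractions(m_hat, series))
  shifts <- list(); fitted <- list(); resid <- list(); beta_all <- numeric(0)
  rss <- 0
  for (nm in names(y)) {
    fit <- stats::lm.fit(X, y[[nm]])
    b <- unname(fit$coefficients)
    b[is.na(b)] <- 0
    shifts[[nm]] <- if (model_id == "2:1-full")
      list(delta_free = b[1], delta_bound_1 = b[2], delta_bound_2 = b[3])
    else
      list(delta_free = b[1], delta_bound_1 = b[2], delta_bound_2 = b[2])
    fitted[[nm]] <- as.numeric(X %*% b)
    resid[[nm]] <- y[[nm]] - fitted[[nm]]
    rss <- rss + sum(resid[[nm]]^2)
    beta_all <- c(beta_all, b[seq_len(n_shift)])
  }

  par_names <- c(
    switch(model_id, "1:1" = "log10_K",
           "2:1-statistical" = "log10_k_micro",
           "2:1-full" = c("log10_K1", "log10_K2")),
    as.vector(t(outer(names(y),
                      if (n_shift == 2L) c("delta_free", "delta_bound")
                      else c("delta_free", "delta_bound_1", "delta_bound_2"),
                      paste, sep = "."))))
  theta_full <- c(theta, beta_all)
  names(theta_full) <- par_names

  se <- rep(NA_real_, n_par); names(se) <- par_names
  covmat <- matrix(NA_real_, n_par, n_par, dimnames = list(par_names, par_names))
  if (!unidentifiable) {
    J <- resid_jacobian(theta_full, n_const, n_shift, model_id, make_model,
                        design, series, y)
    JtJ <- crossprod(J)
    sigma2 <- rss / (n_obs - n_par)
    cv <- tryCatch(sigma2 * solve(JtJ), error = function(e) NULL)
    if (!is.null(cv)) {
      covmat <- cv; dimnames(covmat) <- list(par_names, par_names)
      se <- sqrt(pmax(diag(cv), 0)); names(se) <- par_names
    }
  }

  aicc <- if (n_obs - n_par - 1 > 0)
    n_obs * log(rss / n_obs) + 2 * n_par + 2 * n_par * (n_par + 1) /
      (n_obs - n_par - 1) else Inf

  structure(list(
    model = m_hat, shifts = shifts, standard_errors = se,
    covariance = covmat, rss = rss, n_points = n_obs, n_params = n_par,
    aicc = aicc, fitted = fitted, residuals = resid,
    unidentifiable = unidentifiable, theta = theta_full,
    series = series), class = "titration_fit")
}

# numeric Jacobian of the stacked residual vector wrt all parameters
resid_jacobian <- function(theta_full, n_const, n_shift, model_id,
                           make_model, design, series, y) {
  rfun <- function(th) {
    m <- make_model(th[seq_len(n_const)])
    X <- design(speciation_fractions(m, series))
    unlist(lapply(seq_along(y), function(j) {
      b <- th[n_const + (j - 1L) * n_shift + seq_len(n_shift)]
      y[[j]] - as.numeric(X %*% b)
    }), use.names = FALSE)
  }
  r0 <- rfun(theta_full)
  J <- matrix(0, length(r0), length(theta_full))
  for (k in seq_along(theta_full)) {
    hk <- max(1e-6, abs(theta_full[k]) * 1e-6)
    tp <- theta_full; tp[k] <- tp[k] + hk
    tm <- theta_full; tm[k] <- tm[k] - hk
    J[, k] <- (rfun(tp) - rfun(tm)) / (2 * hk)
  }
  -J
}

#' Headline association constant of a fitted or specified model
#'
#' The microscopic per-site constant for the statistical 2:1 model, K for
#' 1:1 and K1 for the full 2:1 model, with its delta-method standard error
#' (from the log10-space fit) when available.
#' @param fit A `titration_fit`.
#' @return Named list `K`, `se`.
#' @export
primary_constant <- function(fit) {
  stopifnot(inherits(fit, "titration_fit"))
  K <- if (fit$model$model_id == "2:1-statistical") fit$model$k_micro
       else fit$model$K1
  se_log <- fit$standard_errors[[1L]]
  list(K = K, se = if (is.finite(se_log)) K * log(10) * se_log else NA_real_)
}

#' @export
print.titration_fit <- function(x, ...) {
  pc <- primary_constant(x)
  cat(sprintf("Titration fit: %s model, %d observations, %d parameters\n",
              x$model$model_id, x$n_points, x$n_params))
  lbl <- if (x$model$model_id == "2:1-statistical") "k (per site)" else
    if (x$model$model_id == "1:1") "K" else "K1"
  cat(sprintf("  %s = %.4g +/- %.3g M^-1\n", lbl, pc$K, pc$se))
  if (x$model$model_id == "2:1-full")
    cat(sprintf("  K2 = %.4g M^-1 (alpha = %.3g)\n", x$model$K2,
                x$model$alpha))
  cat(sprintf("  rss = %.4g ppm^2, AICc = %.2f\n", x$rss, x$aicc))
  if (x$unidentifiable)
    cat("  WARNING: flat trace(s); constants unidentifiable, no confidence reported\n")
  invisible(x)
}

#' @export
summary.titration_fit <- function(object, ...) {
  est <- object$theta
  tab <- data.frame(estimate = est,
                    std_error = object$standard_errors[names(est)])
  structure(list(fit = object, coefficients = tab,
                 sigma = sqrt(object$rss /
                                max(object$n_points - object$n_params, 1))),
            class = "summary.titration_fit")
}

#' @export
print.summary.titration_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sd = %.4g ppm\n\nCoefficients:\n", x$sigma))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) object$theta

#' @export
residuals.titration_fit <- function(object, ...) object$residuals

#' @export
vcov.titration_fit <- function(object, ...) object$covariance

#' @export
fitted.titration_fit <- function(object, ...) object$fitted

#' Predicted shift traces from a fitted titration model
#'
#' @param object A `titration_fit`.
#' @param newdata Optional: a [titration_series()] with the same nuclei, or
#'   a numeric vector of titrant equivalents at the fitted fixed-species
#'   concentration. Defaults to the fitted series.
#' @param ... Unused.
#' @return Named list of predicted shift vectors (ppm) per nucleus.
#' @export
predict.titration_fit <- function(object, newdata = NULL, ...) {
  s <- object$series
  if (is.null(newdata)) return(object$fitted)
  if (is.numeric(newdata)) {
    eq <- sort(unique(as.numeric(newdata)))
    newdata <- titration_series(
      s$fixed_species_total, eq,
      nuclei = stats::setNames(rep(list(rep(0, length(eq))), length(s$nuclei)),
                               names(s$nuclei)),
      sample_id = s$sample_id)
  }
  predict_shifts(object$model, object$shifts, newdata)
}

#' @export
plot.titration_fit <- function(x, ...) {
  s <- x$series
  eq_dense <- seq(min(s$equivalents), max(s$equivalents), length.out = 200)
  if (eq_dense[1] == eq_dense[length(eq_dense)]) eq_dense <- s$equivalents
  pred <- predict(x, newdata = eq_dense)
  old <- graphics::par(mfrow = c(1, length(s$nuclei)))
  on.exit(graphics::par(old))
  for (nm in names(s$nuclei)) {
    graphics::plot(s$equivalents, s$nuclei[[nm]], xlab = "equivalents",
                   ylab = expression(delta[obs] ~ "(ppm)"), main = nm, ...)
    graphics::lines(sort(unique(eq_dense)), pred[[nm]], col = "firebrick")
  }
  invisible(x)
}

#' Simulate replicate titration series from a fitted model
#'
#' Draws `nsim` new series at the fitted design with Gaussian shift noise
#' (default: the residual standard deviation).
#'
#' @param object A `titration_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param noise_sd Shift noise (ppm); default residual sd.
#' @param ... Unused.
#' @return List of [titration_series()].
#' @export
simulate.titration_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd))
    noise_sd <- sqrt(object$rss /
                       max(object$n_points - object$n_params, 1))
  s <- object$series
  truth <- predict_shifts(object$model, object$shifts, s)
  lapply(seq_len(nsim), function(i) {
    nuc <- lapply(truth, function(tr) tr + stats::rnorm(length(tr), 0, noise_sd))
    titration_series(s$fixed_species_total, s$equivalents, nuc,
                     titrant_total = s$titrant_total,
                     replicate_id = paste0("sim", i), sample_id = s$sample_id)
  })
}
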