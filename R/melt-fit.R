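#' Fit an asymmetric sigmoid to a CD melting curve
#'
#' Least-squares fit of the five-parameter logistic
#' `y(T) = A_unfolded + (A_folded - A_unfolded) / (1 + exp((T - T_half) / width))^s`
#' with `width > 0` and asymmetry exponent `s > 0` (both log-parametrized
#' internally, so a negative width can never be reported). `A_folded` is the
#' low-temperature plateau. The melting temperature is defined as the
#' temperature at which half of the structure has denatured, i.e. the
#' solution of `y(Tm) = (A_folded + A_unfolded) / 2`, located by bracketed
#' root-finding within the data range; for `s = 1` this coincides with
#' `T_half`. Its standard error follows by the delta method from the
#' parameter covariance.
#'
#' With `baseline = "linear"` the plateaus become linear pre- and
#' post-transition baselines `A_folded + m_f T` and `A_unfolded + m_u T`,
#' and Tm solves the half-signal equation against the local baseline mean.
#'
#' @param curve A [melt_curve()] or a data frame with columns
#'   `temperature_C` and `ellipticity_mdeg`.
#' @param orientation `"folded_high"` if the folded state carries the
#'   higher ellipticity at the monitored wavelength (the parallel-G4 260 nm
#'   band), `"folded_low"` otherwise.
#' @param baseline `"constant"` (default) or `"linear"`.
#' @param min_amplitude Minimum ellipticity excursion (mdeg) for a
#'   transition to count as visible; below it a
#'   `"transition-out-of-range"` error is raised. Default 1 mdeg.
#' @return An object of class `"melt_fit"` with components `A_folded`,
#'   `A_unfolded`, `T_half`, `width`, `s`, `Tm`, `Tm_se`, `rss`, baseline
#'   slopes (`m_folded`, `m_unfolded`, zero for constant baselines),
#'   `fitted`, `residuals`, `vcov`, and the input `curve`.
#' @examples
#' d <- gen_melt(melt_design(T_half = 40, seed = 1))
#' fit_melt(d)
#' @export
fit_melt <- function(curve, orientation = c("folded_high", "folded_low"),
                     baseline = c("constant", "linear"),
                     min_amplitude = 1) {
  orientation <- match.arg(orientation)
  baseline <- match.arg(baseline)
  if (is.data.frame(curve))
    curve <- melt_curve(curve$temperature_C, curve$ellipticity_mdeg)
  if (!inherits(curve, "melt_curve"))
    stop("'curve' must be a melt_curve or a data frame", call. = FALSE)
  Tv <- curve$temperatures; y <- curve$ellipticity
  if (diff(range(y)) <= min_amplitude)
    stop_transition("no visible transition: ellipticity excursion below min_amplitude")

  n_edge <- max(3L, ceiling(length(Tv) * 0.05))
  Af0 <- mean(y[seq_len(n_edge)])
  Au0 <- mean(y[seq(length(y) - n_edge + 1L, length(y))])
  if ((orientation == "folded_high") != (Af0 >= Au0))
    warning("plateau order contradicts 'orientation'; fitting the data as observed")
  mid0 <- (Af0 + Au0) / 2
  i_mid <- which.min(abs(y - mid0))
  Th0 <- Tv[i_mid]
  w0 <- max(diff(range(Tv)) / 20, 0.5)

  df <- data.frame(T = Tv, y = y)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14)
  # symbolic gradients: numeric differencing degenerates when a plateau
  # parameter sits near zero relative to the signal scale
  if (baseline == "constant") {
    fit <- minpack.lm::nlsLM(
      y ~ sigmoid5_const(Af, Au, Th, lw, ls, T),
      data = df,
      start = list(Af = Af0, Au = Au0, Th = Th0, lw = log(w0), ls = 0),
      control = ctrl)
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ sigmoid5_linear(Af, Au, mf, mu, Th, lw, ls, T),
      data = df,
      start = list(Af = Af0, Au = Au0, mf = 0, mu = 0, Th = Th0,
                   lw = log(w0), ls = 0),
      control = ctrl)
  }
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, length(cf), length(cf),
           dimnames = list(names(cf), names(cf))))
  pars <- list(Af = cf[["Af"]], Au = cf[["Au"]],
               mf = if ("mf" %in% names(cf)) cf[["mf"]] else 0,
               mu = if ("mu" %in% names(cf)) cf[["mu"]] else 0,
               Th = cf[["Th"]], w = exp(cf[["lw"]]), s = exp(cf[["ls"]]))

  tm <- melt_tm_root(pars, range(Tv))
  if (is.null(tm))
    stop_transition("transition-out-of-range: half-denaturation point not bracketed by the data")

  # delta method on the half-signal root
  grad <- vapply(seq_along(cf), function(k) {
    hk <- max(1e-6, abs(cf[k]) * 1e-6)
    cp <- cf; cp[k] <- cp[k] + hk
    cm <- cf; cm[k] <- cm[k] - hk
    tp <- melt_tm_root(coef_to_pars(cp), range(Tv), extend = TRUE)
    tn <- melt_tm_root(coef_to_pars(cm), range(Tv), extend = TRUE)
    if (is.null(tp) || is.null(tn)) return(NA_real_)
    (tp - tn) / (2 * hk)
  }, numeric(1))
  tm_se <- if (any(is.na(grad)) || anyNA(vc)) NA_real_ else
    sqrt(max(drop(t(grad) %*% vc %*% grad), 0))

  res <- stats::resid(fit)
  structure(list(
    A_folded = pars$Af, A_unfolded = pars$Au,
    m_folded = pars$mf, m_unfolded = pars$mu,
    T_half = pars$Th, width = pars$w, s = pars$s,
    Tm = tm, Tm_se = tm_se, rss = sum(res^2),
    coefficients = cf, vcov = vc, baseline = baseline,
    orientation = orientation,
    fitted = as.numeric(stats::fitted(fit)), residuals = as.numeric(res),
    curve = curve), class = "melt_fit")
}

sigmoid5_const <- stats::deriv(
  ~ Au + (Af - Au) / (1 + exp((T - Th) / exp(lw)))^exp(ls),
  c("Af", "Au", "Th", "lw", "ls"),
  function.arg = c("Af", "Au", "Th", "lw", "ls", "T"))

sigmoid5_linear <- stats::deriv(
  ~ (Au + mu * T) + ((Af + mf * T) - (Au + mu * T)) /
    (1 + exp((T - Th) / exp(lw)))^exp(ls),
  c("Af", "Au", "mf", "mu", "Th", "lw", "ls"),
  function.arg = c("Af", "Au", "mf", "mu", "Th", "lw", "ls", "T"))

stop_transition <- function(msg) {
  stop(structure(class = c("quadbind_transition_error", "quadbind_fit_error",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

coef_to_pars <- function(cf) {
  list(Af = cf[["Af"]], Au = cf[["Au"]],
       mf = if ("mf" %in% names(cf)) cf[["mf"]] else 0,
       mu = if ("mu" %in% names(cf)) cf[["mu"]] else 0,
       Th = cf[["Th"]], w = exp(cf[["lw"]]), s = exp(cf[["ls"]]))
}

melt_value <- function(pars, T) {
  folded <- pars$Af + pars$mf * T
  unfolded <- pars$Au + pars$mu * T
  unfolded + (folded - unfolded) / (1 + exp((T - pars$Th) / pars$w))^pars$s
}

# Tm from y(Tm) = midpoint of the (local) baselines, bracketed root within
# the temperature range; NULL when not bracketed. `extend` widens the
# bracket slightly (used only for delta-method differencing near the edge).
melt_tm_root <- function(pars, trange, extend = FALSE) {
  if (extend) trange <- trange + c(-5, 5) * pars$w
  f <- function(T) {
    mid <- (pars$Af + pars$mf * T + pars$Au + pars$mu * T) / 2
    melt_value(pars, T) - mid
  }
  lo <- f(trange[1]); hi <- f(trange[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) return(NULL)
  stats::uniroot(f, trange, f.lower = lo, f.upper = hi, tol = 1e-10)$root
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Melt fit '%s' (%s):\n", x$curve$sample_id,
              x$curve$condition_label))
  cat(sprintf("  Tm = %.2f +/- %.2f degC  (T_half = %.2f, width = %.2f, s = %.3f)\n",
              x$Tm, x$Tm_se, x$T_half, x$width, x$s))
  cat(sprintf("  plateaus: folded %.2f, unfolded %.2f mdeg; rss = %.4g mdeg^2\n",
              x$A_folded, x$A_unfolded, x$rss))
  invisible(x)
}

#' @export
summary.melt_fit <- function(object, ...) {
  n <- length(object$fitted); p <- length(object$coefficients)
  structure(list(fit = object,
                 sigma = sqrt(object$rss / max(n - p, 1)),
                 n = n, p = p), class = "summary.melt_fit")
}

#' @export
print.summary.melt_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d points, %d parameters, residual sd %.3g mdeg\n",
              x$n, x$p, x$sigma))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(A_folded = object$A_folded, A_unfolded = object$A_unfolded,
    T_half = object$T_half, width = object$width, s = object$s)
}

#' @export
residuals.melt_fit <- function(object, ...) object$residuals

#' @export
fitted.melt_fit <- function(object, ...) object$fitted

#' @export
vcov.melt_fit <- function(object, ...) object$vcov

#' Predicted ellipticity from a fitted melt model
#' @param object A `melt_fit`.
#' @param newdata Optional numeric temperatures (degC) or data frame with
#'   `temperature_C`; defaults to the fitted temperatures.
#' @param ... Unused.
#' @return Numeric vector of ellipticities (mdeg).
#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  Tn <- if (is.data.frame(newdata)) newdata$temperature_C else
    as.numeric(newdata)
  melt_value(coef_to_pars(object$coefficients), Tn)
}

#' @export
plot.melt_fit <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$temperatures, cv$ellipticity, cex = 0.4,
                 xlab = "temperature (degC)", ylab = "ellipticity (mdeg)",
                 main = sprintf("%s (%s)", cv$sample_id, cv$condition_label),
                 ...)
  Td <- seq(min(cv$temperatures), max(cv$temperatures), length.out = 400)
  graphics::lines(Td, predict(x, Td), col = "firebrick", lwd = 2)
  graphics::abline(v = x$Tm, lty = 2)
  invisible(x)
}

#' Simulate replicate melt curves from a fitted model
#' @param object A `melt_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param noise_sd Ellipticity noise (mdeg); default residual sd.
#' @param ... Unused.
#' @return List of [melt_curve()].
#' @export
simulate.melt_fit <- function(object, nsim = 1, seed = NULL,
                              noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd))
    noise_sd <- sqrt(object$rss /
                       max(length(object$fitted) -
                             length(object$coefficients), 1))
  cv <- object$curve
  truth <- predict(object, cv$temperatures)
  lapply(seq_len(nsim), function(i)
    melt_curve(cv$temperatures,
               truth + stats::rnorm(length(truth), 0, noise_sd),
               monitor_wavelength = cv$monitor_wavelength,
               sample_id = cv$sample_id,
               condition_label = paste0(cv$condition_label, "_sim", i)))
}

#' Fraction of folded structure from an ellipticity value
#'
#' Linear normalization of a CD signal against a fully-folded reference and
#' a fully-unfolded baseline:
#' `(value - reference_unfolded) / (reference_folded - reference_unfolded)`.
#' Values slightly outside \[0, 1\] are reported as-is, not clipped.
#'
#' @param value Ellipticity value(s) (mdeg).
#' @param reference_folded Ellipticity of the 100 percent folded reference.
#' @param reference_unfolded Ellipticity of the fully unfolded state.
#' @return Numeric fraction(s) folded.
#' @examples
#' fraction_folded(-5, reference_folded = -10, reference_unfolded = 0)
#' @export
fraction_folded <- function(value, reference_folded, reference_unfolded) {
  if (!is.finite(reference_folded) || !is.finite(reference_unfolded) ||
      reference_folded == reference_unfolded)
    stop("reference_folded and reference_unfolded must differ", call. = FALSE)
  (value - reference_unfolded) / (reference_folded - reference_unfolded)
}
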