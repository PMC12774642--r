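#' Gas constant, J/(mol K)
#' @noRd
R_GAS <- 8.314

#' Binding free energy from an association constant
#'
#' `delta_G = -R T ln(K)`, reported in kJ/mol with R = 8.314 J/(mol K).
#' 25 degC corresponds to the default `temperature = 298.15` K.
#'
#' @param K Association constant (per molar, > 0).
#' @param temperature Absolute temperature (K, > 0).
#' @return A list of class `"thermo_result"`: `delta_G` (kJ/mol),
#'   `temperature` (K), `K_used` (per molar), `gas_constant`.
#' @examples
#' free_energy(exp(1))$delta_G  # -R*T/1000 = -2.479 kJ/mol
#' @export
free_energy <- function(K, temperature = 298.15) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("'K' must be a single finite positive association constant",
         call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be a single positive absolute temperature (K)",
         call. = FALSE)
  structure(list(delta_G = -R_GAS * temperature * log(K) / 1000,
                 temperature = temperature, K_used = K,
                 gas_constant = R_GAS), class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("delta G = %.1f kJ/mol  (K = %.4g M^-1 at %.2f K)\n",
              x$delta_G, x$K_used, x$temperature))
  invisible(x)
}

#' Binding selectivity between two association constants
#'
#' Reports the fold-selectivity `ratio = K_a / K_b` and the free-energy
#' difference `delta_delta_G = -R T ln(ratio)` in kJ/mol. A more negative
#' value means `K_a > K_b` (binding to `a` preferred).
#'
#' @param K_a,K_b Association constants (per molar, > 0).
#' @param temperature Absolute temperature (K, > 0).
#' @return A list of class `"selectivity_result"`: `ratio`,
#'   `delta_delta_G` (kJ/mol), `temperature`.
#' @examples
#' selectivity(50, 1)$delta_delta_G  # -9.70 kJ/mol at 298.15 K
#' @export
selectivity <- function(K_a, K_b, temperature = 298.15) {
  for (nm in c("K_a", "K_b")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite positive constant", nm),
           call. = FALSE)
  }
  ratio <- K_a / K_b
  structure(list(ratio = ratio,
                 delta_delta_G = -R_GAS * temperature * log(ratio) / 1000,
                 temperature = temperature), class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("%.3g-fold selectivity: delta delta G = %.1f kJ/mol at %.2f K\n",
              x$ratio, x$delta_delta_G, x$temperature))
  invisible(x)
}

#' Titrant equivalents needed to reach a target saturation
#'
#' Inverts the saturation curve: finds the smallest equivalents `e` at
#' which the receptor site occupancy reaches `target_fraction`, by
#' bisection on the monotone occupancy-vs-equivalents relation (the design
#' calculation behind choosing, e.g., a 16-equivalent excess for a weak
#' binder). If the occupancy asymptote at `max_equivalents` still falls
#' short, an `"unreachable"` error is raised.
#'
#' @param model A [binding_model()] with at least one positive constant.
#' @param receptor_total Total receptor concentration (molar, > 0).
#' @param target_fraction Target site occupancy in (0, 1).
#' @param max_equivalents Search cap (default 1e4).
#' @param tol Bisection tolerance on equivalents (default 1e-6).
#' @return Equivalents (dimensionless scalar).
#' @examples
#' design_saturation(statistical_from_micro(5e4), 20e-6, 0.5)
#' @export
design_saturation <- function(model, receptor_total, target_fraction,
                              max_equivalents = 1e4, tol = 1e-6) {
  assert_binding_model(model)
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction >= 1)
    stop("'target_fraction' must lie strictly between 0 and 1",
         call. = FALSE)
  if (receptor_total <= 0)
    stop("'receptor_total' must be positive", call. = FALSE)
  occ <- function(e)
    solve_speciation(model, receptor_total,
                     e * receptor_total)$site_occupancy
  if (model$K1 <= 0 || occ(max_equivalents) < target_fraction)
    stop(structure(class = c("quadbind_unreachable_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "target saturation %.3g unreachable within %g equivalents",
                     target_fraction, max_equivalents), call = NULL)))
  lo <- 0; hi <- max_equivalents
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (occ(mid) >= target_fraction) hi <- mid else lo <- mid
  }
  hi
}
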