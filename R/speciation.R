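#' Equilibrium speciation of a host-guest mixture
#'
#' Solves the mass-action system R + L <-> RL (K1), RL + L <-> RL2 (K2) for
#' the physically admissible species distribution at given total
#' concentrations. For the 1:1 model the quadratic closed form is used; for
#' 2:1 models the free-ligand concentration `p` is the unique root of the
#' strictly increasing scalar mass balance
#' `h(p) = p + R_t (K1 p + 2 K1 K2 p^2) / (1 + K1 p + K1 K2 p^2) - L_t`
#' on `[0, L_t]`, located by a bracketed safeguarded solver and polished by
#' damped Newton steps to machine precision.
#'
#' "Receptor" is the single-copy species (the nucleic-acid strand) and
#' "ligand" the species that can bind twice (the peptide), independent of
#' which one an experiment titrates. All concentrations are mol/L and all
#' constants per molar.
#'
#' @param model A [binding_model()].
#' @param receptor_total Total receptor concentration (molar, >= 0).
#' @param ligand_total Total ligand concentration (molar, >= 0).
#'
#' @return An object of class `"speciation"`: a list with elements
#'   `free_receptor`, `free_ligand`, `complex_RL`, `complex_RL2` (molar),
#'   `site_occupancy` (fraction of receptor sites filled, in \[0, 1\]),
#'   `ligand_bound_fraction` (fraction of total ligand complexed), and the
#'   echoed totals. Mass balance holds to better than 1e-10 relative.
#' @examples
#' m <- statistical_from_micro(5e3)
#' solve_speciation(m, receptor_total = 62.5e-6, ligand_total = 125e-6)
#' @export
solve_speciation <- function(model, receptor_total, ligand_total) {
  assert_binding_model(model)
  if (!is.numeric(receptor_total) || length(receptor_total) != 1L ||
      !is.finite(receptor_total) || receptor_total < 0)
    stop("'receptor_total' must be a single finite non-negative molar value",
         call. = FALSE)
  if (!is.numeric(ligand_total) || length(ligand_total) != 1L ||
      !is.finite(ligand_total) || ligand_total < 0)
    stop("'ligand_total' must be a single finite non-negative molar value",
         call. = FALSE)

  Rt <- receptor_total; Lt <- ligand_total
  one_site <- model$model_id == "1:1"
  K1 <- model$K1
  K2 <- if (one_site) 0 else model$K2

  p <- free_ligand_root(K1, K2, Rt, Lt, one_site)

  denom <- 1 + K1 * p + if (one_site) 0 else K1 * K2 * p^2
  Rfree <- Rt / denom
  RL <- K1 * p * Rfree
  RL2 <- if (one_site) 0 else K1 * K2 * p^2 * Rfree

  n_sites <- if (one_site) 1 else 2
  occ <- if (Rt > 0) (RL + 2 * RL2) / (n_sites * Rt) else 0
  lbf <- if (Lt > 0) (RL + 2 * RL2) / Lt else 0

  structure(list(
    free_receptor = Rfree, free_ligand = p,
    complex_RL = RL, complex_RL2 = RL2,
    site_occupancy = occ, ligand_bound_fraction = lbf,
    receptor_total = Rt, ligand_total = Lt,
    model_id = model$model_id), class = "speciation")
}

#' @export
print.speciation <- function(x, ...) {
  cat(sprintf("Speciation (%s): R_t = %.4g M, L_t = %.4g M\n",
              x$model_id, x$receptor_total, x$ligand_total))
  cat(sprintf("  [R] = %.6g  [L] = %.6g  [RL] = %.6g  [RL2] = %.6g M\n",
              x$free_receptor, x$free_ligand, x$complex_RL, x$complex_RL2))
  cat(sprintf("  site occupancy = %.4f   ligand bound fraction = %.4f\n",
              x$site_occupancy, x$ligand_bound_fraction))
  invisible(x)
}

# Free-ligand concentration for the mass-action system. Closed-form
# quadratic for 1:1; bracketed Brent + damped Newton polish for 2:1.
free_ligand_root <- function(K1, K2, Rt, Lt, one_site) {
  if (Lt == 0) return(0)
  if (Rt == 0 || K1 == 0) return(Lt)  # K1 = 0 blocks both binding steps

  if (one_site) {
    # K p^2 + (1 + K (Rt - Lt)) p - Lt = 0, positive root, stable form
    K <- K1
    b <- 1 + K * (Rt - Lt)
    disc <- sqrt(b * b + 4 * K * Lt)
    p <- if (b >= 0) 2 * Lt / (b + disc) else (disc - b) / (2 * K)
    return(min(p, Lt))
  }

  h <- function(p) {
    d <- 1 + K1 * p + K1 * K2 * p^2
    p + Rt * (K1 * p + 2 * K1 * K2 * p^2) / d - Lt
  }
  # h(0) = -Lt < 0, h(Lt) >= 0: valid bracket, h strictly increasing
  hi <- h(Lt)
  if (hi < 0) stop("internal invariant violated: mass balance not bracketed")
  p <- stats::uniroot(h, c(0, Lt), tol = 1e-3 * .Machine$double.eps * Lt,
                      f.lower = -Lt, f.upper = hi)$root

  # Newton polish (h' >= 1 everywhere, so steps are well-behaved)
  hprime <- function(p) {
    d <- 1 + K1 * p + K1 * K2 * p^2
    num <- K1 * p + 2 * K1 * K2 * p^2
    dnum <- K1 + 4 * K1 * K2 * p
    dd <- K1 + 2 * K1 * K2 * p
    1 + Rt * (dnum * d - num * dd) / d^2
  }
  for (i in 1:4) {
    step <- h(p) / hprime(p)
    pn <- p - step
    if (pn < 0) pn <- p / 2
    if (pn > Lt) pn <- (p + Lt) / 2
    if (!is.finite(pn) || abs(pn - p) <= .Machine$double.eps * p) { p <- pn; break }
    p <- pn
  }
  p
}

#' Simulated saturation curve over a titrant-equivalents grid
#'
#' For each equivalents ratio `e` in the grid, solves speciation at
#' `ligand_total = e * receptor_total` and reports the receptor site
#' occupancy and the fraction of ligand bound. Site occupancy is
#' non-decreasing in `e`.
#'
#' @param model A [binding_model()].
#' @param receptor_total Total receptor concentration (molar).
#' @param equivalents Numeric vector of ligand:receptor equivalents (>= 0).
#' @return A data frame with columns `equivalents`, `ligand_total`,
#'   `site_occupancy`, `ligand_bound_fraction`.
#' @examples
#' saturation_curve(statistical_from_micro(5e3), 20e-6, c(1, 2, 4, 8, 16))
#' @export
saturation_curve <- function(model, receptor_total, equivalents) {
  assert_binding_model(model)
  if (any(!is.finite(equivalents)) || any(equivalents < 0))
    stop("'equivalents' must be finite and non-negative", call. = FALSE)
  res <- lapply(equivalents, function(e)
    solve_speciation(model, receptor_total, e * receptor_total))
  data.frame(
    equivalents = equivalents,
    ligand_total = equivalents * receptor_total,
    site_occupancy = vapply(res, `[[`, numeric(1), "site_occupancy"),
    ligand_bound_fraction = vapply(res, `[[`, numeric(1),
                                   "ligand_bound_fraction"))
}
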