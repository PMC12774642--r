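#' Specify a host-guest binding model
#'
#' Constructs the stoichiometry-plus-constants description used throughout
#' the package. Three models are supported: a single 1:1 equilibrium
#' (`"1:1"`), a full stepwise 2:1 ligand:receptor model (`"2:1-full"`) with
#' independent stepwise constants `K1` and `K2`, and the non-cooperative
#' statistical 2:1 model (`"2:1-statistical"`) in which both binding sites
#' are equivalent and independent so that `K1 = 2 * k_micro` and
#' `K2 = k_micro / 2` (statistical factors for two sites).
#'
#' The cooperativity index `alpha = 4 * K2 / K1` is derived, never set:
#' `alpha = 1` identifies the purely statistical (non-cooperative) case.
#'
#' @param model One of `"1:1"`, `"2:1-full"`, `"2:1-statistical"`.
#' @param K1 Stepwise association constant for the first binding event
#'   (per molar). For the statistical model supply `k_micro` instead.
#' @param K2 Stepwise association constant for the second binding event
#'   (per molar); required for `"2:1-full"`, forbidden otherwise.
#' @param k_micro Microscopic per-site association constant (per molar);
#'   only for `"2:1-statistical"`.
#'
#' @return An object of class `"binding_model"`: a list with elements
#'   `model_id`, `K1`, `K2`, `k_micro` and `alpha`.
#' @seealso [statistical_from_micro()], [solve_speciation()]
#' @examples
#' binding_model("1:1", K1 = 1e4)
#' binding_model("2:1-full", K1 = 2000, K2 = 500)
#' statistical_from_micro(5e3)
#' @export
binding_model <- function(model = c("1:1", "2:1-full", "2:1-statistical"),
                          K1 = NULL, K2 = NULL, k_micro = NULL) {
  model <- match.arg(model)
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      stop(sprintf("'%s' must be a single finite non-negative number", nm),
           call. = FALSE)
    as.numeric(x)
  }
  if (model == "2:1-statistical") {
    if (is.null(k_micro))
      stop("the statistical 2:1 model requires 'k_micro'", call. = FALSE)
    if (!is.null(K1) || !is.null(K2))
      stop("supply only 'k_micro' for the statistical model; K1 and K2 are derived",
           call. = FALSE)
    k <- chk(k_micro, "k_micro")
    out <- list(model_id = model, K1 = 2 * k, K2 = k / 2, k_micro = k,
                alpha = 1)
  } else if (model == "2:1-full") {
    if (is.null(K1) || is.null(K2))
      stop("the full 2:1 model requires both 'K1' and 'K2'", call. = FALSE)
    K1 <- chk(K1, "K1"); K2 <- chk(K2, "K2")
    out <- list(model_id = model, K1 = K1, K2 = K2, k_micro = NA_real_,
                alpha = if (K1 > 0) 4 * K2 / K1 else NA_real_)
  } else {
    if (is.null(K1))
      stop("the 1:1 model requires 'K1'", call. = FALSE)
    if (!is.null(K2))
      stop("'K2' has no meaning for a 1:1 model", call. = FALSE)
    out <- list(model_id = model, K1 = chk(K1, "K1"), K2 = NA_real_,
                k_micro = NA_real_, alpha = NA_real_)
  }
  structure(out, class = "binding_model")
}

#' Statistical 2:1 model from a microscopic per-site constant
#'
#' Two equivalent, independent sites on one receptor give stepwise constants
#' `K1 = 2 * k_micro` and `K2 = k_micro / 2`, hence `K1 / K2 = 4` and a
#' cooperativity index of exactly 1.
#'
#' @param k_micro Microscopic per-site association constant (per molar).
#' @return A `"binding_model"` with `model_id = "2:1-statistical"`.
#' @examples
#' m <- statistical_from_micro(1000)
#' m$K1 / m$K2  # 4
#' @export
statistical_from_micro <- function(k_micro) {
  binding_model("2:1-statistical", k_micro = k_micro)
}

#' @export
print.binding_model <- function(x, ...) {
  cat("Binding model:", x$model_id, "\n")
  if (x$model_id == "1:1") {
    cat(sprintf("  K  = %.6g M^-1\n", x$K1))
  } else {
    cat(sprintf("  K1 = %.6g M^-1\n  K2 = %.6g M^-1\n", x$K1, x$K2))
    if (!is.na(x$k_micro))
      cat(sprintf("  k (per site) = %.6g M^-1\n", x$k_micro))
    if (!is.na(x$alpha))
      cat(sprintf("  alpha (4*K2/K1) = %.4g\n", x$alpha))
  }
  invisible(x)
}

is_binding_model <- function(x) inherits(x, "binding_model")

assert_binding_model <- function(x) {
  if (!is_binding_model(x))
    stop("expected a 'binding_model' object; see binding_model()",
         call. = FALSE)
  invisible(x)
}

#' Number of free equilibrium constants in a binding model
#' @noRd
n_constants <- function(model_id) {
  switch(model_id, "1:1" = 1L, "2:1-statistical" = 1L, "2:1-full" = 2L,
         stop("unknown model_id: ", model_id))
}
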