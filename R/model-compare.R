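#' Compare candidate binding models on one titration series
#'
#' Fits each candidate stoichiometry model with [fit_titration()] and ranks
#' them by AICc (ascending). Candidates whose AICc lies within 2 of the
#' best are treated as statistically indistinguishable and the tie is
#' broken in favour of the fewest parameters — the parsimony rule that
#' prefers the simplest adequate stoichiometry. Per-candidate fit failures
#' are recorded, not fatal.
#'
#' @param series A [titration_series()].
#' @param candidates Character vector of model identifiers (>= 1); the
#'   default compares all three supported stoichiometries.
#' @param ... Passed to [fit_titration()].
#' @return An object of class `"binding_model_comparison"`: list with
#'   `fits` (named list, `NULL` where a fit failed), `errors`, and `table`
#'   (a data frame with `model`, `n_params`, `rss`, `aicc`, `delta_aicc`,
#'   `rank`, ordered by rank).
#' @export
compare_binding_models <- function(series,
                                   candidates = c("1:1", "2:1-statistical",
                                                  "2:1-full"),
                                   ...) {
  if (length(candidates) < 1L) stop("need at least one candidate model")
  candidates <- unique(candidates)
  fits <- vector("list", length(candidates)); names(fits) <- candidates
  errors <- character(0)
  for (cand in candidates) {
    fits[[cand]] <- tryCatch(fit_titration(series, model = cand, ...),
                             error = function(e) {
                               errors[[cand]] <<- conditionMessage(e)
                               NULL
                             })
  }
  ok <- !vapply(fits, is.null, logical(1))
  tab <- data.frame(
    model = candidates,
    n_params = vapply(fits, function(f) if (is.null(f)) NA_integer_ else f$n_params, integer(1)),
    rss = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$rss, numeric(1)),
    aicc = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aicc, numeric(1)),
    row.names = NULL)
  tab$delta_aicc <- tab$aicc - min(tab$aicc, na.rm = TRUE)
  # rank: AICc ascending; within 2 of the best, fewest parameters first
  near <- !is.na(tab$delta_aicc) & tab$delta_aicc < 2
  key <- ifelse(near, 0, tab$delta_aicc)  # group the near-ties at the top
  ord <- order(is.na(tab$aicc), key,
               ifelse(near, tab$n_params, 0L),
               tab$aicc)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(fits = fits, errors = errors, table = tab),
            class = "binding_model_comparison")
}

#' @export
print.binding_model_comparison <- function(x, ...) {
  cat("Binding model comparison (AICc ranking, parsimony tie-break):\n")
  print(x$table, digits = 5)
  if (length(x$errors))
    cat("Failed candidates:",
        paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Best model of a comparison
#' @param x A `binding_model_comparison`.
#' @return The rank-1 `titration_fit`.
#' @export
best_fit <- function(x) {
  stopifnot(inherits(x, "binding_model_comparison"))
  x$fits[[x$table$model[1L]]]
}

#' Inverse-variance weighted average of replicate association constants
#'
#' Combines the headline constants of replicate titration fits (all of the
#' same stoichiometry model) as `K_bar = sum(K_i / se_i^2) / sum(1 / se_i^2)`
#' with propagated standard error `1 / sqrt(sum(1 / se_i^2))` — the
#' standard fixed-effect weighting. A single fit is returned unchanged.
#'
#' @param fits A list of `titration_fit` objects sharing one `model_id`.
#' @return Named list `K` (per molar), `se` (per molar), `n` (replicates).
#' @export
average_constants <- function(fits) {
  if (inherits(fits, "titration_fit")) fits <- list(fits)
  if (length(fits) < 1L) stop("need at least one fit", call. = FALSE)
  ids <- vapply(fits, function(f) f$model$model_id, character(1))
  if (length(unique(ids)) != 1L)
    stop("all fits must share the same stoichiometry model; got: ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  pcs <- lapply(fits, primary_constant)
  K <- vapply(pcs, `[[`, numeric(1), "K")
  se <- vapply(pcs, `[[`, numeric(1), "se")
  if (length(fits) == 1L) return(list(K = K, se = se, n = 1L))
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all fits need finite positive standard errors for weighting",
         call. = FALSE)
  w <- 1 / se^2
  list(K = sum(w * K) / sum(w), se = 1 / sqrt(sum(w)), n = length(fits))
}
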