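#' NMR titration series container
#'
#' Holds one titration experiment: a constant concentration of the observed
#' species (the peptide, e.g. 125 uM) titrated with increasing equivalents
#' of the binding partner (the folded nucleic acid), with one observed
#' chemical-shift trace per monitored nucleus under fast exchange.
#'
#' @param fixed_species_total Concentration of the observed, constant
#'   species (molar, > 0).
#' @param equivalents Strictly increasing non-negative titrant equivalents,
#'   starting typically at 0.
#' @param nuclei A named list of numeric shift traces (ppm), one per
#'   nucleus, each the same length as `equivalents`; or a single numeric
#'   vector (taken as one unnamed nucleus).
#' @param titrant_total Optional titrant concentrations (molar). Defaults to
#'   `equivalents * fixed_species_total`.
#' @param temperature Temperature in degrees C (metadata only).
#' @param replicate_id,sample_id Labels carried through fitting and output.
#'
#' @return An object of class `"titration_series"`.
#' @examples
#' titration_series(125e-6, equivalents = seq(0, 2, length.out = 12),
#'                  nuclei = list(PheH = rep(7.3, 12)))
#' @export
titration_series <- function(fixed_species_total, equivalents, nuclei,
                             titrant_total = NULL, temperature = 25,
                             replicate_id = "r1", sample_id = "sample") {
  if (!is.numeric(fixed_species_total) || length(fixed_species_total) != 1L ||
      !is.finite(fixed_species_total) || fixed_species_total <= 0)
    stop("'fixed_species_total' must be a single positive molar value",
         call. = FALSE)
  equivalents <- as.numeric(equivalents)
  if (any(!is.finite(equivalents)) || any(equivalents < 0))
    stop("'equivalents' must be finite and non-negative", call. = FALSE)
  if (any(diff(equivalents) <= 0))
    stop("'equivalents' must be strictly increasing", call. = FALSE)
  if (is.null(titrant_total)) {
    titrant_total <- equivalents * fixed_species_total
  } else {
    titrant_total <- as.numeric(titrant_total)
    if (length(titrant_total) != length(equivalents))
      stop("'titrant_total' must match 'equivalents' in length", call. = FALSE)
  }
  if (is.numeric(nuclei)) nuclei <- list(nucleus_1 = nuclei)
  if (!is.list(nuclei) || length(nuclei) == 0L)
    stop("'nuclei' must be a non-empty list of shift traces", call. = FALSE)
  if (is.null(names(nuclei)) || any(!nzchar(names(nuclei))))
    names(nuclei) <- paste0("nucleus_", seq_along(nuclei))
  for (nm in names(nuclei)) {
    tr <- as.numeric(nuclei[[nm]])
    if (length(tr) != length(equivalents) || any(!is.finite(tr)))
      stop(sprintf("trace '%s' must be finite with one shift per point", nm),
           call. = FALSE)
    nuclei[[nm]] <- tr
  }
  structure(list(
    fixed_species_total = fixed_species_total,
    equivalents = equivalents,
    titrant_total = titrant_total,
    nuclei = nuclei,
    temperature = temperature,
    replicate_id = replicate_id,
    sample_id = sample_id), class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series '%s' (replicate %s): %d points, %d nucle%s\n",
              x$sample_id, x$replicate_id, length(x$equivalents),
              length(x$nuclei), if (length(x$nuclei) == 1) "us" else "i"))
  cat(sprintf("  fixed species %.4g M, titrant %.3g-%.3g equivalents\n",
              x$fixed_species_total, min(x$equivalents), max(x$equivalents)))
  invisible(x)
}

#' Read titration series from CSV
#'
#' Expects columns `sample_id`, `replicate_id`, `equivalents`, `nucleus_id`,
#' `delta_ppm` and either a `fixed_species_total_M` column or the
#' `fixed_species_total` argument; an optional `titrant_total_M` column
#' overrides the equivalents-derived titrant concentration. Decimal point,
#' comma separator, UTF-8, header required.
#'
#' @param path CSV file path.
#' @param fixed_species_total Constant concentration of the observed species
#'   (molar); used when the file has no `fixed_species_total_M` column.
#' @return A list of [titration_series()], one per
#'   `sample_id` x `replicate_id` combination.
#' @export
read_titration_csv <- function(path, fixed_species_total = NULL) {
  df <- read_schema_csv(path, c("sample_id", "replicate_id", "equivalents",
                                "nucleus_id", "delta_ppm"))
  has_conc_col <- "fixed_species_total_M" %in% names(df)
  if (!has_conc_col && is.null(fixed_species_total))
    stop_schema(path, "need a 'fixed_species_total_M' column or the 'fixed_species_total' argument")
  key <- interaction(df$sample_id, df$replicate_id, drop = TRUE)
  lapply(split(df, key), function(d) {
    d0 <- d[d$nucleus_id == d$nucleus_id[1L], ]
    ord <- order(d0$equivalents)
    eq <- d0$equivalents[ord]
    tt <- if ("titrant_total_M" %in% names(d)) d0$titrant_total_M[ord] else NULL
    conc <- if (has_conc_col) d$fixed_species_total_M[1L] else fixed_species_total
    nuclei <- lapply(split(d, factor(d$nucleus_id,
                                     levels = unique(d$nucleus_id))),
                     function(dn) {
      if (nrow(dn) != length(eq))
        stop_schema(path, sprintf(
          "nucleus '%s' of sample '%s' has %d rows; expected one per titration point (%d)",
          dn$nucleus_id[1L], dn$sample_id[1L], nrow(dn), length(eq)))
      dn$delta_ppm[order(dn$equivalents)]
    })
    titration_series(conc, eq, nuclei, titrant_total = tt,
                     replicate_id = as.character(d$replicate_id[1L]),
                     sample_id = as.character(d$sample_id[1L]))
  })
}

#' Write titration series to CSV
#'
#' Inverse of [read_titration_csv()]: long format, one row per
#' (point, nucleus).
#'
#' @param series A `titration_series` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    do.call(rbind, lapply(names(s$nuclei), function(nm) {
      data.frame(sample_id = s$sample_id, replicate_id = s$replicate_id,
                 equivalents = s$equivalents,
                 titrant_total_M = s$titrant_total,
                 fixed_species_total_M = s$fixed_species_total,
                 nucleus_id = nm, delta_ppm = s$nuclei[[nm]])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# ---- shared CSV schema helpers ----

stop_schema <- function(path, msg) {
  stop(structure(class = c("quadbind_schema_error", "error", "condition"),
                 list(message = sprintf("%s: %s", path, msg),
                      call = NULL)))
}

read_schema_csv <- function(path, required) {
  if (!file.exists(path)) stop_schema(path, "file not found")
  df <- tryCatch(utils::read.csv(path, fileEncoding = "UTF-8"),
                 error = function(e) stop_schema(path, conditionMessage(e)))
  if (nrow(df) == 0L) stop_schema(path, "no data rows")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_schema(path, paste("missing column(s):", paste(miss, collapse = ", ")))
  df
}
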