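#' Build a stabilization (delta-Tm) table
#'
#' Tabulates, per sequence, the melting temperature of a control condition
#' against each treatment condition and their difference
#' `delta_T = Tm_condition - Tm_control`, computed from unrounded Tm values
#' (display rounding to 0.1 degC happens only at serialization). A positive
#' delta-T means the additive stabilizes the fold.
#'
#' @param fits Either a list of [fit_melt()] results (sequence and
#'   condition taken from the underlying curve's `sample_id` and
#'   `condition_label`) or a data frame with columns `sequence`,
#'   `condition`, `Tm` and optionally `Tm_se`.
#' @param control Label of the control condition; each sequence must have
#'   exactly one control row. Sequences with a missing or duplicated
#'   control yield rows with `NA` temperatures and an explanatory `note`
#'   instead of failing.
#' @return An object of class `"stabilization_table"`: a data frame with
#'   columns `sequence`, `condition`, `Tm_control`, `Tm_condition`,
#'   `delta_T`, `note`.
#' @examples
#' tm <- data.frame(sequence = "TERRA",
#'                  condition = c("control", "peptide_16x"),
#'                  Tm = c(24.7, 34.0))
#' build_stabilization_table(tm)
#' @export
build_stabilization_table <- function(fits, control = "control") {
  if (is.list(fits) && !is.data.frame(fits) &&
      all(vapply(fits, inherits, logical(1), "melt_fit"))) {
    fits <- do.call(rbind, lapply(fits, function(f)
      data.frame(sequence = f$curve$sample_id,
                 condition = f$curve$condition_label,
                 Tm = f$Tm, Tm_se = f$Tm_se)))
  }
  if (!is.data.frame(fits) ||
      !all(c("sequence", "condition", "Tm") %in% names(fits)))
    stop("'fits' must be melt fits or a data frame with sequence, condition, Tm",
         call. = FALSE)
  if (!"Tm_se" %in% names(fits)) fits$Tm_se <- NA_real_

  out <- do.call(rbind, lapply(split(fits, fits$sequence), function(d) {
    is_ctrl <- d$condition == control
    rows <- d[!is_ctrl, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    if (sum(is_ctrl) == 1L) {
      tm_ctrl <- d$Tm[is_ctrl]
      note <- ""
    } else {
      tm_ctrl <- NA_real_
      note <- if (sum(is_ctrl) == 0L) "missing control" else
        "duplicate control"
    }
    data.frame(sequence = rows$sequence, condition = rows$condition,
               Tm_control = tm_ctrl, Tm_condition = rows$Tm,
               delta_T = rows$Tm - tm_ctrl, note = note)
  }))
  if (is.null(out))
    out <- data.frame(sequence = character(0), condition = character(0),
                      Tm_control = numeric(0), Tm_condition = numeric(0),
                      delta_T = numeric(0), note = character(0))
  rownames(out) <- NULL
  class(out) <- c("stabilization_table", "data.frame")
  out
}

#' @export
print.stabilization_table <- function(x, ...) {
  d <- as.data.frame(x)
  for (cc in c("Tm_control", "Tm_condition", "delta_T"))
    d[[cc]] <- round(d[[cc]], 1)
  cat("Stabilization table (Tm in degC, rounded to 0.1 for display):\n")
  print(d, row.names = FALSE)
  invisible(x)
}

#' Write a stabilization table to CSV
#'
#' Serializes with display rounding to 0.1 degC, mirroring how such tables
#' are printed.
#' @param table A [build_stabilization_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stabilization_csv <- function(table, path) {
  d <- as.data.frame(table)
  for (cc in c("Tm_control", "Tm_condition", "delta_T"))
    d[[cc]] <- round(d[[cc]], 1)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Classify G-quadruplex topology from a CD spectrum
#'
#' Parallel G4s show a strong positive band near 262 nm with a negative
#' band near 245 nm; antiparallel G4s a positive band near 295 nm with a
#' negative trough near 232 nm. Band values are means over a +/- 3 nm
#' window; a band counts when it exceeds `threshold` mdeg in the expected
#' direction. Spectra matching neither rule (or both) are `"undetermined"`.
#'
#' @param spectrum A [cd_spectrum()] covering at least 232-300 nm.
#' @param threshold Band-significance threshold (mdeg), default 1.
#' @return `"parallel"`, `"antiparallel"` or `"undetermined"`.
#' @export
classify_topology <- function(spectrum, threshold = 1) {
  if (is.data.frame(spectrum))
    spectrum <- cd_spectrum(spectrum$wavelength_nm,
                            spectrum$ellipticity_mdeg)
  if (!inherits(spectrum, "cd_spectrum"))
    stop("'spectrum' must be a cd_spectrum or a data frame", call. = FALSE)
  wl <- spectrum$wavelengths
  if (min(wl) > 232 || max(wl) < 300)
    stop("spectrum must cover 232-300 nm for topology classification",
         call. = FALSE)
  band <- function(center) {
    sel <- abs(wl - center) <= 3
    if (!any(sel)) stop(sprintf("no data within 3 nm of %g nm", center),
                        call. = FALSE)
    mean(spectrum$ellipticity[sel])
  }
  par_rule <- band(262) > threshold && band(245) < -threshold
  anti_rule <- band(295) > threshold && band(232) < -threshold
  if (par_rule && !anti_rule) "parallel"
  else if (anti_rule && !par_rule) "antiparallel"
  else "undetermined"
}
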