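#' CD melting curve container
#'
#' Ellipticity monitored at a single wavelength across an ascending
#' temperature ramp (the instrument design records every 0.2 degC from 5 to
#' 95 degC). 260 nm is the characteristic band of parallel G-quadruplexes,
#' 295 nm of antiparallel ones.
#'
#' @param temperatures Strictly increasing temperatures (degC), >= 20 points.
#' @param ellipticity Finite ellipticity values (mdeg), same length.
#' @param monitor_wavelength Wavelength monitored (nm), e.g. 260 or 295.
#' @param sample_id,condition_label Labels carried into stabilization tables.
#' @return An object of class `"melt_curve"`.
#' @export
melt_curve <- function(temperatures, ellipticity, monitor_wavelength = 260,
                       sample_id = "sample", condition_label = "control") {
  temperatures <- as.numeric(temperatures)
  ellipticity <- as.numeric(ellipticity)
  if (length(temperatures) < 20L)
    stop("a melt curve needs at least 20 points", call. = FALSE)
  if (any(!is.finite(temperatures)) || any(diff(temperatures) <= 0))
    stop("'temperatures' must be finite and strictly increasing",
         call. = FALSE)
  if (length(ellipticity) != length(temperatures) ||
      any(!is.finite(ellipticity)))
    stop("'ellipticity' must be finite, one value per temperature",
         call. = FALSE)
  structure(list(temperatures = temperatures, ellipticity = ellipticity,
                 monitor_wavelength = monitor_wavelength,
                 sample_id = sample_id, condition_label = condition_label),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf(
    "Melt curve '%s' (%s): %d points, %.1f-%.1f degC at %g nm\n",
    x$sample_id, x$condition_label, length(x$temperatures),
    min(x$temperatures), max(x$temperatures), x$monitor_wavelength))
  invisible(x)
}

#' CD spectrum container
#'
#' @param wavelengths Ascending wavelengths (nm); must span 232-300 nm for
#'   topology classification.
#' @param ellipticity Finite ellipticity (mdeg), same length.
#' @param sample_id Label.
#' @return An object of class `"cd_spectrum"`.
#' @export
cd_spectrum <- function(wavelengths, ellipticity, sample_id = "sample") {
  wavelengths <- as.numeric(wavelengths)
  ellipticity <- as.numeric(ellipticity)
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be finite and strictly increasing", call. = FALSE)
  if (length(ellipticity) != length(wavelengths) ||
      any(!is.finite(ellipticity)))
    stop("'ellipticity' must be finite, one value per wavelength",
         call. = FALSE)
  structure(list(wavelengths = wavelengths, ellipticity = ellipticity,
                 sample_id = sample_id), class = "cd_spectrum")
}

#' Read melt curves from CSV
#'
#' Expects columns `sample_id`, `condition_label`, `temperature_C`,
#' `ellipticity_mdeg`, `wavelength_nm`.
#'
#' @param path CSV path.
#' @return List of [melt_curve()], one per `sample_id` x `condition_label`.
#' @export
read_melt_csv <- function(path) {
  df <- read_schema_csv(path, c("sample_id", "condition_label",
                                "temperature_C", "ellipticity_mdeg",
                                "wavelength_nm"))
  key <- interaction(df$sample_id, df$condition_label, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$temperature_C), ]
    if (anyDuplicated(d$temperature_C))
      stop_schema(path, sprintf(
        "duplicate temperature rows for sample '%s', condition '%s' (duplicated series?)",
        d$sample_id[1L], d$condition_label[1L]))
    melt_curve(d$temperature_C, d$ellipticity_mdeg,
               monitor_wavelength = d$wavelength_nm[1L],
               sample_id = as.character(d$sample_id[1L]),
               condition_label = as.character(d$condition_label[1L]))
  })
}

#' Write melt curves to CSV
#' @param curves A `melt_curve` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_melt_csv <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv)
    data.frame(sample_id = cv$sample_id,
               condition_label = cv$condition_label,
               temperature_C = cv$temperatures,
               ellipticity_mdeg = cv$ellipticity,
               wavelength_nm = cv$monitor_wavelength))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read CD spectra from CSV
#'
#' Expects columns `sample_id`, `wavelength_nm`, `ellipticity_mdeg`.
#' @param path CSV path.
#' @return List of [cd_spectrum()], one per `sample_id`.
#' @export
read_cd_spectrum_csv <- function(path) {
  df <- read_schema_csv(path, c("sample_id", "wavelength_nm",
                                "ellipticity_mdeg"))
  lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$wavelength_nm), ]
    cd_spectrum(d$wavelength_nm, d$ellipticity_mdeg,
                sample_id = as.character(d$sample_id[1L]))
  })
}
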