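#' Design for a synthetic NMR titration experiment
#'
#' Defaults emulate the instrument design the analysis targets: a constant
#' 125 uM observed peptide titrated with 0-2 equivalents of folded nucleic
#' acid in 12 steps, the three phenylalanine aromatic-proton environments
#' (ortho/meta/para, with ring-current upfield shifts on binding) monitored
#' jointly, statistical 2:1 binding with a plausible (synthetic) per-site
#' constant, and 0.002 ppm Gaussian shift noise.
#'
#' @param fixed_species_total Observed-species concentration (molar).
#' @param equivalents Strictly increasing titrant equivalents grid
#'   starting at 0.
#' @param n_replicates Number of replicate series.
#' @param nuclei List of per-nucleus truths: each a list with
#'   `nucleus_id`, `delta_free` (ppm) and `delta_delta` (ppm, bound-state
#'   shift change; bound shift = `delta_free + delta_delta`).
#' @param model True [binding_model()].
#' @param noise_sd Gaussian shift noise (ppm, >= 0).
#' @param temperature Temperature label (degC).
#' @param sample_id Sample label (drives the per-series noise substream).
#' @param seed Integer seed.
#' @return A list of class `"titration_design"`.
#' @export
titration_design <- function(fixed_species_total = 125e-6,
                             equivalents = seq(0, 2, length.out = 12),
                             n_replicates = 2,
                             nuclei = list(
                               list(nucleus_id = "Phe_Hortho",
                                    delta_free = 7.280,
                                    delta_delta = -0.120),
                               list(nucleus_id = "Phe_Hmeta",
                                    delta_free = 7.360,
                                    delta_delta = -0.100),
                               list(nucleus_id = "Phe_Hpara",
                                    delta_free = 7.310,
                                    delta_delta = -0.090)),
                             model = statistical_from_micro(5e3),
                             noise_sd = 0.002, temperature = 25,
                             sample_id = "synthetic", seed = 1L) {
  assert_binding_model(model)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (equivalents[1] != 0)
    stop("'equivalents' grid must start at 0 (free-state reference point)",
         call. = FALSE)
  structure(list(fixed_species_total = fixed_species_total,
                 equivalents = equivalents, n_replicates = n_replicates,
                 nuclei = nuclei, model = model, noise_sd = noise_sd,
                 temperature = temperature, sample_id = sample_id,
                 seed = as.integer(seed)),
            class = "titration_design")
}

#' Generate synthetic titration series
#'
#' Computes the noiseless fast-exchange traces with [predict_shifts()] at
#' the design truth and adds i.i.d. Gaussian noise. Each replicate draws
#' from its own substream derived by stable hashing of
#' `sample_id`/replicate from the global seed, so adding a series never
#' perturbs another one.
#'
#' @param design A [titration_design()].
#' @param seed Optional override of `design$seed`.
#' @return A list of [titration_series()] (one per replicate) with
#'   attribute `"truth"` holding the generating model and shift parameters.
#' @export
gen_titration <- function(design, seed = NULL) {
  stopifnot(inherits(design, "titration_design"))
  seed <- if (is.null(seed)) design$seed else as.integer(seed)
  shifts <- lapply(design$nuclei, function(nu)
    list(delta_free = nu$delta_free,
         delta_bound_1 = nu$delta_free + nu$delta_delta,
         delta_bound_2 = nu$delta_free + nu$delta_delta))
  names(shifts) <- vapply(design$nuclei, `[[`, character(1), "nucleus_id")
  template <- titration_series(
    design$fixed_species_total, design$equivalents,
    nuclei = lapply(shifts, function(sh) rep(sh$delta_free,
                                             length(design$equivalents))),
    temperature = design$temperature, sample_id = design$sample_id)
  truth_traces <- predict_shifts(design$model, shifts, template)
  out <- lapply(seq_len(design$n_replicates), function(r) {
    rid <- paste0("r", r)
    nuc <- with_substream(seed, paste(design$sample_id, rid), {
      lapply(truth_traces, function(tr)
        tr + stats::rnorm(length(tr), 0, design$noise_sd))
    })
    titration_series(design$fixed_species_total, design$equivalents, nuc,
                     temperature = design$temperature,
                     replicate_id = rid, sample_id = design$sample_id)
  })
  attr(out, "truth") <- list(model = design$model, shifts = shifts,
                             traces = truth_traces, design = design)
  out
}

#' Design for a synthetic CD melting experiment
#'
#' Defaults emulate the melt acquisition: readings every 0.2 degC from 5
#' to 95 degC (451 points), an asymmetric sigmoid truth, and 0.2 mdeg
#' Gaussian noise.
#'
#' @param T_start,T_end,step Temperature ramp (degC).
#' @param T_half Sigmoid position parameter (degC).
#' @param width Transition width (degC, > 0).
#' @param s Asymmetry exponent (> 0); `s = 1` is the symmetric Boltzmann
#'   case where Tm = T_half.
#' @param A_folded,A_unfolded Plateau ellipticities (mdeg).
#' @param noise_sd Gaussian ellipticity noise (mdeg, >= 0).
#' @param monitor_wavelength Monitored wavelength (nm).
#' @param sample_id,condition_label Labels.
#' @param seed Integer seed.
#' @return A list of class `"melt_design"` (with the implied true `Tm`).
#' @export
melt_design <- function(T_start = 5, T_end = 95, step = 0.2,
                        T_half = 40, width = 3, s = 1,
                        A_folded = 10, A_unfolded = 0, noise_sd = 0.2,
                        monitor_wavelength = 260,
                        sample_id = "synthetic",
                        condition_label = "control", seed = 1L) {
  if (step <= 0) stop("'step' must be positive", call. = FALSE)
  if (width <= 0 || s <= 0) stop("'width' and 's' must be positive",
                                 call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  tm <- tm_from_sigmoid(T_half, width, s)
  if (tm < T_start || tm > T_end)
    stop(sprintf("implied Tm (%.2f degC) lies outside the ramp [%g, %g]",
                 tm, T_start, T_end), call. = FALSE)
  structure(list(T_start = T_start, T_end = T_end, step = step,
                 T_half = T_half, width = width, s = s,
                 A_folded = A_folded, A_unfolded = A_unfolded,
                 noise_sd = noise_sd,
                 monitor_wavelength = monitor_wavelength,
                 sample_id = sample_id, condition_label = condition_label,
                 Tm = tm, seed = as.integer(seed)),
            class = "melt_design")
}

#' Closed-form Tm of the asymmetric sigmoid
#'
#' Solves the half-denaturation condition analytically:
#' `Tm = T_half + width * log(2^(1/s) - 1)`.
#' @param T_half,width,s Sigmoid parameters.
#' @return Tm (degC).
#' @export
tm_from_sigmoid <- function(T_half, width, s) {
  T_half + width * log(2^(1 / s) - 1)
}

#' Generate a synthetic CD melt curve
#'
#' @param design A [melt_design()].
#' @param seed Optional override of `design$seed`.
#' @return A [melt_curve()] with attribute `"truth"` (the design, including
#'   the implied true Tm).
#' @export
gen_melt <- function(design, seed = NULL) {
  stopifnot(inherits(design, "melt_design"))
  seed <- if (is.null(seed)) design$seed else as.integer(seed)
  Tv <- seq(design$T_start, design$T_end, by = design$step)
  pars <- list(Af = design$A_folded, Au = design$A_unfolded, mf = 0, mu = 0,
               Th = design$T_half, w = design$width, s = design$s)
  truth <- melt_value(pars, Tv)
  y <- with_substream(seed,
                      paste(design$sample_id, design$condition_label), {
    truth + stats::rnorm(length(truth), 0, design$noise_sd)
  })
  out <- melt_curve(Tv, y, monitor_wavelength = design$monitor_wavelength,
                    sample_id = design$sample_id,
                    condition_label = design$condition_label)
  attr(out, "truth") <- design
  out
}

#' Generate a full synthetic study bundle
#'
#' Writes to `dir` the CSVs of a study-shaped design matrix plus a truth
#' manifest (`truth.json`):
#' * `titrations.csv` — duplicate titrations of four conditions
#'   (RNA/DNA x folded/unfolded) under statistical 2:1 truths whose
#'   ordering mirrors the studied selectivity (folded RNA the strongest,
#'   ~4-fold over unfolded RNA, ~50-fold over folded DNA); the constants
#'   themselves are synthetic placeholders.
#' * `melts.csv` — 7 loop-sequence melt series (native telomeric repeat
#'   plus U3/U2/U1/A3/A2/A1 loop mutants), each under control, 16x
#'   peptide and 16x K+ conditions, with true Tm values taken from the
#'   corresponding published stabilization table.
#'
#' Deterministic per seed; every series has its own noise substream.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param titration_noise_sd,melt_noise_sd Noise levels (ppm, mdeg).
#' @return Invisibly, a list with `dir`, file paths and the `truth`
#'   manifest.
#' @export
gen_study_bundle <- function(dir, seed = 1L,
                             titration_noise_sd = 0.002,
                             melt_noise_sd = 0.2) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop(sprintf("cannot create output directory '%s'", dir),
           call. = FALSE)
  seed <- as.integer(seed)

  titr_truth <- list(RNA_folded = 4e4, RNA_unfolded = 1e4,
                     DNA_folded = 8e2, DNA_unfolded = 5e2)
  titr_series <- list()
  for (nm in names(titr_truth)) {
    des <- titration_design(model = statistical_from_micro(titr_truth[[nm]]),
                            noise_sd = titration_noise_sd,
                            sample_id = nm, seed = seed)
    titr_series <- c(titr_series, gen_titration(des))
  }
  titr_path <- file.path(dir, "titrations.csv")
  write_titration_csv(titr_series, titr_path)

  melt_truth_tm <- bundle_melt_truth_tm()
  s_true <- 1.6; w_true <- 3
  melt_curves <- list()
  for (i in seq_len(nrow(melt_truth_tm))) {
    row <- melt_truth_tm[i, ]
    th <- row$Tm - w_true * log(2^(1 / s_true) - 1)
    des <- melt_design(T_half = th, width = w_true, s = s_true,
                       A_folded = 10, A_unfolded = 0,
                       noise_sd = melt_noise_sd,
                       sample_id = row$sequence,
                       condition_label = row$condition, seed = seed)
    melt_curves <- c(melt_curves, list(gen_melt(des)))
  }
  melt_path <- file.path(dir, "melts.csv")
  write_melt_csv(melt_curves, melt_path)

  truth <- list(seed = seed,
                titration = list(model = "2:1-statistical",
                                 k_micro = titr_truth,
                                 delta_free = 7.300, delta_delta = -0.120,
                                 fixed_species_total_M = 125e-6,
                                 noise_sd_ppm = titration_noise_sd),
                melt = list(table = melt_truth_tm,
                            width = w_true, s = s_true,
                            noise_sd_mdeg = melt_noise_sd))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(dir = dir,
                 files = c(titrations = titr_path, melts = melt_path,
                           truth = truth_path),
                 truth = truth))
}

# True melting temperatures of the bundle's 7 sequences x 3 conditions
# (values as printed in the study's stabilization table)
bundle_melt_truth_tm <- function() {
  seqs <- c("TERRA", "G3U3", "G3U2", "G3U1", "G3A3", "G3A2", "G3A1")
  tm_ctrl <- c(24.7, 31.3, 36.0, 50.9, 43.9, 42.7, 52.7)
  tm_pep <- c(34.0, 35.4, 40.9, 52.5, 41.5, 36.9, 52.5)
  tm_kcl <- c(46.3, 45.3, 54.4, 61.8, 58.7, 45.3, 59.6)
  data.frame(
    sequence = rep(seqs, times = 3),
    condition = rep(c("control", "RGGFGGRGG_16x", "KCl_16x"),
                    each = length(seqs)),
    Tm = c(tm_ctrl, tm_pep, tm_kcl))
}

# Evaluate `expr` under a deterministic RNG substream derived from
# (seed, label) by stable string hashing; restores the caller's RNG state.
with_substream <- function(seed, label, expr) {
  h <- seed %% 2147483647L
  for (code in utf8ToInt(label))
    h <- (h * 31 + code) %% 2147483647L
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(h))
  expr
}
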