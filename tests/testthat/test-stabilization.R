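published_tm <- function() {
  # printed control / 16x-peptide / 16x-K+ melting temperatures (degC)
  data.frame(
    sequence = rep(c("TERRA", "G3U3", "G3U2", "G3U1", "G3A3", "G3A2",
                     "G3A1"), times = 3),
    condition = rep(c("control", "peptide_16x", "KCl_16x"), each = 7),
    Tm = c(24.7, 31.3, 36.0, 50.9, 43.9, 42.7, 52.7,
           34.0, 35.4, 40.9, 52.5, 41.5, 36.9, 52.5,
           46.3, 45.3, 54.4, 61.8, 58.7, 45.3, 59.6))
}

test_that("stabilization table reproduces the printed delta-Tm values", {
  tab <- build_stabilization_table(published_tm())
  pick <- function(seq, cond)
    tab$delta_T[tab$sequence == seq & tab$condition == cond]
  expect_equal(pick("TERRA", "peptide_16x"), 9.3)
  expect_equal(pick("TERRA", "KCl_16x"), 21.6, tolerance = 1e-9)
  expect_equal(pick("G3U3", "peptide_16x"), 4.1)
  expect_equal(pick("G3A3", "peptide_16x"), -2.4)
  expect_equal(pick("G3A2", "peptide_16x"), -5.8)
  # delta_T always equals the unrounded Tm difference
  expect_equal(tab$delta_T, tab$Tm_condition - tab$Tm_control,
               tolerance = 1e-10)
})

test_that("stabilization sign structure separates stabilizers from destabilizers", {
  tab <- build_stabilization_table(published_tm())
  pep <- tab[tab$condition == "peptide_16x", ]
  expect_true(all(pep$delta_T[pep$sequence %in%
                                c("TERRA", "G3U3", "G3U2", "G3U1")] > 0))
  expect_true(all(pep$delta_T[pep$sequence %in%
                                c("G3A3", "G3A2", "G3A1")] < 0))
  kcl <- tab[tab$condition == "KCl_16x", ]
  expect_true(all(kcl$delta_T > 0))  # K+ stabilizes every sequence
})

test_that("identical control and condition give delta_T of zero", {
  tm <- data.frame(sequence = "X", condition = c("control", "treated"),
                   Tm = c(50, 50))
  tab <- build_stabilization_table(tm)
  expect_identical(tab$delta_T, 0)
})

test_that("missing controls become per-row notes, not failures", {
  tm <- data.frame(sequence = c("A", "A", "B"),
                   condition = c("control", "treated", "treated"),
                   Tm = c(40, 45, 50))
  tab <- build_stabilization_table(tm)
  expect_equal(tab$delta_T[tab$sequence == "A"], 5)
  expect_true(is.na(tab$delta_T[tab$sequence == "B"]))
  expect_match(tab$note[tab$sequence == "B"], "missing control")
})

test_that("serialization rounds to 0.1 degC only at output", {
  tm <- data.frame(sequence = "X", condition = c("control", "treated"),
                   Tm = c(40.04, 45.17))
  tab <- build_stabilization_table(tm)
  expect_equal(tab$delta_T, 5.13, tolerance = 1e-10)  # unrounded in memory
  path <- tempfile(fileext = ".csv")
  write_stabilization_csv(tab, path)
  back <- read.csv(path)
  expect_equal(back$delta_T, 5.1)
  expect_equal(back$Tm_control, 40.0)
})

gaussian_band <- function(wl, center, height, width = 6)
  height * exp(-(wl - center)^2 / (2 * width^2))

test_that("CD topology classification follows the published band rules", {
  wl <- 220:320
  par_spec <- cd_spectrum(wl, gaussian_band(wl, 262, 8) +
                            gaussian_band(wl, 245, -6))
  expect_identical(classify_topology(par_spec), "parallel")
  anti_spec <- cd_spectrum(wl, gaussian_band(wl, 295, 5) +
                             gaussian_band(wl, 232, -4))
  expect_identical(classify_topology(anti_spec), "antiparallel")
  zero_spec <- cd_spectrum(wl, rep(0, length(wl)))
  expect_identical(classify_topology(zero_spec), "undetermined")
  # coverage requirement
  narrow <- cd_spectrum(250:300, gaussian_band(250:300, 262, 8))
  expect_error(classify_topology(narrow), "232-300")
})
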