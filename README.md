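# quadbind

Quantitative analysis of weak peptide–G-quadruplex interactions: host–guest
equilibrium speciation, NMR chemical-shift titration fitting with
stoichiometry model selection, CD melting-curve melting-temperature (Tm)
analysis, and the thermodynamic arithmetic that connects them.

The package is aimed at supramolecular / nucleic-acid biophysics workflows
in which a short peptide (for instance an RGG-motif peptide derived from an
RNA-binding protein's disordered region) binds a folded RNA or DNA
G-quadruplex weakly, so that:

* binding constants must be extracted from **fast-exchange ¹H NMR
  titrations** — a single population-weighted resonance per nucleus,
  `δ_obs = (δ_free·[L] + δ_b1·[RL] + δ_b2·2[RL₂]) / L_t` — rather than
  from peak integration;
* the stoichiometry question (one site? two independent sites? cooperative
  sites?) is settled by **AICc model comparison** between a 1:1 model, a
  statistical (non-cooperative) 2:1 model with a single microscopic
  per-site constant `k` (`K₁ = 2k`, `K₂ = k/2`, `K₁/K₂ = 4`,
  cooperativity index `α = 4K₂/K₁ = 1`), and a full 2:1 model;
* thermal stabilization is quantified from **CD melting curves** fitted to
  an asymmetric sigmoid, with Tm defined as the temperature at which half
  of the structure has denatured, and summarised in control-vs-condition
  ΔTm tables;
* selectivity is expressed as `ΔΔG = −RT ln(K_a/K_b)` and experiment
  design as "how many ligand equivalents reach X% site occupancy".

Everything is built on an exact mass-action speciation core: the free
ligand concentration solves the strictly monotone mass balance
`h(p) = p + R_t(K₁p + 2K₁K₂p²)/(1 + K₁p + K₁K₂p²) − L_t = 0`, located by
a bracketed safeguarded solver and polished to machine precision.

Seeded generators (`gen_titration()`, `gen_melt()`, `gen_study_bundle()`)
emulate the corresponding instrument designs (125 µM fixed peptide, 0–2
titrant equivalents in 12 steps, duplicate series; ellipticity every
0.2 °C from 5–95 °C), so the whole pipeline is testable without
instrument data.

## Worked example

```r
library(quadbind)

## duplicate synthetic titrations at the default design
## (125 uM peptide, 0-2 equivalents, three aromatic protons, sd 0.002 ppm,
##  true per-site constant 5000 M^-1)
reps <- gen_titration(titration_design(seed = 7))

fit <- fit_titration(reps[[1]], model = "2:1-statistical")
fit
#> Titration fit: 2:1-statistical model, 36 observations, 7 parameters
#>   k (per site) = 4686 +/- 654 M^-1
#>   rss = 0.0001483 ppm^2, AICc = -428.40

## does the data demand cooperativity? (no: statistical model wins)
compare_binding_models(reps[[1]],
                       candidates = c("2:1-statistical", "2:1-full"))$table
#>             model n_params          rss      aicc delta_aicc rank
#> 1 2:1-statistical        7 0.0001482538 -428.4037    0.00000    1
#> 2        2:1-full       11 0.0001413777 -415.1134   13.29034    2

## inverse-variance weighted average over the duplicates
avg <- average_constants(lapply(reps, fit_titration))
sprintf("weighted k = %.0f +/- %.0f M^-1", avg$K, avg$se)
#> "weighted k = 5222 +/- 484 M^-1"   # truth: 5000

## selectivity between two binding constants
selectivity(4e4, 1e4)
#> 4-fold selectivity: delta delta G = -3.4 kJ/mol at 298.15 K

## a CD melt and its Tm at the half-denaturation point
d <- gen_melt(melt_design(T_half = 26.7, width = 3, s = 1.6,
                          noise_sd = 0.2, sample_id = "TERRA", seed = 7))
fit_melt(d)
#> Melt fit 'TERRA' (control):
#>   Tm = 24.83 +/- 0.04 degC  (T_half = 27.00, width = 3.07, s = 1.727)
#>   plateaus: folded 10.03, unfolded 0.01 mdeg; rss = 16.61 mdeg^2

## design question: equivalents of a weak binder for 90% site occupancy
design_saturation(statistical_from_micro(3.2e4), 20e-6, 0.9)
#> 15.9
```

The numbers mean: the recovered per-site constant (4686 ± 654 M⁻¹ from
one series, 5222 ± 484 M⁻¹ after weighting the duplicates) brackets the
generating truth of 5000 M⁻¹; AICc prefers the non-cooperative statistical
2:1 model over the full 2:1 by 13 units; a 4-fold constant ratio is worth
−3.4 kJ/mol at 25 °C; the melt's Tm (24.8 °C) sits below its sigmoid
position parameter because the transition is asymmetric (s ≈ 1.7); and a
binder of 3.2 × 10⁴ M⁻¹ needs ≈ 16 equivalents over a 20 µM receptor to
fill 90% of its sites.

A thin command-line wrapper over the same functions is installed at
`inst/cli/quadbind.R` (`fit-titration`, `fit-melt`, `classify-cd`,
`simulate`, `gen-synth`; exit codes 0/2/3 for success / input error / fit
failure).

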