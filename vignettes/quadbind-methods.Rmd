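---
title: "Models and methods behind quadbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quadbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadbind)
```

quadbind analyses weak peptide–nucleic-acid binding of the kind probed when
a short RGG-motif peptide is titrated against a folded G-quadruplex: NMR
chemical-shift titrations fitted to host–guest equilibrium models, CD
melting curves fitted for melting temperatures, and the thermodynamic
arithmetic connecting the two. This vignette explains the underlying
models, the choices the package makes where a choice was genuinely open,
and what its synthetic data can and cannot tell you about real
measurements.

## Equilibrium speciation

The core mass-action system is

$$R + L \rightleftharpoons RL \quad (K_1), \qquad
  RL + L \rightleftharpoons RL_2 \quad (K_2),$$

with the receptor $R$ fixed to the nucleic-acid strand and the ligand $L$
to the peptide — two peptides can bind one quadruplex. The convention is
deliberately independent of which species an experiment titrates: the NMR
design holds the *peptide* constant and titrates RNA, but the model does
not care.

Given totals $R_t$ and $L_t$, the free-ligand concentration $p$ solves the
scalar mass balance

$$h(p) = p + R_t\,\frac{K_1 p + 2K_1K_2p^2}{1 + K_1p + K_1K_2p^2} - L_t
  = 0,$$

which is strictly increasing on $[0, L_t]$ with $h(0) = -L_t < 0$ and
$h(L_t) \ge 0$, so a unique bracketed root always exists.
`solve_speciation()` locates it with a safeguarded bracketed solver and
polishes with damped Newton steps; mass balance holds to better than
$10^{-10}$ relative (in practice to machine precision) across
$K \in [1, 10^8]\,\mathrm{M^{-1}}$ and concentrations from 10 nM to
10 mM. The 1:1 model uses the numerically stable quadratic closed form
instead. All internal units are mol/L and $\mathrm{M^{-1}}$; conversion
from µM happens at the I/O boundary, so the core never mixes units.

Three stoichiometry models are supported. The *statistical* 2:1 model is
the one of principal scientific interest here: two equivalent, independent
sites with one microscopic per-site constant $k$, forcing
$K_1 = 2k$, $K_2 = k/2$, a constant ratio $K_1/K_2 = 4$ and cooperativity
index $\alpha = 4K_2/K_1 = 1$. Its speciation is identical to a 1:1 system
of independent sites at twice the receptor concentration — a property the
test suite checks to $10^{-9}$ relative. The *full* 2:1 model frees both
stepwise constants; the 1:1 model keeps a single equilibrium.

Degenerate inputs are handled explicitly: $R_t = 0$ returns
$p = L_t$ without invoking the solver (avoiding a 0/0 in $h$), and
$K_1 = 0$ blocks both binding steps.

## The fast-exchange observation model

On the NMR chemical-shift timescale this binding is in fast exchange: one
population-weighted resonance per nucleus. The observed shift of the
ligand is

$$\delta_{obs} = \frac{\delta_{free}\,[L] + \delta_{b1}\,[RL] +
  \delta_{b2}\,2[RL_2]}{L_t},$$

so with zero titrant $\delta_{obs} = \delta_{free}$ exactly. The
statistical model constrains $\delta_{b2} = \delta_{b1}$: independent,
equivalent sites imply a single bound environment. The full 2:1 model
frees both. Slow- or intermediate-exchange lineshapes are out of scope.

No dilution correction is applied by default — the titrant is assumed
added without changing the fixed-species concentration, since typical
small-volume additions from a concentrated stock perturb it by a few
percent at most. A per-point titrant-concentration column in the input CSV
overrides the equivalents-derived values when a correction is needed.

## Fitting titrations

`fit_titration()` minimises the summed squared shift residuals over all
nuclei and titration points. Two structural facts shape the optimiser:

* Equilibrium constants live on a log scale. They are optimised as
  $\log_{10} K$, initialised from a coarse grid over
  $\log_{10} K \in \{1, \dots, 8\}$ (for the full model the second
  constant starts at the statistical ratio $K_2 = K_1/4$), which removes
  the need for user starting values and avoids the local minima that
  plague isotherm fits.
* The shift parameters enter the prediction *linearly*. At every
  candidate constant they are profiled out exactly by QR projection, so
  the nonlinear search is one-dimensional (1:1, statistical) or
  two-dimensional (full). This makes the fit fast and the optimum
  invariant to reparametrization — fitting on the natural-$K$ scale finds
  the same residual sum of squares, which the tests verify.

Standard errors come from the Jacobian at the optimum,
$\sigma^2 (J^\top J)^{-1}$, and model comparison uses
$\mathrm{AICc} = n\ln(\mathrm{rss}/n) + 2p + 2p(p+1)/(n-p-1)$.
`compare_binding_models()` ranks candidates by AICc; candidates within 2
units of the best are treated as indistinguishable and the tie goes to the
fewest parameters — the parsimony rule for choosing the simplest adequate
stoichiometry. One caveat worth stating plainly: a 1:1 model has exactly
as many parameters as the statistical 2:1 model, and for ligand-observed
shifts their isotherm shapes at these concentrations are so similar that
no information criterion separates them reliably; the meaningful,
well-powered comparison is statistical-2:1 versus full-2:1, i.e. whether
the data demand cooperativity.

Traces whose total excursion stays below the `noise_sd` option
(default 0.002 ppm) are flagged unidentifiable and reported without
confidence intervals rather than with meaningless ones.

Replicate titrations are combined by `average_constants()` as an
inverse-variance weighted mean with propagated standard error,
$\bar K = \sum K_i/\mathrm{se}_i^2 \big/ \sum 1/\mathrm{se}_i^2$. A
"weighted average" of replicate constants admits several readings (across
nuclei, replicates, or stepwise constants); the fixed-effect
inverse-variance weighting across replicate fits is the standard
statistical choice and is the one implemented.

## Melting curves and Tm

CD melts are fitted to the five-parameter asymmetric logistic

$$y(T) = A_u + \frac{A_f - A_u}{\left(1 +
  e^{(T - T_{1/2})/w}\right)^{s}},$$

with width $w > 0$ and asymmetry exponent $s > 0$ kept positive by log
parametrization (a negative width can never be reported). $A_f$ is the
low-temperature (folded) plateau. Commercial fitters' "asymmetric
sigmoidal" families are reparametrizations of the same shape; what is
binding here is not the family but the *definition of Tm*: the temperature
at which half of the structure has denatured,
$y(T_m) = (A_f + A_u)/2$, found by bracketed root-finding within the data
range (so a reported Tm is always supported by data). For $s = 1$ this
collapses to the symmetric Boltzmann case $T_m = T_{1/2}$. The standard
error of Tm follows by the delta method on the half-signal equation.

Because Tm is defined through the half-signal crossing, it is invariant
under affine transforms of the signal ($y \to ay + b$) and equivariant
under temperature shifts — both tested to $10^{-6}$ °C. Plateaus are
constant by default; linear pre-/post-transition baselines sit behind
`baseline = "linear"` since melt data rarely constrain slopes and the
added parameters inflate Tm uncertainty when they are not needed.

Orientation: at 260 nm (the parallel-quadruplex band) the folded state is
the high-signal plateau; at 295 nm likewise for antiparallel folds. The
orientation argument drives labelling and sanity warnings, not the least
squares itself.

`fraction_folded()` is the exact linear normalization against a
fully-folded reference and an unfolded baseline; values slightly outside
$[0, 1]$ are reported untouched, because clipping would hide baseline
problems. `build_stabilization_table()` computes
$\Delta T = T_m^{cond} - T_m^{control}$ from unrounded values and rounds
to 0.1 °C only when serializing, which is why a printed table can show a
$\Delta T$ differing by 0.1 from the difference of its printed Tm columns.

CD topology calls use the canonical band rules — parallel: positive near
262 nm and negative near 245 nm; antiparallel: positive near 295 nm and
negative near 232 nm — with band values averaged over ±3 nm and a 1 mdeg
significance threshold. Anything matching neither (or both) is
`"undetermined"` rather than forced.

## Thermodynamics

`free_energy()` computes $\Delta G = -RT\ln K$ with
$R = 8.314\ \mathrm{J\,mol^{-1}K^{-1}}$ and 25 °C mapped to 298.15 K;
`selectivity()` gives the fold-ratio and
$\Delta\Delta G = -RT\ln(K_a/K_b)$. Note the rounding trap these closed
forms expose: a 50-fold ratio corresponds to −9.70 kJ/mol at 298.15 K, so
a report pairing "~50-fold" with −10.0 kJ/mol must have computed from an
unrounded ratio nearer 56; similarly "~4-fold" with −3.2 kJ/mol implies a
ratio nearer 3.6. The package computes, it does not reconcile.

`design_saturation()` inverts the monotone occupancy-vs-equivalents
relation by bisection to answer the practical design question "how large
an excess of a weak binder do I need?" — e.g. a per-site constant of
$3.2 \times 10^4\ \mathrm{M^{-1}}$ with 20 µM receptor needs 16
equivalents for 90% site occupancy. "Saturation" is interpreted as
receptor *site occupancy* (the fraction of binding sites filled); the
fraction of ligand bound is also reported, since with a large ligand
excess the two differ drastically.

## What the synthetic data emulate — and what they do not

The generators reproduce the *designs* of the corresponding experiments:

* `gen_titration()`: a constant 125 µM observed peptide, titrant from 0
  to 2 equivalents in 12 steps, duplicate series, three monitored
  phenylalanine aromatic-proton environments (ortho/meta/para, with
  upfield ring-current shift changes of −0.12/−0.10/−0.09 ppm from free
  shifts near 7.3 ppm), Gaussian shift noise of 0.002 ppm. The default
  per-site constant of $5 \times 10^3\ \mathrm{M^{-1}}$ is a synthetic,
  order-of-magnitude-plausible value for a weak binder — it is *not* a
  fitted literature constant.
* `gen_melt()`: readings every 0.2 °C from 5 to 95 °C (451 points),
  asymmetric-sigmoid truth, 0.2 mdeg noise.
* `gen_study_bundle()`: the full design matrix — four titration
  conditions (RNA/DNA × folded/unfolded, with synthetic constants whose
  *ordering* mirrors the studied selectivity) and seven loop-sequence
  melt series × three conditions whose true Tm values are the published
  ones, since those are printed numbers usable as inputs.

Noise is i.i.d. Gaussian and homoscedastic. Real spectrometer data have
drift, correlated baseline error, heteroscedastic noise near transitions,
and occasional outliers; passing recovery tests on these generators
therefore demonstrates correctness of the estimators under their stated
model, not robustness to instrument pathology. Randomness is fanned out
from one integer seed to per-series substreams by stable hashing of the
series label, so adding a series to a design never changes another
series' draws, and output CSVs are byte-identical per seed.

Monte-Carlo problem sizes used throughout the tests and the acceptance
script — $10^4$ random speciation systems, 100 seeded duplicate titration
studies, 100 seeded melt curves — were chosen as the smallest sizes at
which the recovery statistics stabilise.

## Known limitations

* Stoichiometries beyond 2:1, binding kinetics, activity/ionic-strength
  corrections and ITC thermograms are out of scope.
* The titration fit assumes fast exchange; it will silently mis-fit
  slow-exchange data (which show two resonances, not one moving peak).
* Van't Hoff enthalpy extraction from melt curves is deliberately not
  offered: plateaus and transition widths of CD melts rarely support it.
* The 1:1 vs statistical-2:1 ambiguity described above is a property of
  the experiment, not of the fitter; resolving stoichiometry needs
  receptor-observed shifts, a Job plot or calorimetry.
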