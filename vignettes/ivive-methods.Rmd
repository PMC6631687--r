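---
title: "Methods: in vitro-in vivo extrapolation of radiotracer clearance"
author: "ivivepk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in vitro-in vivo extrapolation of radiotracer clearance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivivepk)
```

## Scope

`ivivepk` implements a complete in vitro-in vivo extrapolation (IVIVE)
workflow for hepatically cleared PET radiotracers in the rat model:

1. **In vitro**: microsomal substrate-depletion time courses are fitted to a
   monoexponential decay; the half-life is corrected for nonspecific
   microsomal binding and scaled physiologically to intrinsic clearance.
2. **Prediction**: the well-stirred liver model converts intrinsic clearance
   and the plasma free fraction into a predicted plasma clearance.
3. **In vivo**: raw per-animal plasma radioactivity measurements are decay-
   and metabolite-corrected, aggregated into mean curves, fitted with a
   triexponential disposition model, and summarized as observed plasma
   clearance, volume of distribution and terminal half-life.
4. **Binding**: plasma free fractions are computed from ultrafiltration
   count pairs.
5. **Accuracy**: predictions are compared with observations via fold error,
   average fold error (AFE) and RMSE.

A synthetic-data generator reproduces the statistical structure of such a
study so that every stage is testable without animal data. The package
ships reference values for three xanthine-type A~1~ adenosine receptor
ligands (CBX, MCBX, CPFPX) studied in rat, used throughout as the worked
example.

## In vitro models

### Substrate depletion

Peak-area ratios (percent remaining relative to the $t=0$ sample) are
fitted to

$$C(t) = C_0 \, e^{-\ln 2 \, t / t_{1/2}}.$$

$C_0$ is a free parameter rather than being pinned at 100: the $t=0$
normalization makes 100 the nominal intercept, but the $t=0$ measurement
itself is noisy and that noise propagates into every ratio, so a free
intercept is the more robust choice. The fit minimizes **relative**
residuals $(y - \hat y)/\hat y$ by default (`weights = "relative"`):
chromatographic peak-area ratios carry multiplicative error, for which
relative least squares is the likelihood-matched objective; an unweighted
percent-scale fit (`weights = "uniform"`) is available and is the objective
used by the exhaustive grid-search oracle in the test suite. A log-linear
regression provides starting values. Estimated half-lives outside
[0.1, 10000] min are reported as fit failures, never clamped.

Replicates (triplicate by default) are fitted individually; the reported
half-life is their arithmetic mean with SD. Note that with sampling
restricted to 0-20 min and ~5% multiplicative noise, the half-life of a
slowly depleting compound (e.g. 35 min, only one third depleted within the
window) is intrinsically imprecise; this is a property of the assay design,
not of the estimator.

### Microsomal binding correction

The unbound fraction in the incubation is predicted from lipophilicity:

$$f_{mic} = \frac{1}{1 + P \cdot 10^{\,0.072\,\log P^2 + 0.067\,\log P - 1.126}},$$

with $P$ the microsomal protein concentration (mg/mL). $f_{mic}$ is 1 at
$P = 0$, decreases with protein concentration, and decreases with $\log P$
throughout the relevant lipophilicity range (the quadratic's vertex lies at
$\log P \approx -0.47$).

### Scaling to intrinsic clearance

$$CL_{int} = \frac{\ln 2}{t_{1/2} \cdot f_{mic}}
  \cdot \frac{\text{mL incubation}}{\text{mg protein}}
  \cdot \frac{60\ \text{mg protein}}{\text{g liver}}
  \cdot \frac{40\ \text{g liver}}{\text{kg body weight}}.$$

The unbound fraction **divides** the apparent depletion rate (unbound
intrinsic clearance convention): nonspecific binding slows apparent
depletion, so the correction must increase $CL_{int}$. At the default
0.5 mg/mL protein the volume term is 2 mL/mg, giving the overall factor
4800 mL·g/(mg·kg). Scaling factors (60, 40, and hepatic blood flow
Q = 55 mL/min/kg) are standard rat values and are configurable through
`scaling_factors()`.

### Well-stirred liver model

$$CL_p = \frac{Q \cdot f_p \cdot CL_{int}}{Q + f_p \cdot CL_{int}}$$

with $f_p$ the plasma free fraction. The prediction is bounded by both the
flow limit $Q$ and the restrictive limit $f_p CL_{int}$. The algebraic
inverse `invert_well_stirred_fp()` reconstructs an implied free fraction
from a $(CL_{int}, CL_p)$ pair; the bundled reference free fractions
(~0.027, 0.044, 0.017 for CBX, MCBX, CPFPX) were obtained this way and are
reconstructions, not measurements — the underlying study reported free
fractions only as "below 5%".

### Accuracy metrics

Fold error is predicted/observed. AFE is the geometric mean fold error,
$10^{\overline{\log_{10}(\text{pred}/\text{obs})}}$; its inverse is the
fold underprediction. RMSE is computed on the natural clearance scale. All
arithmetic is full precision; rounding (2 decimals for fold errors and AFE,
1 for RMSE) happens only in the reporting layer.

## In vivo pipeline

### Corrections

Measured total radioactivity in a weighed plasma aliquot is converted to
concentration assuming plasma density 1 g/mL, decay-corrected to injection
time by $2^{t/T_{1/2}}$ (fluorine-18: $T_{1/2}$ = 109.77 min, configurable),
and metabolite-corrected by multiplying with the parent fraction linearly
interpolated at each sampling time (clamped to the nearest measurement
outside the measured range). The two corrections are multiplicative and
commute. SUV normalization (concentration divided by injected activity per
gram body mass) is provided for visualization; the analysis operates on
absolute concentration.

### Triexponential disposition model

$$C_p(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} + A_3 e^{-\lambda_3 t},
\qquad \lambda_1 > \lambda_2 > \lambda_3 > 0,$$

fitted by nonlinear least squares with parameters on the log scale
(positivity by construction). Three numerical choices matter:

* **Weighting.** The default objective is relative least squares
  (`weights = "inverse_yhat2"`). Corrected radiotracer concentrations carry
  multiplicative error — counting noise amplified by the decay correction
  plus relative parent-fraction error — and a plasma curve spans more than
  two decades. An unweighted fit lets the early high-concentration points
  dominate, leaving the terminal phase so poorly determined that volume of
  distribution and terminal half-life become unreliable; in simulation its
  median $V_d$ error roughly triples. `weights = "uniform"` is available.
* **Identifiability bounds.** Rate constants are box-constrained to
  $[1/(3 t_{max}),\ 3/t_{first}]$. A phase faster than the upper bound has
  decayed below ~5% before the first sample; one slower than the lower
  bound is indistinguishable from a constant over the observation window.
  In both cases the corresponding amplitude is unconstrained by the data
  and corrupts only the model AUC — producing the familiar pathology of
  individual-animal fits with unphysiologically long terminal half-lives.
  Estimates at a bound mean the data do not support three phases within the
  identifiable range.
* **Multi-start.** Initialization is by curve stripping (log-linear fit of
  the terminal tail, peel, repeat), refined together with 20 restarts: half
  perturb the stripped start, half are drawn globally from the bounded
  parameter box. Ties in the objective are broken toward the larger
  $\lambda_1/\lambda_3$ spread. The test suite verifies the optimizer
  against an independent 200-restart L-BFGS-B oracle on the same bounded
  domain.

Near-degenerate solutions (an amplitude below $10^{-6}\,\max y$, or
adjacent rate constants within 20%) are flagged in the fit's
`diagnostics`; biexponential data therefore either fail or carry a flag.

### PK parameters

$$CL_p = \frac{D}{\sum_i A_i/\lambda_i}, \qquad
  V_d = \frac{CL_p}{\lambda_3}, \qquad
  t_{1/2,term} = \frac{\ln 2}{\lambda_3},$$

where $D$ is the injected activity and the denominator of $CL_p$ is the
analytic AUC of the model over $[0,\infty)$ (verified against adaptive
quadrature in the tests). With a body weight supplied, clearance and volume
are normalized per kg. Dosing is treated as an instantaneous bolus at
$t = 0$; the model is a bolus disposition model even though real
administration takes about a minute.

### Mean-curve aggregation

Individual corrected curves sampled on a common nominal grid are averaged
pointwise (arithmetic mean and sample SD); no resampling is attempted, and
mismatched grids are an error. Averaging absolute concentration is the
default; SUV averaging is available via a flag. Terminal-phase parameters
from single-animal fits are noise-limited, so the mean-curve fit is the
primary estimate; `analyze_pk_study()` reports both, plus the percent
deviation between the mean-curve clearance and the mean of individual
clearances — in simulation this deviation is typically 1-4%.

## Plasma protein binding

The free fraction is the ratio of radioactivity in equal volumes of
ultrafiltrate and spiked plasma. No correction is applied for nonspecific
binding to the filtration device (a documented limitation; none was
characterized for the reference assay). Filtrate counts exceeding plasma
counts are a data-quality error, not silently clamped. Group summaries are
mean ± SD; formal group comparisons are out of scope.

## Synthetic-data generator

The generator emulates the reference study design and is itself tested
code; all generators are pure functions of (profile, noise, n, seed) and
never perturb the caller's RNG state.

* **Depletion** (`generate_depletion()`): sampling at 0, 2, 5, 10, 15,
  20 min; lognormal multiplicative noise with CV 5% (default); the curve is
  renormalized so the $t=0$ sample reads exactly 100, mirroring
  peak-area-ratio normalization.
* **PK studies** (`generate_pk_study()`): the ground truth is a
  triexponential built from the profile's terminal half-life
  ($\lambda_3 = \ln 2 / t_{1/2,term}$), shape multipliers
  $\lambda_1 = 20\lambda_3$, $\lambda_2 = 4\lambda_3$ and amplitude
  proportions 3 : 1 : 1/3 — free parameters chosen to produce three
  visually distinct kinetic phases — rescaled so that
  $D / \sum A_i/\lambda_i$ equals the animal's clearance exactly. The
  per-kg identities for $V_d$ and $t_{1/2,term}$ then hold by construction
  before any noise. Per-animal clearance varies lognormally (CV 10%, an
  assumption; between-animal variability was described only as "small").
  Body weight (0.503 ± 0.044 kg), injected activity (21 ± 2.5 MBq) and
  amount (0.39 ± 0.20 nmol) match the reference cohort. Sampling uses a
  dense-early/sparse-late grid (1, 2, 3, 5, 7.5, 10, 15, 20, 30, 40, 60,
  90, 120, 150, 180 min). The generator emits what the counter sees:
  parent truth divided by the true parent fraction (total radioactivity),
  multiplied by physical decay, in a weighed ~0.1 g aliquot, with Poisson
  counting noise at 0.5 counts/Bq/s over a 60 s counting window (standard
  gamma-counting practice; sub-second counting of few-hundred-Bq samples
  would not be a plausible protocol). Measured parent fractions carry
  additive noise (SD 0.02). The analysis pipeline must undo both
  corrections.
* **Ultrafiltration** (`generate_ultrafiltration()`): 5-6 kBq spikes,
  50 µL of ~250 µL counted, expected filtrate counts $f_p \times$ plasma
  counts, Poisson noise on both.

Parent-fraction declines are monotone anchor tables consistent with the
measured values (98-99% at 1 min falling to 25% / 13% / 7% at 180 min for
CBX / MCBX / CPFPX).

What the generator does **not** emulate: absorption or infusion kinetics
(bolus only), circadian or anesthesia effects, correlated assay drift,
nonspecific filter binding, inter-laboratory differences in counting
efficiency, or model misspecification (the in vivo truth is exactly
triexponential). Passing recovery tests therefore demonstrates estimator
correctness under the stated noise model, not robustness to structural
model error in real data.

### Self-consistency switch

The shipped profiles carry the *observed* in vivo truths, so a full
synthetic run reproduces the realistic situation in which the well-stirred
prediction underpredicts slightly (AFE < 1). For pipeline validation,
`self_consistent_profile()` replaces the in vivo clearance truth with the
profile's own forward prediction (rescaling the terminal half-life to keep
the macroconstant identities intact); with noise off, the end-to-end run
then returns AFE = 1 and RMSE = 0 to solver tolerance.
`run_ivive(mode = "synthetic")` uses self-consistent profiles by default.

## Problem sizes and reproducibility

The test suite and the acceptance script regenerate everything they check:
depletion Monte-Carlo checks use 50 seeds of triplicate assays; parameter
recovery uses 8-animal studies over 10 seeds per compound; the
mean-vs-individual clearance deviation is summarized as a median over
30 seeded studies (3 profiles × 10 seeds); fitter-vs-oracle comparisons use
10 seeded single-animal curves against a 200-restart oracle. These sizes
give stable medians while keeping a full run in well under a minute for the
script and about half a minute for the test suite. Every random draw is
controlled by an explicit seed argument; re-running any pipeline
configuration with the same seed reproduces output files byte for byte.

## Known limitations

* The lipophilicity relationship for $f_{mic}$ is an empirical model for
  neutral/basic compounds; it is not validated for acids.
* Only the well-stirred liver model is provided (no parallel-tube or
  dispersion models), and only monoexponential depletion kinetics (no
  Michaelis-Menten saturation or biphasic depletion).
* Blood/plasma ratio is fixed at 1 by default — appropriate for neutral
  xanthines that do not partition into erythrocytes.
* Terminal-phase parameters from individual noisy curves are intrinsically
  imprecise; prefer the mean-curve estimates, as the reporting functions
  do.
* The free-fraction module assumes no nonspecific device binding.
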