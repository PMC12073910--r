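---
title: "Modelling metabolite diffusion decays and their age trajectories with dmrsage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metabolite diffusion decays and their age trajectories with dmrsage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrsage)
```

## The problem

Diffusion-weighted MR spectroscopy (dMRS) measures how brain *metabolites*
— rather than water — diffuse. Because tNAA, tCho and tCr are almost purely
intracellular, their apparent diffusion properties report on the
intracellular microenvironment of neurons (tNAA), glia (tCho) or both
(tCr), which water diffusion MRI cannot separate. `dmrsage` implements the
complete quantitative chain for a cross-sectional aging analysis of such
data: forward signal models, bounded nonlinear fitting with b-range and
exclusion rules, a simplified transient-level quality-control stage, a
synthetic cohort generator, and the age-trajectory statistics.

The acquisition design the package emulates is a six-b-value tetrahedral
protocol, `b` = 0.01, 1.012, 4.03, 9.06, 16.09, 25.1 ms/µm², four
tetrahedral gradient directions, 24 transients per condition, with signal
amplitudes quantified per condition and then direction-averaged. Units
throughout: b in ms/µm², diffusivities in µm²/ms.

## Signal models

Four models map parameters to the normalized direction-averaged decay
S(b)/S0:

* **Monoexponential**: S = exp(−b·ADC), the Gaussian regime; by convention
  fitted only at b < 5 ms/µm².
* **Kurtosis representation**: S = exp(−b·ADC + b²·ADC²·K/6), the
  second-order cumulant expansion; fitted at b < 10 ms/µm². It is only
  meaningful below its turnover b* = 3/(ADC·K); evaluation beyond b* warns.
* **Astro-sticks**: molecules confined to randomly oriented thin segments
  ("sticks") with intra-stick axial diffusivity Dintra. The powder average
  has the closed form S = (√π/2)·erf(√(b·Dintra))/√(b·Dintra); below
  b·Dintra = 10⁻⁶ a four-term Taylor series avoids the 0/0.
* **Modified astro-sticks**: the stick diffusivity acquires a b-dependence
  through an intra-neurite kurtosis term,
  Deff(θ) = Dintra·(1 − Kintra·Dintra·b·cos²θ), and the powder average
  ∫₀¹ exp(−b·Deff·cos²θ) d cosθ is evaluated by fixed-order Gauss–Legendre
  quadrature (order 64; an order-doubling check must agree within 10⁻⁸ or
  the evaluation errors out).

The Kintra convention follows the literal effective-diffusivity form above
with **no** 1/6 factor inside Deff; the standard cumulant convention would
insert one and rescale Kintra by 6, but the reference parameter values this
package ships were produced under the literal form, so that form is kept.

Two analytic facts anchor the test suite. First, the orientation average of
D_app = Dintra·cos²θ with cosθ uniform on [0, 1] gives the small-b moments
ADC → Dintra/3 and K → 12/5, independent of Dintra; kurtosis fits of
noiseless stick decays approach these values as the b-grid shrinks. Second,
at large b·Dintra the powder-averaged stick signal scales as b^(−1/2), so
the log–log slope between the two highest protocol b-values approaches −1/2
from above. Note the approach is slow: the slope is −0.499 at
Dintra = 0.40 but only −0.478 at Dintra = 0.20 (where b·Dintra is just 3.2
at b = 16.09), so the −1/2 signature should be read as an asymptotic
statement, not a finite-b identity.

When Kintra·Dintra·b > 1 the effective diffusivity is negative near
cosθ = 1. The parameter region is reachable within the permitted bounds, so
the signal is still computed as written but flagged invalid, and the
fitting layer replaces the objective with a smooth penalty proportional to
the constraint excess — the optimizer is pushed back into the physical
region rather than silently exploring an amplifying exponential.

## Fitting

Each model is fitted by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) minimizing the unweighted residual between measured
amplitudes and S0·model(b, θ) over the model's b-range. Choices that the
problem leaves open, and how they are resolved here:

* **S0** is a free positive nuisance scale rather than the b = 0.01
  amplitude, so that single point's noise does not propagate into every
  residual.
* **Bounds**: diffusivities in [10⁻⁶, 1.0] µm²/ms (free-diffusion ceiling,
  strict positivity), kurtosis parameters in [0, 3.0].
* **Initialization**: ADC from a log-linear fit of the two lowest-b points;
  kurtosis starts from the monoexponential solution with K = 1;
  astro-sticks at 3×ADC (inverting the small-b relation); modified
  astro-sticks from the astro-sticks solution with Kintra = 0.05. Five
  seeded random restarts within the bounds guard the shallow
  kurtosis/Kintra degeneracy; the best objective is kept, so a fit is
  deterministic given data, spec and seed.
* **Uncertainties** come from the usual linearized covariance
  s²(JᵀJ)⁻¹ with a central-difference Jacobian at the solution.
* **At-bound flagging**: an estimate within 10⁻⁴ (native units) of its
  lower bound is flagged `at_lower_bound`; such values are the ones the
  exclusion filter later removes. The tolerance absorbs float fuzz while
  being far below any scientifically meaningful estimate.

Brute-force grid searches over the bounded parameter plane (with S0
profiled analytically) serve as the independent objective oracle in the
tests: the optimizer's minimum must never exceed the grid minimum.

## Transient quality control

The spectral stage is a deliberately simplified stand-in for full spectral
quantification: synthetic single-resonance Lorentzian spectra (bandwidth
3000 Hz, 2048 complex points) stand in for metabolite peaks, and windowed
peak integration stands in for basis-set fitting. This is adequate here
because the downstream pipeline consumes only peak areas. Consequences:
multi-metabolite spectral overlap, macromolecule baselines and lineshape
distortions are *not* emulated, and passing QC tests say nothing about
quantification accuracy on crowded in-vivo spectra.

Per transient, a single global phase and a frequency shift are estimated
from the reference (NAA, 2.01 ppm) peak. The peak is located coarsely on a
4× zero-filled spectrum and refined by maximizing the modulus of a mildly
apodized (5 Hz Lorentzian) continuous DTFT — the apodization acts as an
approximate matched filter and halves the frequency noise; for clean data
the refinement is exact to machine precision, so already-aligned transients
pass through unchanged. Transients whose reference peak does not reach 3×
the spectral noise SD are marked uncorrectable. Within each (b, direction)
condition, transients whose peak amplitude falls below
median − 2.5×MAD are discarded (the threshold rule and constant are an
invented, configurable policy; only the existence of such a step is given).
Kept transients are averaged, the real part is integrated over each
metabolite window (default half-width 0.09 ppm — the widest symmetric
choice that keeps the tCr and tCho windows, 0.19 ppm apart, disjoint), and
areas are direction-averaged into decay curves with SE = SD/√n across
directions.

One subtlety worth recording: phasing each transient so its noisy peak
maximum is real-positive rectifies noise at the peak bin, a small positive
bias of order 1/(2·SNR²) that grows toward the highest b-values. At the
emulated SNR (≈ 6–7 at b_max) this is ≈ 1 % of the windowed area and is one
reason QC-corrected curves are compared against ground truth *relative* to
their own b ≈ 0 point in the tests.

## The synthetic cohort generator

The generator defines the study conditions everything else is tested
under; its defaults are fixed once:

* 25 subjects, ages uniform on 25–80 years, two regions (cerebellum, PCC),
  three metabolites.
* Ground truth: astro-sticks decays at the cohort-average reference
  diffusivities (cerebellum tNAA/tCho/tCr 0.346/0.325/0.287; PCC
  0.440/0.407/0.440 µm²/ms); age slopes default to zero — the null
  configuration.
* Area noise: Gaussian relative error interpolating linearly in b from 3 %
  at b ≈ 0 to the region- and metabolite-specific values at b_max
  (cerebellum 4/6/4 %, PCC 7/10/5 %), applied per direction before
  direction-averaging. Area-level noise is Gaussian, not Rician: it stands
  in for spectral-fit amplitude estimates, which are approximately Gaussian
  at these precisions; complex transient-level noise is Gaussian per
  channel.
* Tissue fractions: Gaussian draws around cerebellum fGM/fWM/fCSF
  0.82/0.12/0.06 (SD 0.05/0.05/0.03) and PCC 0.69/0.14/0.17
  (SD 0.07/0.03/0.08), renormalized to sum to one; the fGM mean carries a
  linear age trend of −17 % (cerebellum) or −4 % (PCC) across the age
  range, producing the corresponding decline in the fGM/fWM ratio.
* Transient-level spectra: Lorentzian singlets at 2.01/3.03/3.22 ppm,
  ≈ 4.6 Hz linewidth, target spectral SNR 18–24 at b ≈ 0 (falling naturally
  with the model attenuation to ≈ 6–7 at b_max), optional per-transient
  phase jitter, frequency drift and amplitude corruption (halving) to
  emulate motion.
* Determinism: every substream (ages, sexes, fractions, curves, transients)
  derives its seed from the master seed and integer indices via fixed
  modular arithmetic, so cohorts are bit-reproducible at every granularity.

What the generator does **not** emulate: direction-dependent b-value
jitter is off by default (it is below 3 % in the emulated protocol),
cardiac pulsation, field drift over the session, eddy-current distortions
and partial-volume spectral contamination. Recovery results on this
generator therefore demonstrate correctness of the estimation chain, not
robustness to every in-vivo artifact.

## Age-trajectory statistics

For each (region, metabolite, model, parameter) cell, after removing
estimates flagged at the lower bound (they are unreliable by construction —
a vanishing kurtosis estimate mostly encodes noise, not biology):

1. **Univariate OLS** of the estimate on age, with the two-sided slope
   p-value (t, n−2 df) and 95 % confidence and prediction bands evaluated
   on a 100-point age grid.
2. **Covariate regression** y ~ β0 + β1·age + β2·fGM/fWM, per-coefficient
   p-values (t, n−3 df), uncorrected. An exactly collinear design is
   reported as not analyzable together with its condition number.
3. **Young/old comparison**: two-sample t-test between age < 50 and
   age ≥ 50 (the boundary age joins the older group). The default is
   Welch's unequal-variance test — the source material is contradictory on
   independent vs paired, and with unequal group sizes and no pairing
   structure only an independent test is defined; the pooled Student
   variant is a flag away. Bonferroni control is applied to the t-tests
   only, with m = 2 regions × 3 metabolites = 6 per diffusion metric
   (threshold 0.05/6 ≈ 0.0083, strict inequality).

All regressions and t-tests are delegated to `stats::lm` / `stats::t.test`;
the test suite verifies them against hand-written normal-equation and
Welch–Satterthwaite arithmetic to 10⁻¹⁰, and checks the empirical size of
the slope test against its binomial sampling band on 400–500 null cohorts.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use problem sizes chosen to
make each check statistically meaningful at interactive runtimes: 10×10
(b, Dintra) grids with 2×10⁵ Monte-Carlo orientation samples per point
(MC standard error ≈ 5×10⁻⁴, so a 3-SE agreement check is sharp), 200
noise replicates for recovery bias, 400–500 cohorts for test-size checks,
and the full 25-subject × 2-region × 3-metabolite × 4-model grid for the
end-to-end null run. Gauss–Legendre order 64 is far into the converged
regime for every b·Dintra the protocol reaches (the order-doubling check
sits at machine precision); `optimize` tolerances of 10⁻⁷ Hz in the peak
refinement are similarly far below the 0.2 Hz accuracy the QC stage needs.

## Known limitations

* The kurtosis representation is fitted on four b-values spanning
  0.01–9.06 ms/µm²; its finite-b estimates are systematically below the
  small-b limit (for a noiseless stick decay with Dintra = 0.45 the global
  minimizer has K ≈ 1.66 versus the b→0 value 2.4). This is a property of
  the representation on this grid, verified against a brute-force grid
  search, and should be kept in mind when comparing K across protocols.
* Windowed peak integration underestimates total peak area by the
  truncated Lorentzian tail fraction (≈ 11 % at ±0.1 ppm for a 4.6 Hz
  line); this cancels in normalized decays but matters for absolute
  quantification, which this package does not attempt.
* No diffusion-time dependence, finite stick radius, exchange or explicit
  cell geometries; the stick models are apparent-parameter descriptions.
* Sex is recorded but never modelled, mirroring the analysis design.
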