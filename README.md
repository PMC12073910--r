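# dmrsage

Diffusion-weighted MR spectroscopy (dMRS) signal models and age-trajectory
analysis of brain metabolites.

dMRS measures the diffusion of intracellular metabolites — tNAA (neuronal),
tCho (glial), tCr (both) — rather than water, giving cell-type-specific
access to brain microstructure. `dmrsage` is a tested, reusable
implementation of the full analysis chain for a cross-sectional aging
study of metabolite diffusion in two regions (cerebellar cortex and
posterior cingulate cortex, PCC) on a six-b-value tetrahedral protocol
reaching b = 25.1 ms/µm²:

* **Forward models** — monoexponential S = e^{−b·ADC}; kurtosis
  representation S = e^{−b·ADC + b²ADC²K/6}; the powder-averaged
  **astro-sticks** model S = (√π/2)·erf(√(b·D_intra))/√(b·D_intra); and a
  **modified astro-sticks** model with an intra-neurite kurtosis term,
  D_eff(θ) = D_intra(1 − K_intra·D_intra·b·cos²θ), integrated over
  orientations by Gauss–Legendre quadrature. A seeded Monte-Carlo powder
  average serves as a brute-force oracle.
* **Fitting** — bounded Levenberg–Marquardt least squares with a free S0
  scale, the per-model b-range rules (b < 5 for the monoexponential,
  b < 10 for kurtosis, all b for the stick models), bounds (diffusivities
  ≤ 1.0 µm²/ms, kurtosis ≤ 3.0), multi-start initialization, and
  at-lower-bound flagging.
* **Transient QC** — per-transient zero-order phase and frequency-drift
  correction on the 2.01 ppm reference peak, median−2.5·MAD peak
  thresholding per diffusion condition, averaging, windowed peak-area
  quantification and direction averaging.
* **Synthetic cohorts** — protocol-matched decay curves and
  transient-level Lorentzian spectra with configurable age trends,
  region-specific tissue fractions and noise matched to reported spectral
  precision (CRLB 3–10 %, SNR ≈ 18–24 at b≈0).
* **Age trajectories** — per-cell OLS with 95 % confidence and prediction
  bands, multivariate regression y ~ β0 + β1·age + β2·fGM/fWM, Welch
  young/old (age < 50 vs ≥ 50) t-tests with Bonferroni control
  (0.05/6 ≈ 0.0083), and lower-bound exclusion filtering.

## Worked example

Simulate one noisy cerebellar tNAA decay at the protocol's noise level and
fit the astro-sticks model:

```r
library(dmrsage)
p  <- dmrs_protocol()            # b = 0.01 ... 25.1 ms/um^2, 4 directions
cv <- generate_decay("astrosticks", c(Dintra = 0.346), p,
                     crlb_b0 = 0.03, crlb_bmax = 0.04, seed = 1,
                     metabolite = "tNAA", region = "cerebellum")
fit_model(cv, fit_spec("astrosticks"), seed = 1)
#> dmrs_fit [astrosticks]
#>        estimate   stderr at_lower_bound
#> S0       0.9977 0.004879             NA
#> Dintra   0.3354 0.006725          FALSE
```

The generating diffusivity 0.346 µm²/ms is recovered as 0.335 ± 0.007 from
a single noisy curve. The stick signature is visible in the high-b decay:

```r
highb_loglog_slope(c(16.09, 25.1), "astrosticks", 0.4)
#> [1] -0.4993          # the characteristic b^(-1/2) powder-average scaling
```

A full null cohort (25 subjects, ages 25–80, zero age slopes), fitted and
pushed through the trajectory statistics:

```r
cfg   <- cohort_config(seed = 42)
rec   <- generate_cohort(cfg)
tab   <- fit_cohort(rec, seed = 1)
suite <- run_trajectory_suite(tab, cohort_fractions(rec))
head(suite$grid[suite$grid$model == "astrosticks",
                c("region", "metabolite", "parameter", "slope",
                  "slope_p", "t_p", "t_significant", "n_used")])
#>        region metabolite parameter     slope slope_p   t_p t_significant n_used
#> 1  cerebellum       tCho    Dintra -2.31e-04   0.272 0.276         FALSE     25
#> 7  cerebellum        tCr    Dintra -6.25e-06   0.965 0.946         FALSE     25
#> 13 cerebellum       tNAA    Dintra  2.15e-05   0.869 0.746         FALSE     25
#> 19        PCC       tCho    Dintra  1.01e-04   0.710 0.860         FALSE     25
#> 25        PCC        tCr    Dintra  1.35e-04   0.637 0.865         FALSE     25
#> 31        PCC       tNAA    Dintra -2.83e-04   0.260 0.419         FALSE     25
suite$threshold
#> [1] 0.008333
```

No cell is significant at the corrected threshold — the expected null
pattern. `plot(suite$cells[["cerebellum/tNAA/astrosticks/Dintra"]])` draws
the scatter with the OLS line and both 95 % bands.

A thin command-line wrapper is installed under `inst/cli/`:

```sh
Rscript inst/cli/dmrsage.R simulate     --out cohort.csv --seed 42
Rscript inst/cli/dmrsage.R fit          --in cohort.csv --out table.csv
Rscript inst/cli/dmrsage.R trajectories --in table.csv \
        --fractions cohort.csv.fractions.csv --out grid.csv
Rscript inst/cli/dmrsage.R report       --in grid.csv --out report.md
```

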