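# isebayes

Bayesian calibration and quantification for ion-selective electrodes
(ISEs), aimed at low-cost nitrate (NO3-) and ammonium (NH4+) monitoring in
soil extracts and natural waters.

ISEs respond to the logarithm of ion activity through the
Nikolsky-Eisenman equation,

    E = E0 + S * log10(a + K_bg),

with standard potential `E0` (mV), slope `S` (mV/decade, ~ ±59.2 for
monovalent ions at 25 °C in the ideal Nernstian case), and an interference
background `K_bg = Σ_J Kpot_IJ * a_J^(zI/zJ)` (mol/L) that flattens the
response near the detection limit. Conventional practice fits a straight
line to the Nernstian region, discards everything near the detection
limit, and reports no uncertainties. `isebayes` instead:

* fits the full nonlinear response per electrode — and jointly for
  multi-electrode arrays — by MCMC (JAGS via rjags), with weakly
  informative priors and convergence gating on split R-hat;
* estimates sample concentrations per posterior draw, by **direct
  potentiometry** (inverting the fitted curve, pooling electrodes weighted
  by their fitted precision, with an explicit uncertainty budget for
  baseline drift) and by **standard addition** (spike series with a free
  per-series baseline, so occasion drift cancels exactly), reporting
  posterior medians with central 50%/95% credible intervals in log10 molar
  and ppm;
* computes detection limits with uncertainty: the classical IUPAC
  intersection limit (identically the fitted background), the traditional
  10× limit of quantification, and a detection-theoretic Bayesian limit
  `K_bg * (10^((z_{1-a}+z_{1-b})σ/|S|) - 1)`;
* provides the method-comparison statistics used to validate such sensors
  (Pearson r with p-value, extraction recovery, mean absolute log10
  residuals, credible-interval width comparisons) and a synthetic-data
  generator for calibration series, drifting sample readings,
  standard-addition series and paired comparison tables.

## Worked example

Calibrate a simulated four-electrode ammonium array, then measure a
drifting 1e-4 M sample both ways:

```r
library(isebayes)

arr  <- simulate_array(array_spec(), seed = 1)
cal  <- simulate_calibration(arr, calibration_design(), seed = 2)
post <- fit_array(cal, settings = mcmc_settings(seed = 1), analyte = analyte_nh4())

detection_limit_report(post)[, c("limit", "median_M", "median_ppm", "display_ppm")]
#>      limit median_M median_ppm display_ppm
#>   LOD_1969  3.2e-06     0.0572        0.06
#>        LOQ  3.2e-05     0.5724        0.60
#>  LOD_Bayes  5.3e-07     0.0095        0.01

drift <- drift_model("occasion_offset", 10)      # 10 mV baseline drift
sam <- simulate_sample_emfs(arr, drift, 1e-4, seed = 3)
sa  <- simulate_sa_table(arr, default_sa_schedule(), 1e-4, drift, seed = 3)
dp_est <- estimate_direct(post, sam, drift_sd = 10, seed = 4)
sa_est <- estimate_standard_addition(post, sa, seed = 5)
#>          mode est_log10M q2.5_log10M q97.5_log10M est_ppm censored
#>        direct      -4.01       -4.27        -3.73    1.77    FALSE
#>  std-addition      -4.01       -4.04        -3.97    1.78    FALSE
```

Both modes recover the true 1e-4 M (1.8 ppm NH4+), but the direct
estimate must budget ±0.27 decades for drift it cannot correct, while the
standard-addition interval is ~7× narrower because the spike differences
cancel the baseline. The detection-limit table shows the classical limit
at the fitted background (~3e-6 M, 0.06 ppm at one significant figure)
and the Bayesian limit well below it — the sub-LOD region a nonlinear fit
can still use.

## Analysis workflow

The numbered drivers under `analysis/` walk the full study pipeline and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R           # synthetic array, calibration, samples, comparisons
Rscript analysis/02_calibrate.R          # joint array fit + diagnostics
Rscript analysis/03_quantify.R           # DP vs SA estimates against known truths
Rscript analysis/04_detection_limits.R   # LOD_1969 / LOQ / Bayesian LOD per electrode
Rscript analysis/05_method_comparison.R  # recovery, correlation, drift studies
```

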