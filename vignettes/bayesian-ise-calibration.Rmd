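---
title: "Bayesian calibration and quantification for ion-selective electrodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian calibration and quantification for ion-selective electrodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isebayes)
```

## The measurement problem

Ion-selective electrodes (ISEs) are cheap, field-deployable sensors for
ions such as ammonium (NH4+) and nitrate (NO3-) in soil extracts and
natural waters. The measured cell potential (emf, in mV) follows the
Nikolsky-Eisenman response

$$E = E^0 + S \, \log_{10}\!\left(a_I + K_{bg}\right),$$

where $a_I$ is the primary-ion concentration (mol/L; a constant
ionic-strength extractant background lets us absorb activity coefficients
into $E^0$ -- see *Assumptions*), $S$ is the response slope in mV per decade
(theoretically $2.303\,RT/z_IF \approx \pm 59.2$ mV/decade for monovalent
ions at 25 °C; real electrodes are often sub-Nernstian), and
$K_{bg} = \sum_J K^{pot}_{I,J} a_J^{z_I/z_J}$ is the summed interference
background that flattens the response at low analyte levels. Classical
practice fits a straight line to the Nernstian region only, discards
readings near the detection limit, and reports no uncertainty for the
slope or the detection limit. This package instead treats calibration as a
Bayesian nonlinear regression, keeps the entire response curve, and
propagates all parameter uncertainty into concentration estimates and
detection limits.

## The calibration model

For each electrode $j$ with calibration readings $(x_{ij}, y_{ij})$
($x$ = log10 of the known concentration step, $y$ = emf in mV):

$$y_{ij} \sim \mathrm{Normal}\!\left(E^0_j + S_j \log_{10}(10^{x_{ij}} +
10^{\kappa_j}),\ \sigma_j\right),$$

with $\kappa_j = \log_{10} K_{bg,j}$. Priors (defaults, all overridable
via `prior_spec()`):

* $E^0_j \sim$ Normal(mean of the electrode's observed emf, 1000 mV) --
  weakly informative, dominated by any 4-point dataset;
* $S_j \sim$ Normal(theoretical Nernstian slope for the analyte, 10
  mV/decade) -- the prior mean carries the analyte charge's sign, so anion
  electrodes need no separate code path;
* $\kappa_j \sim$ Uniform(lowest calibration step $-$ 3, highest step) --
  the background is parameterised on the log10 scale for positivity and
  scale invariance;
* $\sigma_j \sim$ half-Cauchy(2 mV), truncated below at 0.001 mV. The
  truncation is a negligible physical floor that keeps the posterior proper
  when data are (numerically) noise-free.

Electrodes are modelled with independent parameters but sampled jointly in
one model (`fit_array()`), because pooling happens at the
sample-estimation stage, not by hierarchical shrinkage across electrodes.
Sampling uses JAGS (via rjags), two chains by default. Internally the
sampler works with the curve height at the centre of the calibration range
rather than $E^0$ itself; the two are deterministically related, and the
centred parameterisation removes the strong intercept-slope correlation
that otherwise stalls one-parameter samplers. Convergence is gated on
split R-hat $\le$ 1.05 with one automatic retry at doubled warmup; a
failure after the retry raises an error carrying the R-hat table.
Constant (zero-variance) chains yield `NA` R-hat rather than an error.

## Concentration estimation

Everything downstream consumes the posterior draws. For a sample measured
on one or more electrodes, each posterior draw $d$ produces one
concentration value, and the draws are summarised by the posterior median
and central 50%/95% credible intervals (reported on the log10 molar scale
and in ppm, where ppm means mg of the *ion* per litre:
$c \cdot M \cdot 1000$).

**Direct potentiometry** (`estimate_direct()`): within draw $d$, the
estimate maximises the joint Normal likelihood of the sample's readings
given that draw's electrode parameters, a single shared concentration, and
electrodes weighted by $1/\sigma_{d,e}^2$ -- noisy electrodes contribute
less, exactly the "automatic weighting" a multi-electrode array should
give. So that the spread of the per-draw values is a genuine posterior
uncertainty rather than only calibration-parameter scatter, each draw sees
the readings perturbed by its own noise level (and by a shared
baseline-drift offset when a drift scale is declared, below). In the
Nernstian (linear) limit this is exactly sampling from the concentration
posterior under a flat log10 prior; in the curved region it is a
first-order approximation to it. This two-stage scheme (calibrate, then
measure) deliberately does not feed sample readings back into the
calibration -- it matches the workflow in the field and keeps estimation
embarrassingly parallel across samples; it is an approximation to a full
joint posterior over calibration and samples.

One design choice deserves emphasis: a plain per-draw *maximisation*
(no perturbation) makes the interval width reflect calibration uncertainty
only, about 0.02-0.04 decades in the working scenario. That is several
times smaller than the error actually induced by 1 mV of reading noise
(about 0.018 decades per electrode) and an order of magnitude smaller than
drift-induced errors, so such intervals would be badly anti-conservative.
The perturbed variant restores calibrated coverage while keeping the
spec of the two-stage workflow intact.

**Baseline drift.** Electrode baselines ($E^0$) shift between measurement
occasions -- in harsh matrices like soil extracts, by many mV. Direct
potentiometry cannot correct this, only budget for it: `drift_sd` (mV)
enters the per-draw perturbation as an offset shared within each
electrode-occasion, widening the intervals honestly. The default is 0;
the drift studies declare the 10 mV scale they simulate.

**Standard addition** (`estimate_standard_addition()`): the sample is
measured before and after spiking known volumes of standard; the cell
concentration after $k$ spikes follows total-mass bookkeeping
(`volume_corrected_conc()`). Per draw, the initial concentration
maximises the joint likelihood of each electrode's series with a *free
baseline offset per electrode-series*, profiled out by mean-centring the
series -- any occasion-specific $E^0$ shift cancels exactly, which is the
classical reason standard addition is drift-immune. Slope, background and
noise are taken from the calibration draws, not re-estimated in-sample, so
systematic drift in parameters other than the baseline is *not* corrected.
The closed-form single-spike estimator (`classical_standard_addition()`)
serves as an independent oracle in the tests.

**Censoring.** A reading at or below the blank response carries no
information about how far below background the sample lies. Per draw, the
analytic criterion is the sign of the likelihood gradient as the
concentration tends to zero; draws that fail it are pinned at the draw's
background level (an upper-bound-style value), and a sample whose draws
censor in the majority is flagged `censored` rather than raising an error.
Censored estimates are excluded (with a count) from residual and
correlation statistics.

**Numerics.** The per-draw maximisation is a vectorised golden-section
search over log10 concentration (bracket $[-14, 2]$ for direct
potentiometry, $[-12, 1]$ for standard addition, 70 iterations, i.e.
bracket widths below 1e-12 decades), run simultaneously across all draws.
The objective is a sum over electrodes of smooth unimodal terms; with
mutually consistent readings the pooled objective is unimodal in
practice. Ties cannot occur with continuous draws.

## Detection limits

Three limits, each computed per posterior draw and summarised with a 95%
interval:

* **LOD1969** (`lod_iupac()`): the classical IUPAC ISE limit, the
  intersection of the extrapolated Nernstian line with the flat blank
  response. For the Nikolsky-Eisenman curve this intersection is *exactly*
  $a = K_{bg}$, so the classical limit is the fitted background, draw for
  draw.
* **Traditional LOQ** (`loq_traditional()`): $10 \times$ LOD, in whatever
  unit the LOD is supplied.
* **Bayesian LOD** (`lod_bayesian()`): the smallest concentration whose
  mean response is distinguishable from the blank with false-positive rate
  $\alpha$ and false-negative rate $\beta$ under the draw's noise:
  $K_{bg}\,(10^{(z_{1-\alpha}+z_{1-\beta})\sigma/|S|} - 1)$, defaults
  $\alpha = \beta = 0.05$. This closed form is this package's
  operationalisation of a detection-theoretic ISE limit (the literature
  source behind the idea does not print its estimator); it is labelled as
  such, reduces to 0 as $\sigma \to 0$, and sits below LOD1969 whenever
  $(z_{1-\alpha}+z_{1-\beta})\,\sigma/|S| \le \log_{10} 2$ -- which holds
  comfortably in the working scenario (1 mV noise, ~57 mV/decade).

ppm limits are conventionally displayed at one significant figure
(`signif_limit()`). Note one unit subtlety: with the NH4+ ion mass
(18.04 g/mol), 5.3e-6 M converts to 0.096 ppm, which displays as 0.1 ppm;
reports that print 0.09 ppm for that molarity have implicitly used the
NH3 mass (~17 g/mol). This package always uses the ion's own mass and
documents the discrepancy rather than silently switching masses.

## The synthetic-data generator

No raw emf data are deposited with the study this package operationalises,
so `simulate_*()` generators stand in for them, and they are first-class,
tested code. The default scenario -- the study conditions, chosen once:

* 4 electrodes; $E^0 \sim$ Normal(200, 5) mV; slope $\sim$ Normal(57, 2)
  mV/decade (slightly sub-Nernstian, as real nitrate/ammonium electrodes
  are); $\log_{10} K_{bg} = -5.5$ (fixed), putting LOD1969 near
  $3 \times 10^{-6}$ M, the reported order of magnitude; reading noise 1 mV.
* Calibration: 9 half-decade steps, 1e-6 to 1e-2 M, one reading per step.
* Drift: independent per electrode and occasion, Normal(0, 10 mV) -- large
  enough that uncorrected direct potentiometry errs by up to half an order
  of magnitude, the regime the study describes.
* Standard addition: two 1-mL spikes of 0.01 M standard into 100 mL
  (roughly doubling then tripling a 1e-4 M sample, ~17 mV steps).
* Method-comparison tables: 11 paired samples across two decades, 98%
  relative recovery of method B, 5% relative measurement noise.

Generators are pure functions of (spec, seed): they save and restore the
global RNG state, and identical inputs give identical tables. What they do
*not* emulate: ion-specific activity coefficients, temperature drift,
electrode ageing/hysteresis, correlated interference from a real soil
matrix, or heavy-tailed noise. Passing tests therefore demonstrate that
the statistical machinery is correct and calibrated *under the stated
generating model*, not that any particular field electrode meets these
numbers.

## Simulation studies and problem sizes

Two seeded studies quantify the headline comparisons, at sizes chosen to
estimate stochastic quantities to a few percent while keeping a complete
run in minutes on one CPU:

* `width_reduction_study()`: per seed, a fresh array and calibration, then
  20 samples at 1e-4 M under drift, estimated by single-ISE direct
  potentiometry and by 4-ISE standard addition; reports the percent
  reduction in mean 95% interval width (typically ~85-90%).
* `residual_reduction_study()`: same scenario, 12 samples spanning
  1e-5..1e-3 M, both modes using the full array; reports the percent
  reduction in mean absolute log10 residual (typically ~65-75%, i.e.
  standard addition removes well over half of the drift-induced error,
  consistent with the reported "over 50%" improvement).

MCMC defaults: 2 chains, 1000 warmup + 1000 retained draws per chain --
ample for a 4-parameter-per-electrode model whose effective sample sizes
land in the hundreds.

## Known limitations

* The per-draw estimator is a cut (two-stage) posterior: sample readings
  never inform the calibration parameters. This is intended, but it means
  pathological samples cannot flag a broken calibration.
* The drift budget for direct potentiometry must be declared by the
  analyst; the package does not estimate drift from single-occasion data
  (it is not identifiable there).
* Standard addition assumes accurately known volumes and standard
  concentration; volumetric error is not modelled.
* `fit_array()` treats electrodes independently; a hierarchical variant
  (shrinkage across electrodes) is out of scope.
* Correlations in method-comparison statistics are computed on the raw
  concentration scale by default, matching the linear axes of conventional
  method-comparison plots; a log option exists (`pearson_with_p(log =
  TRUE)`) and is the better choice when values span many decades.

## Reproducing the study-scale numbers

`scripts/acceptance.R --seed <int> --out <path>` reruns both drift studies
at 10 replicates each and writes the two reduction percentages as JSON.
The numbered drivers under `analysis/` walk the same pipeline step by
step (simulate, calibrate, quantify, detection limits, method comparison)
and write their tables under `results/`.
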