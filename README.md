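# clquant

Quantification of intracellular chloride in sensory neurons from
fluorescence-quenching imaging, and of its downstream physiological and
behavioral consequences.

Peripheral sensory neurons (trigeminal and dorsal root ganglia) accumulate
Cl⁻ above electrochemical equilibrium via the NKCC1 cotransporter. Whether
opening a chloride channel then *depolarises* a neuron (amplifying its
response) or hyperpolarises it depends on where its resting [Cl⁻]ᵢ sits
relative to the critical concentration at which the chloride reversal
potential E_Cl equals the resting membrane potential. `clquant` is a
tidyverse-native R package for the full analysis chain around that
question:

* **Stern–Volmer calibration** — per-cell fits of the quenching relation
  F₀/F = 1 + K_sv·[Cl⁻] from double-ionophore calibration recordings
  (steady states at defined 0/20/40/60 mM steps), and inversion of resting
  MQAE fluorescence to [Cl⁻]ᵢ with quality flags.
* **Nernst equilibrium** — E_Cl = s·log₁₀([Cl⁻]ᵢ/[Cl⁻]ₒ), the critical
  concentration c* = [Cl⁻]ₒ·10^(V/s), driving force, and the predicted
  efflux-competent population fraction Φ((μ−c*)/σ).
* **Response classification** — 10-frame baselines, ΔF in % of baseline,
  and the 4σ rule assigning efflux / influx / none from the signed ΔF
  extremum (MQAE brightens as chloride falls).
* **Fura-2 ratios** — f340/f380 traces, response amplitudes, KCl viability
  filtering.
* **Hill dose–response fitting** — EC50/IC50 and Hill coefficient by
  bounded Levenberg–Marquardt on log₁₀-midpoint, with broom-style
  `tidy()`/`glance()` and `autoplot()`.
* **Brief-access drinking analysis** — Exposure Intake Ratios
  (2nd/1st-exposure intake), concentration–avoidance curves with fitted
  EC50, and log₁₀ curve shifts between genotypes.
* **Synthetic-data generators** — seeded, ground-truth-carrying simulators
  of calibration traces, stimulation traces, dual-channel calcium traces,
  dose–response curves and drinking cohorts, so every stage is testable by
  parameter recovery.

## Worked example

Simulate a wild-type-like population, calibrate it back from its own
traces, and ask the equilibrium question:

```r
library(clquant)

cells <- sim_cell_population(population_params(n_cells = 300), seed = 42)
cal   <- sim_calibration_traces(cells, seed = 42)   # 0/20/40/60 mM steps
res   <- calibrate_cells(cal$traces, cal$protocol)
summarize_population(res$estimates)
#> # A tibble: 1 × 5
#>   mean_cl_mM sem_cl_mM     n n_clamped n_low_r2
#>        <dbl>     <dbl> <int>     <int>    <int>
#> 1       35.9      1.27   300         0        0

ctx <- equilibrium_context()   # 151 mM [Cl-]o, -54 mV RMP, 58 mV/decade
ctx
#> Equilibrium context
#>   [Cl-]o: 151 mM, RMP: -54 mV, slope: 58.00 mV/decade (fixed)
#>   critical [Cl-]i: 17.70 mM
efflux_fraction(mean = 34.1, sd = 27.6)
#> [1] 0.7238
```

The recovered population mean (35.9 ± 1.3 mM over 300 cells) matches the
generating 34.1 mM within sampling error, and at these recording
conditions any cell above 17.7 mM should respond to chloride-channel
opening with a depolarising efflux — about 72% of a Gaussian(34.1, 27.6)
population.

Classify simulated stimulus responses and check them against the
equilibrium prediction:

```r
stim  <- sim_stimulation_traces(cells, ctx = ctx, seed = 42)
calls <- classify_cells(stim$traces, stim_window = c(5, 35))
dplyr::count(calls, direction)
#> # A tibble: 3 × 2
#>   direction     n
#>   <chr>     <int>
#> 1 efflux      221
#> 2 influx       64
#> 3 none         15
```

221/300 = 74% efflux calls, against an empirical 75% of cells above the
critical concentration in this draw.

Dose–response and behavior:

```r
fit_hill(sim_dose_response(noise_cv = 0), "activation")[c("ec50", "hill_n")]
#> $ec50   24.7
#> $hill_n  2.1

wt <- sim_drinking_sessions(behavior_params(), seed = 42)
avoidance_curve(wt$sessions)
#> Avoidance curve (WT): 6 concentrations
#>   EC50: 7.26 uM (Hill n 1.52, top 1.02)
```

The noiseless Hill fit recovers its generating parameters exactly; the
11-mouse avoidance cohort recovers the generating EC50 of 6.4 µM within
its sampling spread.

## Documentation

The methods vignette
(`vignettes/chloride-quantification-methods.Rmd`) describes the models,
the numerical conventions, what the synthetic generators do and do not
emulate, and the design decisions behind the estimators.
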