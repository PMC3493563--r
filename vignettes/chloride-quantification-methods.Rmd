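---
title: "Methods: quantifying intracellular chloride and its behavioral consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying intracellular chloride and its behavioral consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clquant)
```

## The scientific problem

Sensory neurons of the trigeminal ganglion accumulate chloride above its
electrochemical equilibrium through the Na⁺-K⁺-2Cl⁻ cotransporter NKCC1.
When a chloride conductance opens (a GABA_A receptor, or a
calcium-activated chloride channel downstream of a TRPV1 response), the
direction of the resulting current depends on whether the cell's
intracellular chloride sits above or below the concentration at which the
chloride reversal potential equals the resting membrane potential. Cells
above that critical concentration depolarise by chloride efflux —
an amplifying, excitatory event; cells below it hyperpolarise. Whether a
neuron is in the efflux-competent regime is therefore a quantitative
question about [Cl⁻]$_i$, and answering it requires a calibrated optical
measurement, an equilibrium calculation, and downstream response and
behavior statistics. `clquant` implements that chain as a tested, seeded
pipeline.

## Quenching calibration (MQAE → [Cl⁻]$_i$)

MQAE fluorescence is collisionally quenched by chloride, following the
Stern-Volmer relation

$$\frac{F_0}{F} = 1 + K_{sv}\, [\mathrm{Cl}^-]$$

with $F_0$ the fluorescence at 0 mM chloride and $K_{sv}$ the quenching
constant (M⁻¹; concentrations enter in molar, converted from mM exactly
once). Calibration uses the double-ionophore protocol: with nigericin and
tributyltin in the bath, cytosolic chloride equilibrates with solutions of
defined concentration (0, 20, 40, 60 mM by default), each held to steady
state (about 10 minutes, sampled every 15 s). `detect_steady_states()`
takes the plateau as the mean of the last 20% of frames in each step;
`fit_stern_volmer()` regresses $F_0/F - 1$ on concentration *through the
origin*, because $F_0$ is a measured quantity, not a free intercept. The
per-cell resting concentration follows by inversion,
$[\mathrm{Cl}^-]_i = (F_0/F_{rest} - 1)/K_{sv}$.

Numerical conventions:

* Raw negative concentration estimates (resting fluorescence slightly above
  $F_0$, expected for noisy cells near 0 mM) clamp to 0 and are flagged
  `clamped`, never errored.
* Cells with calibration $r^2 < 0.9$ are flagged `low_r2`; flagged cells
  are excluded (and counted) in population summaries. The exclusion
  threshold is a package default — per-cell QC rules are rarely reported
  in primary papers.
* The per-step unsteadiness flag (tail slope beyond 0.05% per frame) is
  advisory metadata: with 1% frame noise and an 8-frame tail the slope
  estimator's own sampling error exceeds that tolerance, so the flag is
  meaningful for low-noise recordings and for genuinely unsettled steps
  (slow equilibration), and fits never silently drop flagged steps.
* `bleaching_check()` estimates a linear relative drift per minute on an
  unstimulated segment (default threshold 1%/min); the generators default
  to zero bleaching, mirroring control recordings in which no significant
  loss was observed.

## Equilibrium predictions (Nernst forms)

For a monovalent anion the Nernst relation gives the chloride reversal
potential and, rearranged, the critical intracellular concentration at a
given membrane potential:

$$E_{Cl} = s \log_{10}\!\frac{[\mathrm{Cl}^-]_i}{[\mathrm{Cl}^-]_o},
\qquad
c^{*} = [\mathrm{Cl}^-]_o \, 10^{V_m / s}.$$

The decade slope $s$ defaults to the conventional rounded room-temperature
constant 58.0 mV/decade, which reproduces the reference values at the
recording conditions used throughout (151 mM external chloride, −54 mV
resting potential): $c^{*} = 17.7$ mM, $E_{Cl}(34.1\,\mathrm{mM}) = -37.5$
mV, $E_{Cl}(13.2\,\mathrm{mM}) = -61.4$ mV. The physically exact slope
$2.303\,RT/F$ (58.57 mV/decade at 22 °C) is available via
`equilibrium_context(temperature_c = )` and shifts the critical
concentration to about 18.1 mM; exactly one of the two modes is active in
a context. No single slope reproduces every published reference potential
to the last digit, which is why the constant is explicit and configurable.
The efflux condition is strict (`cl_i > critical`); at equality the
driving force is zero and no efflux is predicted.

`efflux_fraction()` provides both the empirical fraction of sampled cells
above $c^*$ and the Gaussian closed form
$\Phi((\mu - c^{*})/\sigma)$; for the wild-type population parameters
(mean 34.1 mM, SD 27.6 mM) the closed form gives 0.72 — the "about 70%"
efflux-competent prediction.

## Response classification (k-sigma rule)

Traces are reduced to a baseline (mean and sample SD of the first 10
frames), a relative change series
$\Delta F_t = 100\,(F_t - \bar F)/\bar F$, and a signed amplitude: the
extremum of $\Delta F$ within the stimulus window plus a 10-s tail (the
amplitude window is a package convention; primary sources rarely state
one). A response requires $|\Delta F|$ to exceed $k = 4$ baseline SDs (in
percent units); positive amplitudes are chloride efflux for MQAE (the dye
brightens as chloride falls), negative ones influx. The sign convention
lives in one place and Fura analyses never use direction labels. Noiseless
baselines are floored at $10^{-6}$ of the baseline mean so synthetic data
cannot divide by zero. The 4σ rule is applied on relative ΔF; for a
threshold defined in multiples of the baseline SD this is equivalent to
applying it on raw fluorescence.

A note on specificity: the Bonferroni-style bound on the false-positive
rate of the extremum rule — window length × $2\Phi(-4)$ per frame — is a
statement about thresholds built from the *true* noise SD. A threshold
built from a 10-frame *estimated* SD has Student-t tails
(roughly 50× heavier at 4σ), so short baselines trade specificity for
practicality. The package's specificity test supplies the known noise SD,
isolating the thresholding rule itself; users with long quiet segments can
pass a long-baseline estimate the same way.

## Fura-2 ratio analysis

Dual-channel traces are combined as $f_{340}/f_{380}$ with an alignment
check (timestamps within half a frame) and a guarded denominator.
Amplitudes are peak ratio minus baseline mean; neuron viability is
confirmed by a depolarising KCl response (`viability_filter()`).

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every recovery claim is evaluated.

* **Population.** Resting [Cl⁻]$_i$ is drawn from a truncated Gaussian on
  [2, 110] mM (bracketing the observed single-cell range 7.8–102.1 mM).
  Because truncation shifts the mean of a Gaussian (location 34.1, scale
  27.6 on these bounds would deliver a mean near 40 mM), the sampler
  solves for the location that makes the *delivered* truncated mean equal
  `mean_cl`; the scale is kept at `sd_cl`. Population SDs are
  reconstructed from published SEMs as SD = SEM·√n (wild type 6.9·√16 =
  27.6 mM; knockout 1.1·√33 ≈ 6.3 mM). Quenching constants are Gaussian
  (14.4 ± 3.3 M⁻¹) truncated at zero; $F_0$ is log-normal with 20% CV
  (dye loading varies between cells).
* **Kinetics.** Chloride relaxes first-order toward its current target
  (bath under ionophores; the critical concentration during a stimulus)
  at 0.05 s⁻¹ by default. No kinetic constants are published for these
  responses ("short latency"); the rate only needs to settle within a
  calibration step, and plateau-based estimates are insensitive to it.
  Frame noise is multiplicative Gaussian, 1% by default.
* **Calcium transients.** The ratio transient amplitude is scaled by
  $1 + \alpha \max(0, [\mathrm{Cl}^-]_i - c^{*})/c^{*}$, a
  phenomenological chloride-dependent amplification. The default
  $\alpha = 0.652$ solves for a knockout-to-wild-type mean amplitude
  ratio of 0.615 over the two default populations, i.e. the 38.5%
  amplitude reduction observed in low-chloride neurons. There is no
  biophysical conductance model behind this — the generator emulates
  statistics of measurements, not membranes.
* **Behavior.** First-exposure intakes are log-normal around 242 µl with
  CV 0.18 (the value implied by the published intake SEM at n = 10);
  second exposures follow
  $EIR(c) = \mathrm{baseline}/(1 + (c/EC_{50})^{n})$ with unit-mean
  multiplicative noise. Defaults: wild-type EC50 6.4 µM, knockout
  17.3 µM, water-day baselines 1.11 and 1.15. The avoidance Hill
  coefficient is unpublished; 1.5 matches the steepness of the published
  mean-ratio points.
* **Seeding.** One master seed; each generator derives a named substream,
  so adding or reordering pipeline stages does not perturb other stages'
  draws. Identical seeds give bit-identical outputs.

What the generator does *not* emulate: pixel-level imaging, motion,
focal drift, heterogeneous response latencies, receptor desensitisation,
day effects in behavior, or any correlation between a cell's chloride and
its dye loading. Passing recovery tests therefore demonstrates that the
analysis inverts its own forward model under realistic noise — a
necessary condition — not that it is robust to every artefact of real
recordings.

## Dose-response fitting

`fit_hill()` fits the four-parameter Hill equation (activation
$r(c) = b + (t-b)/(1 + (EC_{50}/c)^{n})$; inhibition mirrored) by
Levenberg-Marquardt least squares, parameterised on $\log_{10} EC_{50}$
for conditioning, with the midpoint bounded within two decades of the
sampled concentrations and the Hill coefficient in (0, 10]. Initial
values: asymptotes from the response extremes, Hill coefficient 1, and
the midpoint at the geometric mean of the two concentrations bracketing
the half-range response. Standard errors are asymptotic (from the final
Jacobian), with the midpoint SE delta-transformed back to linear scale.
Non-convergence warns and flags rather than errors; flat data are a
degenerate-fit error. Parameters can be pinned (`fix =`) when an
asymptote is known, and per-point weights are supported.

## Avoidance analysis

The Exposure Intake Ratio (second-exposure intake over first-exposure
intake, per mouse) controls for between-animal differences in overall
consumption. `avoidance_curve()` summarises ratios per concentration and
fits a descending Hill curve whose midpoint is the avoidance EC50.

Design choices made where the design was genuinely open:

* **Fitting scale.** Intake noise is multiplicative, so the ratio's
  variance grows with its mean. The default fit therefore uses the
  geometric mean ratio per concentration with inverse-squared-value
  weights — equivalent, to second order, to least squares on the log
  ratio, which is homoskedastic under this noise model. In simulation at
  the study's cohort size (11 mice, 6 concentrations), this halves the
  median EC50 error relative to an arithmetic-mean fit (4.5% vs 6.6%)
  and is unbiased. Arithmetic-mean fitting with inverse-SEM² weights is
  available (`eir_scale = "linear"`) and is used automatically when any
  ratio is zero, where a geometric mean is undefined. Reported
  per-concentration summaries are always arithmetic mean ± SEM, matching
  how such curves are plotted.
* **Asymptotes.** The lower asymptote is pinned at 0 — a saturating
  aversive concentration drives intake to essentially complete refusal —
  which removes a weakly identified parameter from a 6-point design. The
  top is fitted, not fixed at the water-day ratio, because solvent-day
  and water-day baselines may differ.
* **Curve shift.** `curve_shift()` reports the direct
  $\log_{10}(EC_{50,b}/EC_{50,a})$. For midpoints 6.4 and 17.3 µM this is
  0.43; published shift values computed by other (unstated) conventions,
  such as constrained joint fits, can differ, so the package makes no
  attempt to guess one.
* **Inference.** Group-level repeated-measures statistics are delegated
  to standard routines; `eir_long_table()` emits the tidy table they
  consume.

## Problem sizes and reproducibility

The package's own verification uses: 600-cell populations for noisy
calibration recovery (population-mean sampling error ~1 mM, small enough
that the 5% recovery band tests bias rather than sampling noise), a
2000-cell run in the acceptance script for the mean quenching constant,
10,000 flat traces for classifier specificity, 100 replicates for noisy
Hill-fit bias, and 11-mouse cohorts (the study's size) for avoidance
recovery. All randomness flows from explicit seeds; re-running any
pipeline with the same configuration and seed reproduces outputs
bit-identically (the run manifest records a configuration hash for this
purpose).

## Known limitations

* The calibration model assumes ideal ionophore equilibration and a
  strictly linear Stern-Volmer relation over 0–110 mM; real dyes deviate
  at high quencher concentrations.
* The equilibrium module is single-ion Nernst; it ignores bicarbonate
  permeability of GABA_A receptors and any Goldman-Hodgkin-Katz
  multi-ion correction.
* Classification assumes stationary baseline noise; slow drifts inflate
  the effective false-positive rate beyond the analytic bound.
* The avoidance EC50 from a single 11-mouse cohort retains an honest
  sampling spread of roughly ±10–15%; claims at finer resolution need
  larger cohorts or replication.
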