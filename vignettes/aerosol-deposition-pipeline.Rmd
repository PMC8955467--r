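---
title: "Methods: aerosol spectrometry, inhaler resistance, and synthetic lung deposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aerosol spectrometry, inhaler resistance, and synthetic lung deposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerodepo)
```

## What the pipeline models

A patient inhaling through a dry powder inhaler (DPI) generates the airflow
that aerosolizes the dose. In the bench configuration this package analyzes,
a mechanical breathing simulator draws air through the device and an
upper-airway model into a lung equivalent, and an optical aerosol
spectrometer samples the airstream just below the upper airway at a constant
5 L/min — during inhalation (what enters the lung) and during exhalation
(what comes back out). The difference in particle number concentration
between the two is attributed to deposition in the lung equivalent.

The package separates cleanly into (i) exact spectrometry arithmetic on
binned counts, (ii) maneuver characterization from flow/pressure traces,
(iii) deposition accounting, (iv) the nonparametric comparison, and (v) a
calibrated synthetic generator standing in for the physical rig.

## Spectrometry arithmetic

Counts arrive on a logarithmic grid: `intervals_per_decade = 128` bins per
decade of diameter over the instrument range 0.2–10 µm. The geometric edge
progression is anchored at the lower instrument bound and the final edge is
clipped to exactly 10 µm, giving 218 bins; bins are half-open
`[lower, upper)`, so a particle at exactly 10 µm belongs to the last bin and
no count is lost at the range maximum. Bin centers are *arithmetic*
midpoints `x_i = lower_i + Δx_i/2`, even though the bins are geometric —
deliberately so, because that is the convention the downstream moment
definitions use; the geometric-mean center would shift `M1` by a factor of
about `10^(1/256)` per bin and is not what spectrometer software reports.

From counts `n_i`, the differential number distribution is
`q0(x_i) = n_i / (Σn · Δx_i)` and the mean diameter is the first moment
`M1 = Σ x_i q0(x_i) Δx_i`, algebraically identical to the count-weighted
mean of bin centers — the test suite holds the two routes together to 1e-9.
Concentrations divide counts by the sampled volume `Vm = Q·t`
(5 L/min × duration; 1 L/min = 1000/60 cm³/s). A spectrum with zero total
count yields a flagged empty distribution rather than NaN, and `M1` on it is
an error — degenerate inputs fail loudly instead of propagating.

Background correction subtracts the ambient concentration spectrum bin-wise
and clips at zero. The source procedure only states that results were
adjusted for the recorded background load; bin-wise subtraction with
clipping is the simplest estimator that cannot produce negative
concentrations. The clip introduces a small positive bias in bins where the
signal is comparable to background noise; with the default study's
signal-to-background ratio (~200:1) this is negligible.

## Maneuver characterization

DPIs follow the orifice relation `√ΔP = R·Q`. The relation is never written
out in most device tables — it is forced by the printed resistance unit
kPa^½/(L/min) — so `resistance_from_peak()` implements `R = √ΔP / PIF` and
`predicted_pressure_drop()` its exact inverse `(R·Q)²`. Recomputing the
published characterization/respiration table from its own (ΔP, PIF) pairs
reproduces seven of the eight printed four-decimal resistances; the eighth
(one respiration cell) recomputes to 0.0321 against a printed 0.0320,
consistent with rounding of unprinted raw values, and is deliberately not
forced to agree.

`extract_features()` takes peak inspiratory flow as the global maximum over
the inhalation phase (the alternative reading — flow at the instant of peak
pressure — coincides with it under the orifice relation, and is ill-defined
on noisy flutter traces), inhaled volume by trapezoidal integration of the
sampled flow (the integrator is a package choice; any quadrature consistent
with ~10 ms sampling differs negligibly), and inhalation time from the phase
bounds. Phase segmentation prefers explicit marks stored in the trace file;
otherwise it thresholds at 2 L/min with hysteresis (the phase must first
exceed 4 L/min), so capsule-flutter oscillations around the threshold cannot
split the inhalation.

## Deposition accounting

For one device, the inhalation and exhalation concentration spectra are
averaged across the repeated runs *first*, and the exhaled fraction is the
ratio of the averaged totals, `EF = 100·ΣC_ex/ΣC_in`; overall deposition is
`100 − EF` exactly. Averaging before forming the ratio matches a design in
which concentrations are averaged over the individual cycles; the per-run
ratios are also computed and reported as dispersion (median, IQR) since the
alternative order is a legitimate reading. Per-bin deposition
`100·(C_in−C_ex)/C_in` is reported only where the inhaled bin is positive
(`NA` otherwise — a bin into which nothing was inhaled has no deposition
fraction) and clipped to [0, 100] so counting noise cannot yield a nominal
negative deposition. Everything downstream of the sampling point counts as
"lung": the accounting is number-based and makes no mass or dose claim.

## Nonparametric comparison

The Kruskal–Wallis statistic uses pooled mid-ranks with the standard tie
correction `1 − Σ(t³−t)/(N³−N)` and the χ² approximation with `k−1` degrees
of freedom (critical value 3.841 at α = 0.05, df = 1). For two fully
separated groups of 12 the tie-free maximum is exactly
`H = 12/(24·25)·(78²/12 + 366²/12) − 75 = 17.28`; a published value of
17.29 for this configuration can only be software rounding, so the tests
assert 17.28 from a brute-force oracle (rank-ANOVA form, exhaustively
checked against all two-group partitions of n ≤ 8, and against
`stats::kruskal.test`). The implementation's type-I error at α = 0.05 under
a continuous null is checked empirically over 10,000 simulations at
n = 12 + 12; the χ² approximation is known to be slightly conservative or
liberal at such n, and the suite requires the empirical rate in
0.05 ± 0.01.

## The synthetic generator and its calibration

No spectra from the physical experiment are distributed, so the generator
defines the study conditions end-to-end:

* **Flow traces.** Peak inspiratory flow is resistance-limited,
  `Q_peak = √(4 kPa)/R_system`. In characterization ("bag") mode
  `R_system` is the device resistance (literature values 0.0216 / 0.0286 /
  0.0504 / 0.0313 kPa^½/(L/min)); in porcine mode a configured increment of
  0.003 is added — the airway model and lung equivalent raise every system
  resistance — and the sinusoidal ramp is replaced by a flattened
  saturating-exponential rise, emulating the compliant lung's prolonged,
  flatter profile. Capsule devices overlay a seeded 30–45 Hz flow
  oscillation (capsule flutter). Inhalation times (3.0 / 2.1 / 1.4 / 1.6 s)
  are the published per-device maneuver times. The pressure channel is
  `(R_system·Q)²`, so re-characterizing any simulated trace returns
  `R_system` exactly — a deliberate closure property the tests exploit.
* **Emitted aerosol.** Lognormal in number, integrated over the grid bins
  and renormalized to the in-range emission concentration (the spectrometer
  cannot see outside 0.2–10 µm). Geometric standard deviations of 1.8–2.0
  are typical of carrier-based DPI fines; each device's count median
  diameter is then solved so the *gridded* mean diameter lands on the
  calibration target — 2.90 µm (HandiHaler) and 0.95 µm (Turbohaler) are
  published endpoints, 2.00 µm (Breezhaler) and 1.20 µm (Ellipta) are
  interior choices consistent with the published ordering of inhaled means.
* **Upper-airway filter.** Inertial impaction scales with `d²Q`, so
  survival is a decreasing logistic in `d²Q` with midpoint at 3 µm (the
  size above which upper-airway capture dominates) at a 60 L/min reference
  flow, steepness 3. The flow applied is the mean inspiratory flow of the
  device's porcine-mode trace.
* **Lung retention.** A phenomenological U-shaped deposition curve, not an
  airway-generation transport model: survival is maximal at 0.5 µm (the
  well-known deposition minimum between diffusion- and
  sedimentation-dominated regimes) and falls off as a Gaussian in
  log-diameter with slope 0.8 per decade² below and 70 per decade² above
  the minimum. The sharp large-particle slope is what drives the exhaled
  mean diameters into the narrow 0.31–0.56 µm published window for all
  four devices simultaneously; the per-device *peak survival* is the one
  remaining free constant and is solved in closed form (the exhaled
  fraction is linear in it) so each device's expected exhaled fraction
  equals its published value — 2.13 / 2.94 / 6.22 / 10.24 %. These
  calibration constants ship as data in
  `inst/extdata/study_config.yaml`, not as code.
* **Noise.** Counting is Poisson with mean `(expected + background)·Vm`; no
  inter-run variance beyond Poisson is added because none is published —
  run-level dispersion of the synthetic study is therefore narrower than a
  physical instrument's, and run-dispersion checks are deliberately soft.
  The ambient background is a 10 particles/cm³ lognormal (0.3 µm, GSD 2.0)
  measured for 60 s per run.

The default design is 4 devices × 12 runs, the published replication count.
At the default emission concentration (2000 particles/cm³) an inhalation
spectrum carries ~10⁵ counts, so the Monte-Carlo error of an exhaled
fraction is ~0.02 percentage points — comfortably inside the ±0.5-point
regression band the acceptance suite uses.

What passing these checks shows — and what it does not: the pipeline's
arithmetic is exact, its estimators are unbiased under Poisson counting, and
the calibrated generator reproduces the published study-level numbers as a
*regression* standard. It does not independently validate the physical
experiment: real DPI plumes have inter-run variance from capsule handling
and humidity, coincidence and counting-efficiency artifacts, and
hygroscopic growth, none of which are modeled.

## Numerical choices and limitations

* Grid anchoring at the lower instrument bound is a package decision (the
  instrument convention is not published); rebuilding a grid from
  `(d_min, d_max, intervals_per_decade)` is bit-for-bit reproducible.
* `M1` is computed per run and aggregated across the 12 runs (run-level
  values are exposed); pooled-count alternatives differ only through the
  run weighting.
* Exhaled fractions default to the averaged-spectra estimator; per-run
  ratios are reported alongside.
* File formats are delimited text with `# key=value` headers; counts
  round-trip bit-exactly, and readers fail with line-numbered parse errors
  on negative counts or non-contiguous bins.
* Problem sizes in the shipped tests and acceptance script — 12 runs per
  device, 10,000 null simulations, exhaustive rank-test enumeration to
  n = 8 — were chosen so the whole suite completes in well under the time a
  practitioner would tolerate interactively, while keeping every
  Monte-Carlo tolerance at least an order of magnitude above its standard
  error.
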