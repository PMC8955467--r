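# aerodepo

Dry powder inhalers (DPIs) deliver drug as a powder aerosolized entirely by
the patient's own inspiratory effort, so what reaches (and stays in) the lung
depends on the device's airflow resistance, the inhalation maneuver, and the
size-selective filtering of the airways. `aerodepo` is an R package and
analysis workflow for studies that characterize DPI aerosols with an optical
aerosol spectrometer mounted in a mechanical breathing simulator: it
processes log-binned particle counts sampled from the airstream during
inhalation and exhalation, characterizes device and system resistance from
flow/pressure traces, and quantifies lung deposition as the particle number
lost between inhaled and exhaled air. It targets aerosol scientists and
inhalation-device engineers who need these computations reproducible and
testable without instrument access.

## The computations at the core

Spectra live on a logarithmic size grid (128 intervals per decade,
0.2–10 µm, 218 bins) with arithmetic bin centers
`x_i = x_lower,i + Δx_i / 2`. From per-bin counts `n_i`:

* differential number distribution `q0(x_i) = n_i / (Σn · Δx_i)` (µm⁻¹),
  which integrates to one;
* mean particle diameter `M1 = Σ x_i · q0(x_i) · Δx_i` (µm);
* number concentration `dCn_i = n_i / Vm` (particles/cm³), with the sampled
  volume `Vm = Q · t` (5 L/min sampling flow), background-corrected bin-wise.

Device and system airflow resistance follows the orifice relation
`√ΔP = R · Q`, so `R = √ΔP / PIF` in kPa^½/(L/min). Lung deposition of a
paired run set is `100 − 100 · ΣC_ex / ΣC_in` (%), the complement of the
exhaled fraction. Inhaled and exhaled metrics are compared with a
tie-corrected Kruskal–Wallis rank test against the χ² critical value 3.841
(α = 0.05, df = 1).

Because no instrument data ship with the package, a calibrated synthetic
generator emulates the whole experiment: per-device lognormal emitted
aerosols, maneuver flow traces (ramp to the 4 kPa pressure-drop target,
5 s hold, 30 L/min × 6 s exhalation, capsule flutter for capsule devices),
an upper-airway impaction filter (cut near 3 µm), a U-shaped lung retention
curve with minimum deposition near 0.5 µm, ambient background aerosol, and
Poisson counting noise.

## Worked example

```r
library(aerodepo)

design <- default_study_design(seed = 1)      # 4 devices x 12 runs
generate_study(design, "results/study")       # 252 delimited-text files
a <- analyze_study("results/study")
print(a$summary, digits = 4)
```

```
      device overall_deposition exhaled_fraction mean_diameter_in mean_diameter_ex n_runs
1 breezhaler              97.06            2.942           1.4669           0.5094     12
2    ellipta              89.77           10.231           1.0985           0.4779     12
3 handihaler              97.85            2.148           2.2024           0.5398     12
4 turbohaler              93.77            6.231           0.9205           0.4703     12
```

Each row is one device: the percentage of the inhaled particle number
concentration retained in the lung equivalent (all > 80 %), the exhaled
fraction (its complement), and the mean particle diameters of the inhaled
(post-upper-airway) and exhaled aerosol — exhalation collapses every device
onto the 0.47–0.54 µm band where lung deposition is weakest. The per-device
Kruskal–Wallis comparison of the 12 inhaled vs 12 exhaled mean diameters
separates completely (`H = 17.28`, `p = 3.2e-05`), and
`characterize_study()` recovers each configured system resistance to four
decimals from the simulated traces.

The same steps, with commentary and output tables under `results/`, are the
numbered drivers in `analysis/`:
`01_simulate.R` → `02_characterize.R` → `03_deposition.R` → `04_report.R`.

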