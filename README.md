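# il2field

Spatial modeling of binary IL-2 secretion and graded CD25 expression in
T cell populations.

## What this package is for

During an immune response, CD4⁺ T helper (Th) cells encode antigen dose
in a **binary** way for IL-2 — the dose sets the *fraction* of secreting
cells, not the amount each cell secretes — while CD25 (IL-2Rα) is
expressed in a **graded** way, shifting on every cell. `il2field` is for
computational immunologists and modelers who want to study what this
combination does to antigen-dose-dependent activation of Th and
regulatory T (Treg) cells through the paracrine IL-2 field. It provides:

* a **synthetic flow-cytometry generator** (dose- and time-resolved
  log-normal mixture models for IL-2, CD25, CD69, p-STAT5, c-Fos, NFATc2,
  plus CFSE generation profiles), so every downstream stage is testable
  without data downloads;
* the **expression-analysis stage**: Hartigan's dip statistic with a
  bootstrap unimodality test, EM deconvolution of Gaussian mixtures on
  the log scale, binary/graded condition calls, percent-positive
  extraction, quartile conditioning, and cohort-corrected CFSE precursor
  frequencies;
* **dose–response calibration** with Hill curves on a normalized antigen
  stimulus scale, and the piecewise-linear secretion (peak 9 h) and
  receptor (peak 18 h) time windows;
* a **2D reaction–diffusion model** of IL-2 on a circular tissue domain,

  ```
  du/dt = D ∇²u − d_UR · IL2R_bg · u/(u+k),      u = 0 on the rim,
  ```

  with cells as discs whose boundaries carry secretion fluxes
  `IL2·f(A,t)/c_cell` and Michaelis–Menten uptake
  `IL2R·g(A,t)·u/((u+k)·c_cell)`, where `k = (k_deg + k_off)/k_on`.
  Binary and graded secretion scenarios are compared at equal total
  secretion; per-cell internalized IL-2 integrated over 48 h defines
  activation via a single threshold calibrated against p-STAT5⁺
  fractions (~11% Th, ~50% Treg at maximal dose);
* a **pipeline** (`run_full_pipeline()`) chaining
  generate → analyze → calibrate → simulate → compare with one master
  seed and a reproducibility manifest.

## Worked example

Classify the IL-2 distribution of 20,000 synthetic antigen-specific Th
cells at the maximal dose (2000 µg, 14 h readout):

```r
library(il2field)
cfg <- generator_config(dose_grid = c(0, 2000), time_grid = 14,
                        events_per_condition = 2e4,
                        populations = "Th_tg", markers = c("IL2", "CD25"),
                        seed = 1)
tab <- generate_dataset(cfg)
il2 <- tab$fi[tab$marker == "IL2" & tab$dose_ug == 2000]
classify_condition(il2, n_boot = 500, seed = 1)
#> binary expression | %positive 75.6 | mode(s) 1.00/2.40 | MFI 244.8 | dip p 0.001996
```

The dip test rejects unimodality (p ≈ 0.002), so the condition is called
*binary* and the percent positive (75.6%) is the weight of the
higher-mean mixture component — recovering the generator's 75% producer
calibration. The two mode locations (10¹·⁰ and 10²·⁴) are the fixed
"off" and "on" states; dose moves cells between them, not along them.

Simulate the binary scenario across antigen stimuli, calibrate the
activation threshold to the p-STAT5 anchors, and read off activated
fractions:

```r
profiles <- default_profiles()
params <- model_params(n_cells = 200, domain_radius = 126, dx = 4)
sweep <- run_dose_sweep("binary", c(0, 0.0625, 0.25, 1),
                        n_replicates = 5, params, profiles, seed = 1)
cal <- calibrate_threshold(
  sweep, data.frame(A = 1, population = c("Th", "Treg"),
                    fraction = c(0.11, 0.50)))
cal$threshold
#> [1] 7316
sweep_fractions(sweep, cal$threshold)
#>        A population fraction      sd
#> 1 0.0000         Th   0.0000 0.00000
#> 2 0.0000       Treg   0.0000 0.00000
#> 3 0.0625         Th   0.0000 0.00000
#> 4 0.0625       Treg   0.0300 0.02739
#> 5 0.2500         Th   0.0163 0.00713
#> 6 0.2500       Treg   0.2500 0.07706
#> 7 1.0000         Th   0.1313 0.02898
#> 8 1.0000       Treg   0.4950 0.05420
```

With a single threshold of ≈7.3×10³ internalized IL-2 molecules, 13% of
Th and 50% of Treg cells activate at maximal stimulus (matching the
p-STAT5 anchors within sampling error), Treg activation rises at much
lower stimulus than Th — a quarter of Treg cells are already signaling at
a quarter of the maximal stimulus, where Th activation is barely
detectable — and nothing activates without antigen.
`compare_scenarios()` on a binary and a graded sweep quantifies the
published contrast: the graded scenario produces steeper (more
switch-like) activation curves, the binary scenario a wider proportional
range.

The methods vignette (`vignettes/il2field-methods.Rmd`) documents the
model equations, the numerical scheme, every default parameter and the
reasoning behind it, and the generator's calibration anchors.

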