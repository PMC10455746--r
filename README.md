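# scaffoldlab

Quantitative characterization of polymer-coated calcium-phosphate bone
scaffolds: an R toolkit for the four measurement families that
characterize poly(DL-lactide)-coated β-tricalcium-phosphate (β-TCP)
composites, written for biomaterials and tissue-engineering labs.

* **Mass balances** — coating efficiency
  `CE% = 100·(w_after − w_before)/w_after` and water absorption capacity
  `WAC% = 100·(w_wet − w_dry)/w_wet`, with batch mean ± SD summaries.
* **3-point flexure** — strength `σ = 3PI/(2wb²)`, elastic modulus
  `E = mL³/(4wb³)` from the least-squares slope `m` of the 20–80 %
  load window, and elongation at break `A_g` (deflection at peak load).
* **Degradation kinetics** — descriptive summaries, threshold crossings
  and comparisons of pH/conductivity time series.
* **Raman mineralization metrics** — the core of the package: detecting
  cell-formed hydroxyapatite (HA) on a calcium-phosphate core material
  via a fixed pipeline (background subtraction → modpoly baseline →
  Savitzky–Golay smoothing) followed by band ratios — HA/Phe
  I(960)/I(1004), HA/amide III I(960)/I(1244), carbonate/HA
  I(1070)/I(960) — and a crystallinity index 1/FWHM from a Gaussian fit
  of the 960 cm⁻¹ apatite band over 900–1000 cm⁻¹
  (FWHM = 2√(2 ln 2)·s).
* **Group statistics** — Welch t, one-way ANOVA + Tukey–Kramer, two-way
  ANOVA + Šídák simple effects, qPCR (GAPDH) and fluorescence (nuclear
  stain) normalizations.
* **Synthetic data** — seeded generators for spectra, load–deflection
  curves, mass tables and degradation series with retained ground truth,
  so every stage is testable offline.

See `vignettes/scaffold-analytics.Rmd` for the methods in full.

## Worked example

```r
library(scaffoldlab)

# coating-efficiency batch from the bundled mass-balance table
batch <- read_coating_table(system.file("extdata", "coating_table.csv",
                                        package = "scaffoldlab"))
batch_ce_summary(batch)
#> coating efficiency [%]: 14.52 ± 3.128 (n = 16)

# water absorption of the two coating grades, and their comparison
wac <- read_wac_table(system.file("extdata", "wac_table.csv",
                                  package = "scaffoldlab"))
printed <- split(wac$wac_printed_pct, wac$group)
wac_group_summary(printed[["PDL-02"]])
#> WAC [%]: 24.73 ± 5.597 (n = 4)
wac_group_summary(printed[["PDL-04"]])
#> WAC [%]: 14.38 ± 1.477 (n = 4)
welch_t_test(printed[["PDL-02"]], printed[["PDL-04"]])$p
#> [1] 0.03024769   # PDL-04 retains significantly less water (*)

# a synthetic flexure specimen, analyzed like a measured one
sp <- gen_flexure_curve(flexure_model(E_true = 900, noise_sd = 0.2, seed = 7))
analyze_flexure(sp)
#> Flexure result 'synthetic': sigma = 5 MPa, E = 897.4 MPa, A_g = 0.2469 mm

# Raman metrics of a synthetic cell-seeded scaffold spectrum
s <- gen_spectrum(spectrum_model(noise_sd = 2, seed = 11))
s <- smooth_sg(suppressWarnings(baseline_correct(s)))
compute_ratios(s)
#> Raman mineralization metrics
#>   HA/Phe       3.95
#>   HA/amide III 5.361
#>   carbonate/HA 0.2019
fit_apatite_gaussian(s)
#> Gaussian fit: mu = 962 1/cm, sigma = 8.959, FWHM = 21.1 1/cm, 1/FWHM = 0.0474 cm
```

The mean CE of 14.52 ± 3.13 % reproduces the bundled table's printed
batch line; the recovered modulus of 897 MPa sits within 0.3 % of the
900 MPa ground truth; the ratios match the generator's band amplitudes
(e.g. HA/Phe ≈ 100/25 = 4); and the fitted width exceeds the injected
8 cm⁻¹ because the 971 cm⁻¹ phosphate shoulder falls inside the fitting
window — which is why the crystallinity index is interpreted relatively,
between conditions.

`run_pipeline(default_pipeline_config(seed = 1), "out/")` executes all
stages, writes per-stage CSVs plus `report.txt` with the resolved
configuration, and is byte-identical across repeated runs with the same
seed.

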