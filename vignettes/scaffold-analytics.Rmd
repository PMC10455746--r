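---
title: "Methods: quantitative characterization of polymer-coated calcium-phosphate scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative characterization of polymer-coated calcium-phosphate scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldlab)
```

## The problem

Beta-tricalcium phosphate (β-TCP) is a resorbable bone-substitute ceramic;
coating it with poly(DL-lactide) (PDLA, grades such as PDL-02 and PDL-04)
improves its mechanical strength roughly tenfold while keeping it
degradable. Characterizing such composites raises four quantitative tasks,
each covered by one module of this package:

1. **Mass balances** — how much polymer did the scaffold take up (coating
   efficiency, CE) and how much open porosity survives the coating (water
   absorption capacity, WAC)?
2. **Flexure mechanics** — flexural strength σ, elastic modulus E and
   elongation at break A~g~ from 3-point-bending load–deflection curves.
3. **Degradation kinetics** — descriptive summaries of pH and electrical
   conductivity time series during immersion (polyester hydrolysis
   releases lactic acid: pH falls, conductivity rises).
4. **Raman mineralization metrics** — the central and least trivial task:
   detecting hydroxyapatite (HA) formed by cells *on top of a
   calcium-phosphate material that shares the same chemistry*. Raw
   phosphate band heights cannot distinguish cell-derived mineral from
   the scaffold itself; ratios of the 960 cm⁻¹ apatite ν₁ band to
   protein reference bands, the carbonate-to-phosphate ratio, and a
   crystallinity index from the band's width can.

A synthetic-data module generates spectra, load–deflection curves, mass
tables and degradation series with known ground truth, so every analysis
stage is testable without an instrument.

## Mass-balance arithmetic

Both quantities are fractions of the *final* mass:

$$\mathrm{CE}\% = 100\,\frac{w_\text{after}-w_\text{before}}{w_\text{after}},
\qquad
\mathrm{WAC}\% = 100\,\frac{w_\text{wet}-w_\text{dry}}{w_\text{wet}}.$$

Group summaries use the sample standard deviation (n − 1 denominator)
throughout; that convention reproduces the published batch statistics of
the bundled tables (`inst/extdata/coating_table.csv`,
`inst/extdata/wac_table.csv`) to the printed precision. The polymer and
water *content* columns of such tables are always recomputed from the two
weighings rather than read back, which keeps the arithmetic
self-consistent; where a printed table's own rounding propagates (a few
WAC rows differ in the last digit when recomputed from dry/wet weights),
comparisons tolerate ±0.1 percentage points.

```{r masses}
batch <- read_coating_table(system.file("extdata", "coating_table.csv",
                                        package = "scaffoldlab"))
batch_ce_summary(batch)
```

## Flexure mechanics

Strength uses the standard 3-point formula σ = 3PI/(2wb²) with the
breaking load P (N), support span I (mm) and the caliper-averaged width w
and thickness b (mm); in these units σ is in MPa. Width and thickness are
measured at three points along the bar and averaged.

No closed formula is universal for the modulus, so the package takes the
standard route for brittle ceramics: an ordinary-least-squares slope m
(N/mm) of the load–deflection curve over the 20–80 % window of the
breaking load — below 20 % seating effects dominate, above 80 % damage
accumulates — converted by rectangular-section beam theory,

$$E = \frac{m L^3}{4 w b^3},$$

equivalent to the midspan deflection δ = PL³/48EI with I = wb³/12. The
window needs at least five points; fewer is an error, not a silent fit.
A~g~ is the crosshead deflection at maximum load, reported in mm (not
converted to strain, matching how such cohorts are usually reported).
Default geometry is the 45 × 6 × 6 mm bar on a 40 mm span used for this
composite class.

## Raman workflow

The pipeline order is fixed and fingerprinted in every output:
**background subtraction → baseline correction → Savitzky–Golay
smoothing → metrics.**

* **Background**: the dish/medium spectrum is linearly interpolated onto
  the sample axis and subtracted pointwise.
* **Baseline**: default is modified-polynomial (modpoly) fitting of order
  3 — fit a polynomial, clip the signal to the fit, refit — which relaxes
  the polynomial under the peaks onto the fluorescence baseline.
  Iteration stops at a relative baseline change below 1e-6 or at 100
  iterations; hitting the cap is flagged on the result (for spectra with
  isolated strong peaks or noise the criterion is strict and the flag is
  common; the baseline estimate is nevertheless stable, and peak heights
  are preserved within 2 %, which the tests assert). An
  `endpoint_linear` method is provided for short windows such as
  900–1000 cm⁻¹.
* **Smoothing**: Savitzky–Golay, second order, 7 points — each point is
  replaced by the value of the least-squares quadratic on its centered
  window, with terminal windows at the edges. The implementation is
  `signal::sgolayfilt`; the test suite checks it against a brute-force
  per-point polyfit oracle to 1e-10.
* **Peak intensities** are local maxima within ±5 cm⁻¹ of the nominal
  centers (874 PLA, 960 HA, 971 P–O, 1004 Phe, 1070 carbonate, 1091
  νP–O, 1244 amide III, 1374 P=O), tolerant to small calibration offsets.
  The phenylalanine center is set at its canonical 1004 cm⁻¹
  ring-breathing position.
* **Ratios**: HA/Phe = I(960)/I(1004) and HA/amide III = I(960)/I(1244)
  rise with mineralization; carbonate/HA = I(1070)/I(960) falls. The HA
  numerator defaults to 960 cm⁻¹ but is configurable to 971 cm⁻¹.
* **Crystallinity**: a Gaussian A·exp(−(x−μ)²/2s²) + c is fitted over
  900–1000 cm⁻¹ (Levenberg–Marquardt, parameter tolerance 1e-8;
  initialization from the in-range argmax, range, and half-maximum
  crossing distance). FWHM = 2√(2 ln 2)·s and 1/FWHM (cm) is the
  crystallinity index: narrower bands, larger apatite crystals. The
  constant offset c guards against residual baseline; an offset-free
  variant is available. Non-convergence or a width at its bounds returns
  a flagged result with diagnostics instead of an error.

`set_metrics()` runs the chain on every spectrum of a mapping set and
summarizes each metric as mean ± SD, excluding (and counting) failed
spectra. All ratios and 1/FWHM are invariant to rescaling the spectrum
intensity, which the property tests assert.

```{r raman}
co <- set_metrics(gen_spectrum_set(
  spectrum_model(noise_sd = 2, seed = 1), 12, jitter = 0.05, label = "CO"))
co
```

## Degradation kinetics

The module is deliberately descriptive — initial/final values, total
change, maximum finite-difference rate, linear-interpolated threshold
crossings and pairwise series comparisons — because the underlying
measurements are usually reported as curves, not fitted models. The
exponential pH form lives only in the synthetic generator. Crossing
direction defaults to the physical course of each channel: downward for
pH, upward for conductivity.

## Group statistics

Welch's t test is the default unpaired comparison (the WAC groups have
visibly unequal variances); the pooled variant is a flag, and both reach
the same conclusion on the bundled tables. One-way ANOVA uses
`stats::aov` with Tukey–Kramer HSD (valid for unequal cohort sizes such
as 6 controls vs 8 coated specimens). The two-way design
(condition × material) uses `values ~ group * factor2` with
Šídák-adjusted simple-effect contrasts computed from the pooled residual
mean square; the Šídák form p~adj~ = 1 − (1 − p)^m is exposed directly as
`sidak_adjust()`. Stars follow the usual convention (\*, \*\*, \*\*\*,
\*\*\*\* at 0.05, 0.01, 0.001, 0.0001). qPCR copy numbers are normalized
to GAPDH; fold induction is donor-wise OB/CO by default (mean-wise by
flag), and fluorescence signals are normalized to nuclear staining.

## The synthetic generators

The generators define the reference conditions for every recovery test:

* **Spectra**: 600–1800 cm⁻¹ at 1 cm⁻¹ spacing (covers all eight bands);
  Gaussian bands (matching the Gaussian fitting model); additive Gaussian
  noise, default SD 2 counts ≈ 2 % of the default 100-count apatite band;
  mapping sets multiply each band amplitude by Normal(1, 0.05) per
  spectrum, emulating spot-to-spot compositional variation.
* **Flexure**: E 900 MPa, break load 18 N (σ ≈ 5 MPa, the order measured
  for PDLA-coated β-TCP bars), load noise 0.2 N on 200 points.
* **Masses**: multiplicative Normal(1, 0.02) weighing noise around a true
  coating fraction of 0.145.
* **Degradation**: pH 7 → 2 at 0.1/day over 0–180 days sampled every
  2 days; conductivity rises with initial slope 20 µS/cm/day saturating
  on the series duration (the saturation timescale is not separately
  parameterized).

Every generator is a pure function of its model including the seed (the
caller's RNG stream is untouched), rejects invalid parameters rather than
clamping, and attaches its ground truth to the output. Noiseless outputs
are exactly inverted by the corresponding analysis (CE, beam slope, FWHM),
which the round-trip tests assert.

What the generators deliberately do **not** emulate: cosmic-ray spikes,
detector nonlinearity and wavenumber miscalibration in spectra;
non-linear toe/damage regions in load–deflection curves; autocatalytic
hydrolysis kinetics. Passing recovery tests therefore demonstrate the
correctness of the arithmetic and fitting under the stated noise models,
not robustness to every instrument artifact.

## Problem sizes and reproducibility

The bundled analyses use deliberately modest sizes — Monte-Carlo checks
at 100 seeds, mapping sets of 8–30 spectra (real maps carry 90–148; the
estimators are per-spectrum, so set size only tightens the summary SD),
1000-row mass tables for the CE recovery — chosen so the whole suite
re-runs in seconds while leaving the statistical conclusions
unambiguous. `run_pipeline()` embeds its resolved configuration and
master seed in the report, derives all stage seeds from that master
seed, and produces byte-identical output across repeated runs.

## Known limitations

* The modpoly baseline is one defensible reading of a vendor's
  unspecified "arithmetic" baseline step; absolute band heights depend
  on it (ratios much less so).
* A single Gaussian over 900–1000 cm⁻¹ absorbs the 971 cm⁻¹ shoulder
  into the fitted width; the crystallinity index is therefore a
  *relative* measure between conditions measured with the same band
  structure, not an absolute crystal-size estimate.
* Welch vs pooled t and donor-wise vs mean-wise fold induction are
  configurable because the conventional choice varies between labs; the
  defaults are stated above.
* Degradation summaries assume reasonably dense sampling; the maximum
  finite-difference rate underestimates the instantaneous rate of a
  convex decay on coarse grids.
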