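---
title: "Methods: ligand-albumin binding analysis from fluorescence, CD and FT-IR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-albumin binding analysis from fluorescence, CD and FT-IR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(albuminbind)
```

## Scope and model assumptions

`albuminbind` analyzes ligand binding to bovine serum albumin (BSA) from
three spectroscopic modalities. All of its regressions assume a specific
physical picture, which the synthetic-data module samples exactly:

* **Static quenching by an n:1 ground-state complex.** Fluorescence follows
  `F = F0 / (1 + Kb [Q]^n)`, so the double-logarithm plot
  `log10((F0−F)/F)` vs `log10 [Q]` is exactly linear with slope `n` and
  intercept `log10 Kb`. `[Q]` is the *total added* ligand concentration; no
  free-ligand (mass-action) correction and no dilution correction are
  applied, which matches the printed regression forms but biases `Kb`
  downward when ligand depletion by the protein is substantial.
* **van't Hoff temperature dependence.** `ln Kb = −ΔH°/(RT) + ΔS°/R` with
  temperature-independent `ΔH°`, `ΔS°` (no ΔCp term). The regression uses
  natural logarithms throughout so that it is algebraically consistent with
  `ΔG° = −RT ln Kb`; a base-10 reading would require 2.303 factors that the
  conventional presentation omits.
* **Linear helix-to-ellipticity mapping.** The α-helix percentage is an
  affine function of the mean residue ellipticity at 208 nm anchored at
  −33,000 (pure helix, 100%) and −4,000 (β/coil crossover, 0%)
  deg cm² dmol⁻¹. Only the 208 nm estimator is implemented; no CONTIN/SELCON
  style full deconvolution.
* **Amide-I as a sum of Gaussians.** Each secondary-structure class
  contributes one Gaussian band; class percentages are area shares of the
  fitted components.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `tau0` | 1e-8 | s | conventional unquenched biopolymer lifetime; the 2×10¹⁰ dm³ mol⁻¹ s⁻¹ collision limit presumes this scale |
| `protein_conc` | 1e-6 | mol dm⁻³ | standard BSA working concentration for quenching/CD titrations |
| `n_residues` | 583 | — | residue count of mature BSA |
| `l` (CD path) | 1 | cm | 10 mm cuvette |
| `ratios` | 0.1–1.9 step 0.2 | — | ligand:protein molar ratios of the additions (ten points) |
| `temperatures` | 297, 303, 308 | K | physiological bracket; three points suffice for a linear van't Hoff fit |
| `smoothing_window` | 11 | points | quadratic Savitzky–Golay window for the second derivative |
| `prominence_frac` | 0.05 | — | fraction of the deepest second-derivative minimum a seed must reach |
| `min_separation` | 6 | cm⁻¹ | minima closer than this merge to the deepest (noise splits a band's curvature dip) |
| `max_components` | 8 | — | more candidate bands than this is treated as noise, not structure |

The Stern–Volmer intercept is *fitted*, not pinned to 1; a deviation beyond
0.05 raises a warning rather than an error, because forcing the intercept
would silently absorb curvature (combined quenching, inner-filter residuals)
into `K_SV`.

## Numerical choices

* **OLS everywhere a line is fitted** (`stats::lm`), with the slope/intercept
  verified in the test suite against a hand-written normal-equation solver.
  Flat responses (all `F = F0`) are reported with `r² = 1` since the zero
  slope reproduces the data exactly.
* **Gaussian band fitting** uses bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`): centers constrained to seed ± 4 cm⁻¹, FWHM in
  [5, 25] cm⁻¹, amplitudes ≥ 0. Initialization is deterministic (amplitude =
  region value at the seed, FWHM = 12 cm⁻¹); on non-convergence two
  alternative width starts (8, 18 cm⁻¹) are tried before failing with
  diagnostics. Identical input therefore always yields identical output.
* **Second-derivative seeding.** The region is smoothed with a local
  quadratic (Savitzky–Golay) filter; on the generator's 0.5 cm⁻¹ grid the
  default 11-point window spans 5 cm⁻¹, narrow against 10–16 cm⁻¹ bands, so
  residual noise can split a single band's curvature dip into several
  adjacent minima. Rather than widen the default smoothing (which blurs
  genuinely close bands), minima closer than `min_separation` are merged to
  the deepest of the cluster, and a region yielding more than
  `max_components` seeds is rejected as structureless noise. These two
  guards are what make the end-to-end recovery stable at 0.5% peak noise.
* **Baseline and normalization.** The amide-I baseline is the straight line
  through the window endpoints, which removes any additive linear tilt
  exactly and makes all downstream quantities invariant to positive
  rescaling of the raw spectrum. Sub-zero residuals after subtraction are
  clipped to zero (they carry no band area) before unit-area normalization.
* **Interpolation.** CD at exactly 208 nm, and spectra-dialect titration
  intensities at a non-grid analysis wavelength, use linear interpolation
  between bracketing grid points.
* **Sign tests** for the interaction classification treat |ΔH°| or |ΔS°|
  below 1e-9 (fitted units) as zero → indeterminate, so a numerically flat
  fit is never forced into a physical category.
* **Degenerate inputs** fail loudly with classed conditions: fewer than 3
  usable double-log points, non-quenching titrations, Kb ≤ 0, missing
  ratio-0 CD spectrum, amide window not covered, etc. Points with
  `F ≥ F0` are excluded from the double-log fit and counted in a warning
  rather than silently dropped.

## Design choices that were genuinely open

* **Analysis wavelength** for the spectra dialect is the emission maximum of
  the *zero-quencher* spectrum, held fixed across all additions. Tracking
  each spectrum's own maximum would fold ligand-induced red shifts into the
  quenching signal.
* **Band-assignment ranges** are half-open `[low, high)` with the top bin
  closed: β-sheet [1610, 1640), random coil [1640, 1650), α-helix
  [1650, 1660), β-turn [1680, 1691), β-antiparallel [1691, 1700].
  β-antiparallel sits at the high-wavenumber end per the standard amide-I
  assignment convention; components falling in the 1660–1680 gap (or below
  1610) are binned to the nearest class under an explicit warning instead of
  being silently absorbed or discarded.
* **Out-of-range helix percentages are reported, not clamped**, with an
  `in_range = FALSE` flag: a helix content outside [0, 100] almost always
  means wrong concentration or path-length metadata, and clamping would hide
  that.
* **Site assignment** requires *both* marker ratios below 1 and a strict
  ordering between them; ties or a marker that apparently increases `Kb`
  yield `indeterminate` rather than a coin-flip call.

## What the generators emulate — and what they do not

The generators produce data with *exactly* the statistical structure the
regressions assume: the quenching law above (with the inner-filter
attenuation applied in the forward direction so that the correction is its
exact inverse), CD spectra whose 208 nm value encodes the programmed helix
fraction inside a smooth two-lobe negative band, and amide-I profiles that
are literally sums of Gaussians on a linear baseline. Consequently,
noiseless round-trip recovery is a *correctness* check of the estimators,
not evidence about real spectra. Real data additionally contain free-ligand
depletion, dilution, combined static+dynamic quenching, peak shifts,
non-Gaussian band shapes, ATR penetration-depth effects and correlated
baselines — none of which the generators produce. Passing tests therefore
demonstrate that the pipeline computes its defined quantities correctly and
stably under modest white noise, not that those quantities are unbiased for
arbitrary instruments.

Default generator conditions mirror the standard experimental design: BSA
1×10⁻⁶ mol dm⁻³, ten additions at molar ratios 0.1–2.0 (0.2 steps), 297/303/
308 K, CD ratios 0–10 over 205–250 nm, amide-I on a 0.5 cm⁻¹ grid over
1580–1720 cm⁻¹. The default binding scenario (ΔH° = −40 kJ mol⁻¹,
ΔS° = −39 J mol⁻¹ K⁻¹) implies `Kb(297 K) ≈ 9.95×10⁴ dm³ mol⁻¹` — the
order of magnitude typical for drug-like ligands on albumin — and the
default amide-I composition is the free-BSA benchmark (α-helix 53.8%,
β-sheet 29.2%, β-turn 17.0%). The default CD series programs a
4.3-percentage-point helix loss at ratio 10, within the few-point range
typical for such ligands. Noise defaults to zero; tests that exercise noise
set it explicitly. These problem sizes (10-point titrations, 91-point CD
spectra, 281-point IR spectra, 60–100-replicate property sweeps) keep every
check fast while leaving the estimators nothing to hide behind.

```{r example}
sc <- default_scenario()
fit <- fit_double_log(simulate_titration(sc, 297))
c(Kb = fit$Kb, n = fit$n_sites)
```

## Determinism

Every stochastic simulation derives a sub-seed deterministically from the
scenario seed and the condition (temperature, marker, ratio index) and draws
through `withr::with_seed`, so identical scenarios give bit-identical
outputs without touching the session RNG state. Report files contain no
timestamps; reruns with the same inputs are byte-identical.

## Known limitations

* `Kb` from the double-log intercept is an extrapolation over several
  decades of `[Q]`; even sub-percent intensity noise propagates into tens of
  percent on `Kb` (the slope `n` is far more stable). Marker-competition
  calls on noisy data inherit this sensitivity.
* Three temperatures give a van't Hoff fit with one residual degree of
  freedom; the package reports `r²` but deliberately no significance tests.
* The modified (Lehrer) Stern–Volmer plot, lifetime-resolved analysis,
  Amide II quantification and CD full-spectrum deconvolution are out of
  scope.
* Druglikeness rules operate on a supplied descriptor table; the package
  does not compute descriptors from structures.
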