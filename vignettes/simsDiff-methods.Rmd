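---
title: "Methods: differential analysis of ToF-SIMS imaging studies"
author: "simsDiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential analysis of ToF-SIMS imaging studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simsDiff)
```

## The scientific problem

Time-of-Flight Secondary Ion Mass Spectrometry (ToF-SIMS) images a tissue
surface by rastering a pulsed primary-ion beam and recording, per pixel, a
full secondary-ion mass spectrum. Because ionisation efficiency and
primary-ion dose vary between acquisitions, ToF-SIMS is semi-quantitative:
comparisons are made on *relative* intensities after normalising each
spectrum to its total ion count (TIC). simsDiff implements the complete
comparative workflow for a three-arm rodent study of hepatic metabolism —
a healthy control arm (LEAN), a diabetic control arm (P1) and a
drug-treated diabetic arm (P2) — from raw hyperspectral images to per-ion
statistics and report tables.

The quantity at the centre of the package is the **recovery index** of a
target ion,

$$ R = 100\,\frac{I_{P2} - I_{P1}}{I_{LEAN} - I_{P1}}, $$

where $I_g$ is the TIC-normalised mean intensity of the ion in group $g$:
0% means treatment left the ion at the diabetic level, 100% means full
convergence to the healthy level, and overshoot beyond [0, 100] is
reported rather than clipped. Alongside it, each ion is given a **trend
label** from the sign pattern of its two contrasts against the diabetic
control: `Up` when both the healthy and the treated group sit above P1,
`Down` when both sit below, and `Mixed` otherwise (an exact zero in either
contrast also falls to `Mixed`, the residual category for divergent
behaviour).

## Statistical model

Per ion, animal-level TIC-normalised intensities are compared across the
three groups with a classical one-way ANOVA (between/within $F$ with
$k-1$, $N-k$ degrees of freedom), followed by Tukey–Kramer studentized-range
contrasts for the three pairs, which remain valid for the unequal group
sizes (4/8/8) of the default design. Multiplicity over the ion panel is
controlled with the Benjamini–Hochberg step-up procedure,
$q_{(i)} = \min_{j \ge i} p_{(j)}\, m / j$, and ions with $q < 0.05$ are
called significant. Two modelling choices deserve emphasis:

* **Technical replicates are pseudoreplicates.** Each animal contributes
  three replicate acquisitions; these are averaged to a single animal
  value before any statistics, so ANOVA degrees of freedom come from
  animals (n = 4/8/8), not from acquisitions (12/24/24). The alternative
  (`replicate_policy: pool`) is available but anticonservative.
* **BH families follow the ion classes.** The lipid panel and the
  amino-acid panel are corrected as separate families (they are reported
  as separate tables with separate significance counts); a single pooled
  family is available via `family = "global"`.

Log2 fold changes are taken on ratios of group means of animal-level
values — not means of per-animal logs — because that convention
reproduces the published fold-change columns from the published group
means. Shapiro–Wilk normality (per group, needs $n \ge 3$) and Levene
variance-homogeneity diagnostics (classical mean-centred form) are
computed and reported for every ion but never gate the ANOVA: the
workflow reports parametric statistics throughout and leaves the
diagnostics to the reader.

## The synthetic study generator

Real ToF-SIMS studies are large and instrument-bound, so the package
ships a generator whose defaults *are* the study conditions used in all
tests: three groups with 4/8/8 animals, 3 technical replicates per
animal, 128×128-pixel images over a 250 µm field, negative mode, m/z
0–911. Its construction:

* **Spectral model.** Each image carries a sparse channel axis holding
  the 26-ion target panel (10 lipid-related, 16 amino-acid-related ions,
  with the published group means as TIC fractions), the five low-mass
  calibration species H⁻, C⁻, CH⁻, C₂⁻, C₃⁻ (fixed 17% of the TIC —
  these dominate negative-ion spectra of organic surfaces), and 50
  broadband background pseudo-ions that absorb the remaining TIC
  fraction with an exponentially falling mass profile. The background
  makes TIC normalisation non-degenerate and keeps the per-group channel
  fractions summing exactly to one, which is what makes the noise-free
  closure below exact.
* **Counting noise** is Poisson at pixel level: static-SIMS detection is
  counting-statistics dominated. The default TIC budget is 2000 counts
  per pixel (typical of bunched-mode Bi₃⁺ acquisitions at this pixel
  density), with a 5% log-normal per-replicate fluctuation.
* **Spatial texture** is a smooth multiplicative random field (Gaussian
  -filtered white noise, mean 1, CV 0.08, 30 µm correlation length)
  shared by all channels of a pixel. Liver lobular microstructure is
  homogeneous at this scale, so no sharp compartments are simulated.
  Because the multiplier is shared across channels it cancels exactly
  under TIC normalisation — it shapes ion maps, not statistics.
* **Between-animal biology** is a per-animal log-normal scale drawn
  independently per target ion (CV 0.10, mean 1), shared by the animal's
  replicates. This is a stipulation, not a published estimate: no
  variance decomposition is available for these data, and 10% between
  animals makes the ANOVA neither trivial nor powerless. It is the
  dominant noise source for the group means.
* **Mass drift**: an optional multiplicative miscalibration (ppm) of the
  stored axis, used to exercise the calibration stage.

What passing tests on this generator show — and do not show: they verify
the pipeline's arithmetic, its statistical calibration (permutation-level
FDR control), and unbiased recovery of the generator's own group means;
they cannot validate instrument physics the generator omits (charging,
detector dead time, matrix effects, fragmentation chemistry) or the
biological truth of the panel annotations.

## Preprocessing conventions

* **Calibration** finds each reference species as the strongest channel
  of the image mean spectrum within ±0.5 Th of its expected position and
  fits observed→expected by least squares in $\sqrt{m/z}$ space (flight
  time scales with $\sqrt{m/z}$); degree 1 absorbs multiplicative drift
  exactly, degree 2 is available for larger distortions. Fewer than two
  detected references skips calibration with a flag; any post-fit
  residual above 300 ppm (the instrument's mass-accuracy contract) marks
  the image as failing validation.
* **ROI**: a centred square crop of 150 µm (chosen to avoid edge and
  charging artefacts). Pixel arithmetic is fixed so results are
  bit-reproducible: side = `round(roi/pixel)`, offset = `floor((width -
  side)/2)` — on the default grid, a 77×77 px block at zero-based offset
  (25, 25).
* **Integration** sums counts over all ROI pixels within ±0.05 Th of the
  target (the resolving power m/Δm ≈ 4000 gives ≈0.06 Th FWHM at m/z
  241; a ppm window mode is available). Windows of two targets that
  would overlap are truncated at their midpoint, the midpoint channel
  going to the lower-mass ion, so no count is integrated twice.
* **TIC normalisation** divides by the ROI total over *all* channels,
  not just the panel, making results invariant to overall dose.

Degenerate inputs resolve by documented convention: zero within- and
between-group variance gives $F = 0$, $p = 1$; zero within-variance with
real separation gives $p \to 0$ with an infinite $F$; a LEAN–P1 gap
below $10^{-12}$ (absolute) leaves the recovery index undefined rather
than exploding.

## Reporting surfaces

Volcano tables use the Tukey pairwise p for the chosen contrast (a
per-contrast volcano needs a per-contrast p; the omnibus ANOVA p is a
documented alternative) and flag ions with |log2FC| > 0.6 *and* p < 0.05,
both strict. Heatmaps standardise each ion to Z-scores across samples and
cluster agglomeratively with Ward linkage on Euclidean distances — the
published analyses name neither metric nor linkage, so the package fixes
this common pairing and exposes it; the top-k ions are selected by
ascending q (default 40). Ion maps divide per-pixel window counts by the
per-pixel TIC and share one fixed colour range across the groups of an
ion so images are visually comparable. Boxplots follow the Tukey
convention (hinges, 1.5×IQR whiskers, outliers shown individually), and
every figure has a data-behind-the-figure CSV.

## Problem sizes used by the test suite

The noise-free closure checks run at 16×16 px — exactness is
size-independent, so the smallest geometry that exercises the ROI
arithmetic suffices. Stochastic checks (parameter recovery over 100
seeds, permutation-level FDR over 200 relabellings) run at 32×32 px with
the TIC budget scaled by pixel area (2000 × (128/32)² = 128 000 counts
per pixel): shrinking the pixel grid of the same acquisition concentrates
the same ion dose into fewer pixels, so ROI-level counting statistics —
what the group statistics actually see — match the full-resolution
acquisition.

## Known limitations

* The ion panel is an input; there is no peak picking or deisotoping of
  unknown ions, and no database cross-referencing — annotations ride
  along from the panel table (including its one oddity: m/z 115.011 is
  annotated as aspartic acid but classed with the lipid family,
  following the published grouping).
* imzML support is continuous-mode, rectangular-grid only; vendor raw
  formats are out of scope (CSV peak tables are the bridge).
* With the stipulated 10% between-animal CV, ions whose true contrasts
  are below ~1% of the mean (several published fold changes are) have
  trend labels near the noise floor; their signs are not individually
  reproducible at n = 4/8/8, only in aggregate.
* No effect-size shrinkage, no mixed-effects replicate modelling, no
  missing-ion imputation.
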