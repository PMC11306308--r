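---
title: "Assessing bony resection margins from LIBS electrolyte spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing bony resection margins from LIBS electrolyte spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In bone-invasive oral cancer, the surgeon must decide intraoperatively where
non-tumorous bone begins, yet no rapid analytical method for native bone
exists: frozen sections do not work on mineralized tissue, and histological
validation of a bony margin takes days. Laser-induced breakdown spectroscopy
(LIBS) offers a route around this: a pulsed laser ablates a microscopic
tissue volume and the atomic emission lines of the resulting plasma report
the local elemental composition. Tumor tissue carries more potassium and
less soluble (non-hydroxyapatite) calcium than healthy bone, so per-spot K
and soluble-Ca emission values, and their ratio, track the distance to the
tumor border.

`marginlibs` implements this analysis end to end on synthetic data:

1. a seeded generator of LIBS cohorts with four margin-distance classes —
   tumor (distance ≤ 0 mm from the histologically validated border),
   very close (< 1 mm), close (1–5 mm, endpoints included), clear (> 5 mm);
2. per-spectrum electrolyte quantification (baseline deduction,
   baseline-peak normalization, windowed peak-area integration at
   K 765/770 nm and Ca 547/596/610 nm);
3. group statistics (per-class medians/IQR, Kruskal–Wallis, Dunn's post hoc
   with Bonferroni adjustment) for electrolytes and ordinal HOES histology
   grades, plus covariate-adjusted logistic regression per margin
   transition;
4. ROC analysis with DeLong confidence intervals, Youden-index threshold
   rules, and a cascaded four-class margin-status classifier.

The repository is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the package functions and
write their tables under `results/analysis/`.

## The synthetic cohort: what it emulates

No raw spectra from the motivating clinical setting are publicly deposited,
so the generator *is* the study material. Its defaults fix the study
conditions once:

* **Class sizes** 1298 (tumor), 336 (very close), 1092 (close), 2610
  (clear); 5,336 spectra in total, distributed over 10 patients on a 1 mm
  measurement grid with 240 µm spots and 30 shots per position recorded as
  metadata. The analysis unit is the single spectrum (no averaging during
  acquisition); per-position median aggregation is available as an explicit
  optional step (`aggregate_position()`).
* **Spectral model.** Wavelength grid 200–900 nm at 0.25 nm (chosen to
  cover every analysis line plus the Na 589.0/589.6 nm distractor doublet;
  no instrument resolution is dictated by the problem, and the grid is
  configurable). Each spectrum is a broad Gaussian continuum (peak 200 AU
  at 360 nm, width 130 nm, dark offset 20 AU) plus Gaussian emission lines
  of FWHM 0.7 nm and additive Gaussian noise (sd 1 AU). The Gaussian line
  shape gives a closed-form area, which the test suite uses as an oracle.
* **Class-conditional amplitudes.** Per-spectrum K and soluble-Ca
  electrolyte values are independent lognormals whose medians are the
  per-class calibration targets. The log-scale dispersions are not free:
  σ_K = log(6.079/1.9505)/Φ⁻¹(0.95) ≈ 0.691 is fixed by requiring that a
  K threshold of 1.9505 AU detects tumor (median 6.079 AU) with
  sensitivity 0.95, and σ_Ca ≈ 0.749 analogously from the tumor-border
  soluble-Ca discriminability (AUC 0.949). With these two choices the
  whole diagnostic surface (AUC ordering across transitions,
  rule orientations) emerges rather than being imposed.
* **Distances** are uniform within each class's bin (tumor on [−5, 0] mm,
  clear on (5, 10] mm); only the bins are scientifically meaningful.
* **HOES grades** (bone neogenesis/fibrosis; lymphocyte/macrophage
  infiltrates, each 0–3) are drawn from per-class probability vectors that
  are stochastically ordered from tumor to clear, mirroring the reported
  direction of the histology differences.
* **Covariates** (age ~ N(65, 10²) truncated to (30, 95); gender
  Bernoulli(0.5); ordinal G-status with probabilities 0.2/0.6/0.2) are pure
  nuisance variables with no effect on the spectra. Regression odds-ratio
  *magnitudes* on synthetic data are therefore not comparable to clinical
  values; only their directions are.

### Calibration by pipeline inversion

Raw line amplitudes are obtained by inverting the processing chain: the
generator measures the chain's response to unit-amplitude lines on a
noiseless spectrum (the chain is linear in line amplitude, because the
continuum estimator is an order statistic that narrow lines cannot move)
and divides the per-spectrum targets by that response. A small correction
factor, measured on line-free noisy replicates, accounts for noise slightly
inflating the estimated continuum maximum used as the normalization
reference. Processed per-class medians therefore recover their targets by
construction, not by tuning.

Two numerical subtleties:

* With independent lognormal K and Ca, the ratio median is forced to
  median(Ca)/median(K). The three per-class targets are mutually
  inconsistent with that identity by 2.5–4.2%; the generator splits the
  discrepancy evenly on the log scale, so each of the three medians is off
  by at most ~1.4% structurally. Matching all three exactly would require
  a non-lognormal joint distribution for which the source tables give no
  basis.
* Sample medians of iid lognormals with σ ≈ 1 wobble by several percent at
  n = 336. The generator instead draws each class's (K, Ca) pair from a
  randomly shifted two-dimensional Kronecker (R2) lattice mapped through
  the lognormal quantile functions: marginals are preserved, the pair
  stays effectively independent, and empirical medians of K, Ca and their
  ratio all concentrate on the population values at roughly O(log n / n).
  This is a variance-reduction choice about *how* the configured
  distributions are sampled, not a change to the distributions.

## Spectral processing

"Baseline" is resolved into two parts, making each spectrum self-contained:

1. **Dark offset**: the per-spectrum minimum is subtracted.
2. **Continuum**: estimated by three passes of a rolling median (20 nm
   window) followed by a symmetric rolling-mean polish. A rolling median
   rejects emission lines, which occupy well under half of any window, and
   — unlike a low-percentile filter, which sits systematically below a
   curved continuum and under noise — is unbiased on smooth spectra; on a
   pure noiseless continuum the residual is below 1% of the continuum peak.
   The *maximum* of the estimated continuum is the "baseline peak" used as
   the normalization reference, which makes the whole chain invariant to
   positive rescaling of the raw spectrum (tested to 1e-9 relative).

Peak areas are trapezoidal integrals over ±2 nm windows after subtracting
the straight line through the window endpoints; the 2 nm half-width is the
largest that keeps the adjacent K windows (763–767, 768–772 nm) disjoint.
Line areas are *summed* within an element (the ratio is invariant to
sum-versus-mean as long as the choice is consistent). Negative areas in
pure-noise windows are clipped to zero and counted, since emission values
are physically non-negative. A spectrum with zero K emission keeps its K
and Ca values but has an undefined ratio; it is flagged and excluded from
ratio analyses only. A spectrum whose normalization reference is not
positive is excluded as unquantifiable.

## Statistics

* Kruskal–Wallis (tie-corrected, χ² reference with g−1 df) is the global
  test; the fully degenerate all-ties case is reported as H = 0, p = 1.
* Dunn's post hoc z statistics use mean ranks with the tie-corrected pooled
  variance; p-values are Bonferroni-adjusted over all g(g−1)/2 pairs
  (Holm by flag). Bonferroni is the default because it is the common
  default of the clinical statistics software this analysis style comes
  from.
* Medians/IQRs use the type-7 (linear interpolation) quantile convention.
* Logistic models are fitted per transition (outcome 1 = the class nearer
  the tumor) by maximum likelihood via `stats::glm`, with Wald 95% CIs on
  the OR per 1 AU. Complete separation is detected (boundary fitted
  probabilities with exploding standard errors) and reported as such. The
  tests verify the score equations at the optimum, parameter recovery at
  β = log 2, 92–98% null CI coverage, and agreement with an independent
  direct likelihood optimization.
* Spectra are nested within 10 patients, but the models are ordinary
  (non-hierarchical) logistic regressions, replicating the analysis style
  of the setting; this understates standard errors under real clustering
  and is a documented limitation.

## Diagnostic stage

ROC curves are empirical over all distinct thresholds, oriented so
AUC ≥ 0.5 (`">="` = high score calls the positive class). AUC equals the
Mann–Whitney concordance exactly; its variance is the DeLong placement
variance, giving a normal 95% CI clipped to [0, 1] and a p-value against
0.5. The Youden rule maximizes J = sensitivity + specificity − 1 over all
candidate cutoffs, reported SPSS-style as midpoints between adjacent
observed values; ties are broken toward higher sensitivity, then the lower
cutoff. Both AUC and the Youden scan are tested against brute-force
oracles (pair counting; exhaustive scan) and cross-checked against pROC.

The three binary rules are operationalized as a cascade (tumor rule first,
then very-close, then close, else clear) — a construction of this package,
labeled as such in reports: the source analyses evaluate the three
contrasts independently and define no combined procedure. Profiles with an
undefined ratio fall back to the K rules.

## What passing tests do and do not show

The synthetic cohort reproduces the *statistical skeleton* of the clinical
study: class sizes, calibrated medians, stochastic HOES ordering, the
diagnostic separability of the tumor border and the weak very-close/close
contrast. It does not emulate patient-level clustering of emission values,
instrument drift, wavelength miscalibration, self-absorption, or any
covariate–electrolyte association. Green tests therefore validate the
pipeline's correctness and the internal consistency of the published
analysis surfaces — not clinical performance on real tissue.

## Problem sizes and determinism

The default full-size run (5,336 spectra × 2,801 grid points) generates in
~1 s and processes in ~30 s on one core; the test suite runs the full-size
cohort once and shares it across checks, with oracle and coverage
simulations sized (200 random instances; 500 logistic replicates at
n = 2,000 and 1,000) to keep the whole suite within a few minutes. All
randomness flows from the single config seed through named per-stage
substreams; identical configurations give byte-identical datasets and
reports (verified by checksum), and `run_pipeline()` records stage
checksums in a JSON manifest.
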