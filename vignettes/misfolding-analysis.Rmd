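---
title: "Reading alpha-synuclein misfolding from immuno-infrared difference spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading alpha-synuclein misfolding from immuno-infrared difference spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irsyn)
```

## The measurement and its read-out

An immuno-infrared sensor captures alpha-synuclein from cerebrospinal fluid
on an antibody-functionalized ATR crystal and records FT-IR absorbance
spectra before (sample background) and after (sample wash) the capture. The
wash-minus-background difference spectrum is, up to instrument drift, the
absorbance spectrum of the captured protein. Its Amide-I band
(1700–1600 cm⁻¹, the backbone C=O stretch) encodes secondary structure:
alpha-helical/random-coil protein absorbs near 1650 cm⁻¹, amyloid-like
beta-sheet near 1624 cm⁻¹. As misfolding progresses the band's weight moves
downward in wavenumber.

`irsyn` implements the complete chain from raw spectra to cohort statistics:

1. **Preprocess** (`process_run()`): average replicate spectra per stage,
   subtract a fitted water-vapor reference, subtract a two-anchor linear
   baseline, form the wash-minus-background difference, and apply
   Savitzky–Golay smoothing. The canonical order is
   average → vapor-correct → baseline-correct → difference → smooth; every
   stage appends its parameters and scalar diagnostics to a trace carried in
   the spectrum's metadata.
2. **Quality control** (`run_qc()`): spectra are accepted only if the
   Amide-I/Amide-II peak ratio lies in \[1.10, 1.50\] (both bounds included)
   and the signal-to-noise ratio is at least 20, with S the mean absorbance
   over 1560–1540 cm⁻¹ and N the root-mean-square absorbance over
   1800–1900 cm⁻¹ of the *unsmoothed* difference spectrum. Both gates are
   invariant to a global gain.
3. **Features** (`extract_features()`): the absolute Amide-I maximum
   position; the center-of-mass maximum over the upper 85% of the band (a
   robust position estimator for small signals); and the primary read-out,
   the ratio of the absorbance at 1656.0 cm⁻¹ (helix/random-coil side) to
   1623.5 cm⁻¹ (beta-sheet side), evaluated by linear interpolation on the
   smoothed difference spectrum. The ratio decreases strictly as the
   beta-sheet fraction grows.
4. **Classification** (`classify_traffic_light()`): ratios below 1.065 are
   *red* (high misfolding), above 1.14 *green* (low misfolding), and the
   closed interval between is *yellow* (intermediate, at risk). A single
   threshold at 1.093 is available via `classify_single()`. Confusion
   metrics compare the extreme groups only (`confusion_from_extremes()`).
5. **Statistics** (`fit_logistic_score()`, `roc_auc()`,
   `mann_whitney_u()`, `chi_square_sex()`): group comparison of ratios by a
   two-sided Mann–Whitney U test; discrimination by a logistic model of
   disease status on ratio, age and sex, scored as predicted probabilities
   and summarized as the empirical ROC AUC with a DeLong 95% interval.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| Amide-I window | 1700–1600 | cm⁻¹ | canonical backbone band |
| Amide-II window | 1580–1500 | cm⁻¹ | quality gate denominator |
| ratio positions | 1656.0 / 1623.5 | cm⁻¹ | extrema of the group difference spectrum |
| QC ratio range | 1.10–1.50 | — | excludes drift-distorted spectra |
| QC S/N minimum | 20 | — | excludes weak captures |
| smoothing | window 9, order 3 | points | Savitzky–Golay; preserves band shape at 2 cm⁻¹ spacing |
| COM fraction | 0.85 | — | midpoint of the 0.80–0.90 convention; both endpoints are accepted |
| baseline anchors | 1800–1750, 1490–1480 | cm⁻¹ | protein-free flanks |
| vapor window | 1900–1700 | cm⁻¹ | protein-free, line-rich |
| thresholds | 1.065 / 1.093 / 1.14 | ratio | classification constants |

Fractional feature positions (1656.0, 1623.5) are always evaluated by
linear interpolation between grid points, never nearest-neighbour: the
positions are defined at half-wavenumber precision while the default grid
spacing is 2 cm⁻¹. The grid spacing itself is configurable because the
assay does not fix an instrument point spacing.

## Numerical choices

* **Water-vapor coefficient.** The correction subtracts `alpha * vapor_ref`
  with `alpha` fitted by least squares on *second differences* over
  1900–1700 cm⁻¹. Sharp rotational lines dominate the curvature there while
  broad Amide bands and linear baselines contribute almost none, so the fit
  targets exactly the vapor contamination; for a noiseless
  `clean + alpha*vapor` input the coefficient is recovered to machine
  precision. The window is protein-free by construction (it contains the
  noise window).
* **Baseline.** A straight line through the mean absorbance of the two
  anchor windows. Exact for linear drift and idempotent; no algorithm is
  prescribed by the assay, so the simplest correct one is the default.
* **S/N boundary semantics.** Values exactly at a gate boundary are
  included (ratio 1.10, ratio 1.50, S/N 20). The RMS is computed without
  mean subtraction (the literal root-mean-square of the absorbance values);
  a mean-subtracted variant sits behind the `mean_subtract` flag.
* **Traffic-light boundaries.** The red and green calls use strict
  inequalities; ratios exactly at 1.065 or 1.14 are yellow. A ratio exactly
  at the single threshold 1.093 is classified negative.
* **Ties in `absolute_max`** break toward the higher wavenumber.
* **Nonpositive ratio denominators** mark the feature invalid (`NA`) and
  flag the subject; such subjects are excluded from statistics and counted,
  never silently dropped.
* **Perfect separation.** On small cohorts the logistic fit can separate
  perfectly; the score then falls back to the rank of the linear predictor
  (a monotone equivalent, so the ROC is unchanged) with an explicit
  warning.
* **Mann–Whitney branches.** The exact null distribution is used for
  tie-free samples with a smallest group of at most 8; otherwise the normal
  approximation with tie correction. Exactness under ties is undefined, so
  two identical tied samples return U = n₁n₂/2 with an approximate p close
  to (but not exactly) 1.
* **Reported percentages** round half-up to integers (`round_half_up()`),
  matching the precision at which sensitivity and specificity are quoted;
  raw fractions are always retained.

## What the synthetic generator emulates

No public per-subject CSF spectra exist for this assay, so the package
ships a forward model (`simulate_cohort()`) that stands in for them:

* **Band library.** Pseudo-Voigt components at 1650 cm⁻¹ (helix/random
  coil, FWHM 42), 1647 cm⁻¹ (oligomer, FWHM 40), 1624 cm⁻¹ (beta sheet,
  FWHM 28), and an Amide-II band at 1548 cm⁻¹ (FWHM 45) scaled to 0.75× the
  realized Amide-I maximum, which keeps the quality ratio near 1.33.
* **Mass conservation.** A subject's spectrum is a conformer mixture scaled
  to a common integrated Amide-I area: the same amount of captured protein
  redistributes between conformers. This is what produces the
  two-lobed group difference spectrum (beta gain mirrored by
  helix/random-coil loss with comparable integrals).
* **Acquisition effects.** Linear baseline drift shared within a run with
  small per-stage increments, per-stage water-vapor line amplitudes (the
  same fixed line list serves as the correction reference), white noise per
  spectrum (default 1.5e-5 AU, placing default 10-replicate runs at
  S/N ≈ 25–60 so that quality-gate exclusions are confined to the
  low-amplitude tail), and a saturating-exponential binding kinetics trace
  at 1550 cm⁻¹ with a 10-minute injection delay and a 20-minute time
  constant over a 120-minute acquisition.
* **Cohort structure.** Group sizes default to 62 misfolding-positive
  versus 72 controls with the corresponding diagnosis mix, per-group age,
  sex (23% vs 53% female) and albumin-quotient distributions, and
  log-normal Amide-I amplitudes around 5e-4 AU.
* **Calibration.** Per-group beta-sheet fractions follow logit-normal
  distributions whose parameters `calibrate_beta_fractions()` derives once
  by inverting the noiseless forward model at the reported interquartile
  bounds of the ratio (1.01–1.11 positives, 1.08–1.22 controls). The
  subject-level band-center jitter contributes ratio variance of its own,
  which the calibration budgets against the box spread. The jitter standard
  deviation is set to 1 cm⁻¹: it decouples the difference-band extrema from
  the component centers, while a 2 cm⁻¹ jitter alone would exceed the
  spread implied by the published boxes and leave no room for the
  composition signal.
* **Determinism.** One cohort seed fans out into per-subject substreams by
  stable hashing of subject ids, so outputs are bitwise reproducible and
  independent of iteration order.

**What passing tests do and do not show.** The generator reproduces the
published *summary* structure: group quartiles of the ratio, the ordering
of group medians, QC gate behaviour, and the sign pattern of the group
difference spectrum. It is not constrained by published per-subject data,
and box statistics do not pin down tail mass: the simulated cohorts place
more subjects in the opposite-extreme tails than the real study did, so
cohort-level AUC and extreme-group sensitivity/specificity come out lower
in simulation than the assay's reported performance. Those numbers are
therefore reported by the acceptance script as descriptive outputs of the
simulation, not as reproductions of the clinical result. Real-data effects
the generator does not model at all: co-pathology, channel-to-channel
drift, scatter artefacts, CO₂ bands, and non-Gaussian instrument noise.

## Normalization modes for the group difference

`group_difference()` offers two flagged modes. The default normalizes each
subject spectrum to unit Amide-I maximum before averaging, which removes
amplitude variation but pins both group means to 1 at the band maximum —
the difference there is structurally near zero, so the helix-side negative
lobe is strongly suppressed relative to the beta lobe (about 13:1 on this
forward model). The alternative (`normalize = "difference"`) averages raw
spectra, differences, then normalizes the result; under conserved captured
mass this shows the two comparable lobes expected from a conformer
redistribution. Lobe-integral analyses (`band_integrals()`) should
therefore use the difference-normalized mode; the per-lobe boundary is the
zero crossing nearest 1640 cm⁻¹ when one exists, 1640 cm⁻¹ otherwise.

## A small worked run

```{r example}
cfg <- run_config(cohort_config(n_positive = 16, n_control = 16, seed = 7))
report <- run_pipeline(cfg)
cat(make_report(report), sep = "\n")
```

## Problem sizes used by the test suite

Unit and property tests run on single spectra and cohorts of 2–24 subjects;
the calibrated-cohort checks use the full 62/72 study layout once. The
statistical oracles use exhaustive enumeration up to 6 subjects per group
(Mann–Whitney), 10⁴ permutation replicates for the size check, n = 2000 for
the closed-form binormal AUC recovery, and 1000 simulated cohorts of
n = 200 for DeLong interval coverage. These sizes keep the full suite
around a quarter of a minute while leaving the Monte-Carlo tolerances
meaningful.

## Known limitations

* The generator calibrates to published group summaries only; per-subject
  tail behaviour (and hence simulated AUC/sensitivity/specificity) is a
  model property, not data.
* The two-point linear baseline does not handle curved backgrounds; a
  rubber-band alternative is out of scope.
* JCAMP-DX support covers single-block AFFN XYDATA/XYPOINTS files;
  compressed (SQZ/DIF) ordinates and multi-block compounds are rejected
  with explicit errors. Proprietary instrument binaries are upstream
  conversions.
* Whether the group-average band position should be the mean of per-subject
  center-of-mass maxima or the center-of-mass of the group-mean spectrum is
  not decidable from the assay description; the package computes the former
  by default (`mean_com_max` in the run report), and both are available.
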