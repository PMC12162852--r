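# irsyn

Analysis of alpha-synuclein (αSyn) misfolding measured with an
immuno-infrared sensor (iRS): antibody-functionalized ATR-FTIR difference
spectroscopy of cerebrospinal fluid.

## The problem

Synucleinopathies (Parkinson's disease, multiple system atrophy) are driven
by the misfolding of αSyn from α-helical/random-coil toward β-sheet-rich
conformers. The iRS assay captures all αSyn conformers from CSF on an
antibody-coated ATR crystal and reads their *secondary-structure
distribution* directly from the Amide-I infrared band (1700–1600 cm⁻¹):
helical/random-coil protein absorbs near 1650 cm⁻¹, β-sheet fibrils near
1624 cm⁻¹, so the band's weight shifts down in wavenumber as misfolding
progresses. `irsyn` is for analysts working with such spectra (or wanting a
fully testable stand-in for them): it implements the processing chain,
quality gates, spectral read-outs, diagnostic classification and cohort
statistics as one reproducible pipeline.

## The read-out

For each subject the pipeline forms the processed difference spectrum
*D(ν)* (sample wash − sample background, vapor- and baseline-corrected,
smoothed) and computes

* the absolute Amide-I maximum position and the center-of-mass maximum
  ν̄ = Σνᵢ·A(νᵢ) / ΣA(νᵢ) over the upper 85% of the band,
* the primary misfolding score, the absorbance ratio
  **r = A(1656.0) / A(1623.5)** — strictly decreasing in β-sheet content,
* a traffic-light label: **red** (high misfolding) for r < 1.065,
  **green** (low misfolding) for r > 1.14, **yellow** (intermediate, at
  risk) between; a single threshold at 1.093 is also available.

Quality gates follow the assay definition: Amide-I/Amide-II peak ratio in
[1.10, 1.50] and S/N ≥ 20 (S = mean absorbance 1560–1540 cm⁻¹, N = RMS
absorbance 1800–1900 cm⁻¹ of the unsmoothed spectrum). Cohort statistics
are a two-sided Mann–Whitney U test on the ratio, and a logistic model of
disease status on ratio + age + sex scored by ROC AUC with a DeLong 95%
interval.

Because no per-subject CSF spectra are publicly deposited, the package
includes a calibrated synthetic-data generator (`simulate_cohort()`) whose
per-group β-fraction distributions are derived by inverting the noiseless
forward model at the published interquartile ranges of the ratio; every
pipeline stage is testable end to end against it.

## Worked example

```r
library(irsyn)

cfg <- run_config(cohort_config(n_positive = 16, n_control = 16, seed = 7))
report <- run_pipeline(cfg)
cat(make_report(report), sep = "\n")
```

```
== iRS misfolding analysis ==
subjects: 32 (excluded by QC: 0, invalid ratio: 0)
analyzed: 32 (16 misfolding-positive / 16 control)
traffic light: red 13 / yellow 7 / green 12
median 1656.0/1623.5 ratio: positives 1.035, controls 1.180
Mann-Whitney U = 45.0, p = 0.00188
logistic ROC AUC (ratio + age + sex): 0.855 (95% CI 0.712-0.999)
covariate-only AUC (age + sex): 0.648
extremes (red vs green): sensitivity 83%, specificity 77% (tp=10 fn=2 fp=3 tn=10)
```

Reading this: 32 simulated subjects all passed both quality gates; the
misfolding-positive group's median ratio (1.035) sits well below the
controls' (1.180), a difference the rank-sum test calls significant; the
covariate-adjusted model discriminates with AUC 0.855 while age and sex
alone reach only 0.648, so the discrimination comes from the spectral
ratio; and comparing only the clearly-called subjects (red vs green)
classifies 10 of 12 positives and 10 of 13 controls correctly.

Individual stages are plain functions if you bring your own spectra:
`read_spectrum_csv()` / `read_spectrum_jcampdx()` →
`process_run()` → `run_qc()` → `extract_features()` →
`classify_traffic_light()` → `roc_auc()`.

A thin command-line wrapper is installed at
`inst/scripts/irsyn-run.R`:

```sh
Rscript inst/scripts/irsyn-run.R --seed 1 --n-positive 62 --n-control 72 --out out/
```

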