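---
title: "Single-cell Raman classification of focal cortical dysplasia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell Raman classification of focal cortical dysplasia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanfcd)
```

## The problem

Focal cortical dysplasia (FCD) type II is the most common cause of
drug-resistant focal epilepsy in children. Surgical resection can be
curative, but the lesion borders are poorly visible on imaging, and residual
dysplastic tissue frequently leaves patients with ongoing seizures.
Spontaneous Raman microspectroscopy offers a label-free biochemical readout
of single cells: the inelastic scattering spectrum of 785 nm laser light
carries narrow vibrational bands whose positions and intensities reflect the
protein, lipid and nucleic-acid composition of the cell under the beam.

`ramanfcd` implements, as a tested and reusable package, an end-to-end
analysis for this setting: spectral preprocessing, Gaussian peak-fit feature
extraction over a dataset-wide consensus peak set, sparse feature selection,
and a cross-validated linear support vector machine (SVM) evaluated on a
held-out test set with a receiver operating characteristic (ROC) analysis.
Two binary models are built: FCD type II cells versus normal cortical
neurons (model 1), and FCD subtype IIa versus IIb (model 2).

Because the patient spectra underlying this design are not publicly
deposited, the package also ships a forward model of the acquisition — a
synthetic-data generator producing datasets with the statistical structure
the analysis assumes, together with matching calibration reference
measurements. Every stage of the pipeline is therefore verifiable without
any download, against ground truth that the generator knows exactly.

## The acquisition forward model

The generator emulates a confocal Raman microscope acquiring 1024 spectral
bins over 300–1800 cm⁻¹, ten accumulations of equal exposure averaged per
cell. One simulated measurement is built as

\[
y(x) \;=\; r(x)\sum_{i} h_i\,
\exp\!\Big(\!-\,4\ln 2\,\frac{(x-\mu_i)^2}{w_i^2}\Big)
\;+\; A\,e^{-(x-300)/\tau} \;+\; d \;+\; \varepsilon(x),
\]

where the sum runs over the cell's Raman bands (FWHM parameterization
\(w_i\)), \(r(x)\) is a smooth, strictly positive instrument response,
\(A e^{-(x-300)/\tau}\) an autofluorescence-like exponential baseline,
\(d\) the CCD dark level, and \(\varepsilon\) zero-mean Gaussian noise with
variance \(\sigma_d^2 + s \cdot \text{signal}\) drawn independently per
accumulation — the standard CCD read-noise plus Poisson-like shot-noise
model. The reported wavenumber axis is additionally distorted by a small
monotone cubic map, and the generator emits the calibration measurements a
real experiment would provide: a laser-off dark spectrum, the measured and
certified emission of an intensity standard, and known/measured position
pairs of a wavenumber-reference compound (acetaminophen-like shift-standard
positions).

Class structure. Each of the three cell populations (normal neurons,
FCD IIa dysmorphic neurons, FCD IIb dysmorphic/balloon cells) carries the
same 24 bands: the 17 catalogued cortical-tissue bands
(758–1657 cm⁻¹, see `band_catalogue()`) plus 7 shared nuisance bands at
720, 880, 965, 1155, 1365, 1490 and 1680 cm⁻¹, so that the consensus-peak
machinery sees the 24 consistently detectable peaks that define the
72-feature space. Between-class mean height differences are applied only at
the bands reported to differ, with the reported directions (FCD II above
normal at 758, 827, 852, 933, 1263, 1337, 1554, 1602, 1657 cm⁻¹ and below
at 1002, 1031, 1302, 1447 cm⁻¹; IIb above IIa at 852, 1031, 1101, 1124,
1201, 1263, 1302, 1447, 1554, 1593 cm⁻¹ and below at 1002 cm⁻¹), and with
magnitude `effect_scale` × within-class SD. Heights jitter log-normally per
spectrum (CV 0.15, keeping them positive), and a patient-level log-normal
offset (SD 0.05 × height) induces within-patient correlation so that
split-leakage questions can be studied.

Defaults that the study conditions fix: per-class counts 700/396/374
(the published dataset accounting; the abstract's "1420" conflicts with
those counts and is not used), 10 accumulations, 1024 bins over
300–1800 cm⁻¹. Defaults the study does not state, chosen once as realistic
and documented here: band FWHMs of 9–16 cm⁻¹, with the closely spaced
1593/1602 cm⁻¹ pair set narrow (5 cm⁻¹) and relatively tall so the doublet
is resolvable after smoothing — both bands are reported as consistently
detected, so the emulated data must resolve them; baseline amplitude 10× the
mean band height (so baseline removal is genuinely exercised) with decay
scale 600 cm⁻¹ and 30% log-normal amplitude variation; dark level 100
counts with read-noise SD 4; shot-noise scale 0.5. Cosmic-ray spikes exist
as a stressor flag but are off by default, since the protocol mentions no
despiking step.

What the generator does *not* emulate: paraffin residues, H&E
co-registration, optical effects (confocality, objective NA), non-Gaussian
line shapes, and instrument drift. Passing tests therefore demonstrate the
pipeline's correctness and its statistical calibration on data obeying the
assumed model — not performance on real tissue spectra.

## Preprocessing

`run_preprocessing()` applies, per spectrum and in this order:

1. **Accumulation averaging** (when raw accumulations are supplied) —
   pointwise mean.
2. **Dark-count subtraction** of the laser-off measurement.
3. **Instrument response correction**: the standard's measured emission is
   smoothed (same Savitzky–Golay settings as step 5, for parsimony),
   divided by its certified curve and rescaled to unit mean; spectra are
   divided by this estimate. The unit-mean rescaling makes the correction
   invariant to the standard's exposure.
4. **Wavenumber calibration**: a least-squares cubic map from measured to
   known reference-peak positions (centred predictor for conditioning;
   monotonicity verified over the axis), then linear re-interpolation onto
   a uniform 1.1 cm⁻¹ grid *anchored at 700 cm⁻¹*. Anchoring makes the
   closed truncation interval below retain exactly 910 bins; a stated
   "900 bins over 700–1700 cm⁻¹ at 1.1 cm⁻¹" is internally inconsistent,
   and the grid spacing wins here.
5. **Savitzky–Golay smoothing**, order 3, window 11. Each point is replaced
   by the value of the local least-squares cubic over the centred window;
   at the edges the polynomial is fitted on the truncated one-sided window
   (no reflection padding). An order-3 filter reproduces cubics exactly,
   which the tests assert to 1e-9.
6. **Rolling-ball baseline removal**: the background is the morphological
   opening (erosion then dilation) of the spectrum with a disc structuring
   element of radius 120 cm⁻¹ in (cm⁻¹, scaled-intensity) space — the
   envelope traced by a ball rolled under the spectrum — smoothed with the
   same Savitzky–Golay window, then subtracted. The intensity scaling is
   set in two passes: a first opening (scaled by the full data range)
   strips the baseline, and the definitive opening scales intensity by the
   range of that first correction — the peak structure alone — so the
   residual penetration into inter-peak gaps does not grow with the
   baseline amplitude. The radius default sits
   well above any band FWHM (≤ 60 cm⁻¹ by construction) and well below the
   baseline's decay scale, and is exposed in `preprocess_config()` since
   the protocol does not state it.
7. **Truncation** to the closed interval [700, 1700] cm⁻¹.
8. **SNV normalization**: per-spectrum centring and scaling to unit sample
   SD. SNV is deliberately last; the suite asserts mean 0 / SD 1 for every
   spectrum after the full chain.

Degenerate inputs fail loudly with the offending `spectrum_id`: constant
spectra (SNV undefined), non-monotone calibrated axes, non-positive
smoothed response standards, and truncations that leave fewer than two
bins.

## Peak features

Detection operates on the SNV spectrum: local maxima whose topographic
prominence exceeds 3× the noise level, estimated robustly as
`mad(diff(y))/sqrt(2)`; candidates closer than 8 cm⁻¹ are pruned in order
of decreasing prominence. These two thresholds are analysis parameters
(the protocol does not state a detection rule) and live in the
configuration.

Each candidate is fitted by bounded Levenberg–Marquardt least squares with
the model \(h\,e^{-4\ln 2 (x-\mu)^2/w^2} + c\) over a ±15 cm⁻¹ window,
with \(h \ge 0\), \(w \in [2, 60]\) cm⁻¹ and \(\mu\) within ±5 cm⁻¹ of the
candidate. Two implementation choices matter here:

* the **local offset `c`** is a nuisance parameter absorbing the negative
  inter-peak level that SNV necessarily produces (a mean-zero spectrum with
  positive peaks sits below zero between them); without it, heights would
  be biased by tens of percent. The reported features remain (position,
  height, FWHM).
* **territory masking**: within the window, bins closer to a *different*
  candidate than to this one are excluded, so overlapping neighbours — in
  particular the 9 cm⁻¹-spaced 1593/1602 pair — do not pull the fit. A
  non-converged fit falls back to (candidate position, local-max height,
  moment-based width) and is flagged.

The dataset-wide **consensus peak set** is single-linkage clustering of all
fitted positions with the linkage cut at 5 cm⁻¹ — for 1-D positions this
reduces to splitting the sorted positions at gaps above the tolerance,
which the tests verify against a brute-force `hclust` oracle. Clusters
present in at least 80% of spectra are retained ("consistently detected"
is not quantified in the protocol; 0.8 keeps bands absent from occasional
cells), and the consensus position is the member median. The ±5 cm⁻¹
tolerance is half a typical FWHM; catalogue bands are ≥ 11 cm⁻¹ apart
except 1593/1602.

`extract_features()` emits 3 features per consensus peak (position, height,
FWHM). A spectrum lacking a matched fit at some consensus position gets a
constrained refit there (height bounded at zero) rather than an imputed
zero, so absent bands produce near-zero heights *on the intensity scale*
and the matrix has no gaps. With 24 consensus peaks this gives the
72-feature space.

## Classification and evaluation

The modelling procedure, per binary model:

1. a class-stratified 20% test split, set aside before anything is fitted
   (`round(0.2 n_c)` per class; 294 of 1470 spectra for model 1);
2. on the training set, a grid search over the SVM cost
   C ∈ {0.01, 0.1, 1, 10, 100} and the retained-feature count
   k ∈ {4, 8, 13, 24, 48, 72} by stratified five-fold cross-validation,
   scoring fold AUC; standardization and feature selection are refitted
   inside every training fold, so no information leaks into validation
   folds. Ties prefer fewer features, then smaller C;
3. feature selection by an L1-penalized sparse linear classifier: the
   glmnet lasso path is walked to the strongest penalty whose support
   reaches k, and the k largest-|coefficient| features are retained. The
   final classifier is a standard L2 linear SVM (`e1071`) — L1 is used for
   selection only, matching the two-stage description of the procedure.
   No installed package provides an L1-penalized linear *SVM*; sparse
   logistic regression is the same sparse linear-margin selector and only
   the ranking support matters downstream, which the planted-support test
   calibrates (≥ 11 of 13 planted features recovered, median over 20
   seeds);
4. evaluation on the held-out set: ROC over the sorted unique decision
   scores (±∞ endpoints), trapezoidal AUC, and the confusion matrix at the
   **upper-left operating point** — the ROC point minimizing the Euclidean
   distance to (FPR 0, TPR 1), ties resolved toward higher TPR. Sensitivity,
   specificity and accuracy are reported at that threshold, with FCD II
   (model 1) or IIb (model 2) as the positive class.

The default split is stratified by *class*, mirroring a spectrum-level
random hold-out. Spectrum-level splits can leak patient-level structure
(spectra of one patient on both sides); `stratify_by = "patient"` moves
whole patients to one side and exists precisely so that this sensitivity
can be quantified rather than silently ignored.

Determinism: every stochastic step (generator, split, fold assignment)
derives from an explicit integer seed; `run_all()` derives stage seeds from
its global seed, and rerunning a configuration reproduces all numeric
outputs exactly (asserted in the suite).

## Calibration properties the suite enforces

* With `effect_scale = 0` the class profiles are identical; permuted-label
  and null-feature runs give chance-level cross-validated AUC and test
  accuracy (0.5 ± 0.07 and 0.5 ± 0.1 over 20 seeds).
* AUC equals the Mann–Whitney U statistic scaled by \(n_1 n_0\) to 1e-12,
  and is invariant under strictly monotone score transforms.
* Noiseless generator data round-trip: Gaussian parameters to 1e-6
  relative; recovered height *ratios* to 1% (SNV rescales each spectrum by
  its own SD, so absolute heights are not identifiable — ratios are).
* Baseline handling: a pure 10× exponential baseline is suppressed below
  2% residual RMS, and the preprocessed output is insensitive (< 2% RMS)
  to a 4× change of baseline amplitude.

## Problem sizes

Unit and property tests run on reduced problem sizes (512-bin instruments,
tens of spectra) chosen so the full suite completes in a few minutes; the
surrogate study itself — 1470 spectra at the full 1024-bin resolution
through the complete pipeline, both models — runs once and takes on the
order of one to two minutes on a single core.

## Known limitations and recorded discrepancies

* The synthetic surrogate is, by design, easier than real tissue: Gaussian
  bands, exponential baseline, no paraffin residue or lipid-protein overlap
  ambiguity. Surrogate performance (both models near-perfect at
  `effect_scale = 3`) bounds what the code can do on well-behaved data; it
  does not certify field performance.
* Published count inconsistencies are not reproduced, only documented: an
  abstract total of 1420 spectra versus per-class counts summing to 1470
  (the generator follows the per-class counts); subtype-model train/test
  counts exceeding the 770 available FCD spectra (the package applies the
  20% rule, testing 154); a "4:1" train ratio versus the ~1:1.1 class
  counts (the counts win).
* Bands at 756 and 1081 cm⁻¹ are mentioned in the source discussion but
  absent from its band table; the packaged catalogue follows the table
  (758; no 1081).
* Whether "13 retained features" was a grid outcome or a fixed choice is
  ambiguous; both readings are available, since 13 sits in the
  feature-count grid.
* The wavenumber-reference band list of the real instrument software is
  unknown; the package treats the reference-peak table as data, not as
  hard-coded constants.
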