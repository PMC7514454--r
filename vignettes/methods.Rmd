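---
title: "Textural radiomics of CESM lesion ROIs: models, parameters and design choices"
author: "CESMRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Textural radiomics of CESM lesion ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CESMRadiomics)
```

# The problem

Contrast-enhanced spectral mammography (CESM) produces, for every
examination, a low-energy (LE) image — essentially a standard digital
mammogram — and a recombined (RC) image in which dual-energy subtraction
highlights iodine contrast uptake. Radiologists crop a region of interest
(ROI) around each lesion on both channels. This package quantifies the
texture of such paired ROIs and asks which texture descriptors, and which
descriptor families, carry benign-versus-malignant information.

The pipeline has four stages: feature extraction (four fixed-arity sets per
lesion), PCA-based global assessment of each set, feature-importance
analysis (a wrapper and an embedded selector, each validated against
label-permuted baselines with Fisher's exact test), and cross-validated SVM
benchmarking of the selected sub-sets.

# Feature sets

All four sets are computed per channel (LE first, then RC) with a stable
naming scheme `<set>_<channel>_<subimage?>_<direction?>_<statistic>`.

**STAT (22 features).** Eleven first-order statistics of the raw gray
levels: mean, standard deviation, their ratio, variance, skewness,
histogram entropy, relative smoothness, kurtosis, minimum, maximum, range.
Conventions fixed package-wide and checked against brute-force oracles in
the tests:

* population moments (denominator $n$); kurtosis non-excess (Gaussian
  $\to 3$);
* "their ratio" is the coefficient of variation $\sigma/\mu$ (the
  scale-free companion of mean and SD; the alternative reading $\mu/\sigma$
  is a constructor switch away, since only the reciprocal changes);
* entropy is Shannon entropy in bits of the gray-level histogram — one bin
  per integer level for integer images, 256 uniform bins over
  $[\min,\max]$ otherwise (the common radiomics default when no binning is
  prescribed);
* relative smoothness $R = 1 - 1/(1+\sigma^2_{01})$ with $\sigma^2_{01}$
  the variance after linear rescaling to $[0,1]$, so $R \in [0,1)$ and is
  intensity-scale free;
* degenerate inputs return 0 by convention (constant image: SD, entropy,
  $R$, skewness, kurtosis, range; zero-mean image: $\sigma/\mu$). These
  conventions keep every downstream selector total.

**GRAD (24 features).** The Sobel gradient field $(f_x, f_y)$ is computed
by 3×3 convolution with symmetric edge reflection; magnitude
$\sqrt{f_x^2+f_y^2}$ and direction $\mathrm{atan2}(f_y,f_x)$ (zero where
both derivatives vanish) each contribute the six moment-type statistics
(mean, variance, skewness, entropy, relative smoothness, kurtosis).
Direction values are treated as plain reals on $[-\pi,\pi]$ — ordinary, not
circular, moments — matching how such statistics are usually applied to
gradient orientation maps. Prewitt kernels are deliberately not offered.

**HAAR (96 features).** A two-level separable orthonormal Haar analysis
(filters $(1,1)/\sqrt2$ and $(1,-1)/\sqrt2$) yields sub-images LL1, HL1,
LH1, HH1 and, reapplied to LL1 only, LL2, HL2, LH2, HH2. The six
moment-type statistics of each of the eight bands give 48 per channel. Odd
dimensions are edge-replicated to even size at each level (recorded in the
decomposition); replication avoids the spurious high-frequency edge energy
a zero pad would inject, and statistics are computed on the padded bands.
Orthonormality is enforced by tests: energy is conserved per level to 1e-8
relative and reconstruction is exact on the unpadded region.

**GLCM (312 features).** Gray-level co-occurrence matrices are computed on
the level-1 detail bands HL, LH, HH of each channel, in the four offsets
0°, 45°, 90°, 135° (row/col convention with origin top-left), accumulated
symmetrically and normalized. Thirteen Haralick-type statistics per matrix
— contrast, correlation, cluster prominence, cluster shade, dissimilarity,
energy, entropy, homogeneity, sum average, sum variance, sum entropy,
difference entropy, normalized inverse difference moment — give
3×4×13 = 156 per channel. Numerical choices:

* quantization to `nLevels = 16` equal-width bins over each band's own
  $[\min,\max]$ and offset distance `d = 1` — standard radiomics defaults,
  both recorded in the table metadata and exposed as arguments. Detail
  bands are signed, so quantizing over the band's own range is the natural
  mapping;
* levels are indexed 1..Ng in the statistics; this affects only the
  location-type descriptors (sum average);
* sum variance is centered on the sum average (the other Haralick dialect
  centers on sum entropy; the choice is config-switchable in spirit — the
  statistic function takes the matrix, so an alternative centering is a
  one-line wrapper);
* a flat band makes the correlation denominator vanish; correlation is then
  0 by convention so every feature stays finite;
* $0\log 0 := 0$ in all entropies.

Every statistic is verified against an independent brute-force double-loop
oracle at Ng ∈ {2, 4, 8, 16} in all four directions.

# Feature importance

**Wrapper.** A two-step procedure: (1) keep features with a two-sided
Wilcoxon–Mann–Whitney rank-sum p < 0.05 (normal approximation with tie
correction; a constant feature yields p = 1 and is never kept; no
multiplicity correction, deliberately); (2) sequential backward selection
with a Gaussian naive Bayes classifier, scored by stratified 5-fold
cross-validated misclassification error with a fixed inner fold seed. The
search removes the feature whose removal most decreases the error and stops
at the first local minimum (no removal strictly decreases the error). Ties
are broken by the larger filter p-value, then name order, so results are
reproducible. Because the naive Bayes log-posterior is additive over
features, each fold's per-feature log-density slices are cached once and a
candidate removal is scored by subtraction — the search is $O(p^2 n)$
rather than $O(p^3 n)$ refitting.

**Embedded.** A 500-tree random forest; per-feature importance is the mean
decrease in out-of-bag accuracy when that feature's out-of-bag values are
permuted (unscaled), and features with importance strictly above the
unweighted mean over all candidates are selected. Correlated copies of a
strong feature share importance and may both clear the mean; this is
documented behavior rather than a defect of the rule.

**Significance of selection frequency.** Neither selector's output is
meaningful without a chance baseline. Each selector is run `nRounds` (default
100, minimum 20) times on stratified bootstrap resamples with the true
labels and `nRounds` times with labels freshly permuted within each resample;
per feature, the 2×2 table of selection counts is tested with a one-sided
Fisher's exact test for enrichment under true labels at α = 0.05
(two-sided available). One-sided enrichment is the question actually asked
— a feature selected *less* often than chance is not a discovery. The
resampling scheme (stratified bootstrap, 100 rounds per arm) is this
package's choice of how to give a stochastic selector a selection
*frequency*; fold-based or repeated-run schemes would be equally valid, and
the round count is a parameter. Rounds in which a selector fails are
dropped; if fewer than 90% succeed the analysis aborts rather than report a
biased frequency. Fisher p-values are verified against exhaustive
hypergeometric tail sums over all count pairs at margins up to 100.

# Evaluation

PCA (z-score standardization, then an eigendecomposition of the
correlation structure) orders components by explained variance with a
deterministic sign convention. The PC sweep trains a linear SVM on the
first $k$ components for $k = 1, 2, \ldots$; standardization and PCA are
refit inside every training fold, never on the full data, so the curves are
honest out-of-sample estimates — a global PCA before cross-validation would
leak test-fold variance structure and flatter the curve.

The benchmark classifier is a linear-kernel SVM with unit cost and no class
weighting (the cohort is near-balanced); an RBF kernel is a parameter away
but not used in reports. Discrimination is measured by stratified 10-fold
cross-validation repeated 100 rounds with round-specific shuffles;
malignant is the positive class, so sensitivity is the malignant detection
rate and specificity the benign one. Reported per metric: the mean percent
over rounds and the 95% interval mean ± 1.96·sd/√rounds (a normal
approximation over round means). Per-round confusion counts always satisfy
TP + FN = #malignant and TN + FP = #benign, which the tests assert.

# The synthetic cohort generator

No clinical CESM collection ships with the package; a seeded generator
provides cohorts with the same structure so that every downstream stage is
exercised end to end. Its defaults mirror the structure of a screening
cohort: 55 lesions (29 benign, 26 malignant), four background parenchymal
enhancement (BPE) levels assigned round-robin within each class (per-level
class counts differ by at most 1), ROI sides uniform on 32–96 px, 16-bit
gray levels written as uncompressed TIFF.

Per lesion — with an RNG stream keyed by (seed, lesion index), so cohorts
are extensible without reshuffling earlier lesions — the model is:

1. **Background**: Gaussian-filtered white noise (separable filter,
   σ = correlation length, 4 px for both classes — the simplest stationary
   texture with controllable second-order structure), scaled to
   `backgroundSd` (1500 gray levels) times a BPE multiplier spaced
   0.5–1.5 over the levels.
2. **Lesion mask**: a centered quasi-ellipse (radius ≈ 0.3 of the side)
   whose radius is modulated by a truncated Fourier perturbation over
   harmonics 3–8 with random phases — one scalar amplitude turns a smooth,
   benign-like margin into a spiculated, malignant-like one. The mask is
   smoothed with a 1-px Gaussian so the margin is a ramp, not a step.
3. **Channels**: RC adds the enhancement amplitude inside the mask plus
   in-lesion high-frequency texture (white noise scaled by
   textureEnergy × amplitude); LE adds the same lesion terms scaled by
   `leFactor = 0.35`, mirroring the fact that the recombined image
   highlights contrast uptake while the low-energy image shows a weaker
   density correlate.
4. White noise (`noiseSd = 300`), rounding, clipping to 16 bits (defaults
   clip fewer than 0.1% of pixels; tests assert this).

Class defaults — benign: amplitude 5000, irregularity 0.08, texture energy
0.08; malignant: amplitude 6500, irregularity 0.28, texture energy 0.25 —
were calibrated once with `classSeparabilityReport()` so that RC-derived
first-order features separate the classes strongly (|d| > 0.8 for at least
one RC feature, the generator's acceptance gate) and then frozen. Setting
both classes to identical parameters is the built-in null: downstream CV
accuracy is then statistically indistinguishable from 50%, which the test
suite checks across generation seeds.

**What the generator does not emulate.** Real CESM ROIs have anatomical
structure (ducts, vessels, skin lines), scanner-specific noise and
artifacts, radiologist-dependent cropping, and correlations between lesion
size, BPE and malignancy. The synthetic classes are also cleanly separated
— cross-validated accuracies in the high 90s rather than the ~64–80%
typical of clinical texture studies — because the generator plants its
signal directly in second-order statistics. Passing tests therefore
demonstrate that the *machinery* (extraction arities and formulas,
selection calibration, honest cross-validation) is correct and that planted
signal of known location is recovered; they say nothing about how much
texture information real CESM lesions carry.

# Problem sizes in the tests and acceptance script

The shipped tests run the full default cohort (55 lesions) for the
structural and signal-recovery checks, 100 resampling rounds per arm for
the selection-frequency criterion, and reduced round counts (20–25 CV
rounds, 25–40 selection rounds) where only calibration — not precision — is
at stake; these sizes are the package's choice of a thorough-but-quick
default and are parameters everywhere, so a user can scale any of them back
up to the 100×10-fold geometry of the full analysis.

# Known limitations

* DICOM ingestion is not provided; ROIs arrive as PNG or TIFF. Lesion
  segmentation is out of scope — ROIs are rectangular crops, and whether a
  masked-lesion variant would change feature rankings is untested.
* Direction statistics use ordinary moments on angles; circular statistics
  would be the alternative for strongly anisotropic textures.
* The Fisher step tests each feature marginally; correlated features yield
  correlated significance calls, and no multiplicity correction is applied
  (by design, to report per-feature selection stability rather than a
  family-wise discovery claim).
* The normal-approximation CI over CV rounds understates uncertainty from
  the single finite cohort (rounds reuse the same lesions); it quantifies
  fold-assignment variability only.
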