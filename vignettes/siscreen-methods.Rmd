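---
title: "Methods: simulation, segmentation, screening and scoring in siscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, segmentation, screening and scoring in siscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`siscreen` implements a computationally-guided histologic biomarker
workflow for lung squamous cell carcinoma tissue microarrays: a feature
screen against censored survival, the stromal inflammation (SI) score with
its recording and paired-core rules, PD-L1 scoring, and the downstream
survival battery. This vignette is the package's account of the methods:
what each stage assumes, which parameters matter and why their defaults
are what they are, what the synthetic data do and do not emulate, and
where the numerically delicate choices sit.

## 1. The synthetic TMA core

Real TMA cores are 0.6 mm discs of tissue, two per patient, sampled from
representative tumor regions. `generate_tma_image()` renders a stylized
analog on a `width x height` raster (default 128 px — small enough that a
sixty-case cohort with two cores per case segments in minutes on one CPU,
large enough to hold several epithelial nests and a connected stromal web):

* **Tissue disc.** Pixels within 0.47·min(width, height) of the center are
  tissue; the rest is near-white background.
* **Epithelial nests.** A Gaussian white-noise field is smoothed with a
  Gaussian kernel of `nest_scale / 2` (default nest scale 20 px) and
  thresholded at the quantile matching `epithelial_fraction` (default 0.5),
  producing contiguous smooth blobs. No claim is made that real nest
  geometry follows a thresholded Gaussian field; only the downstream
  compartment contract (each tissue pixel is epithelial or stromal) matters.
* **Nuclei.** Epithelial nuclei are discs with radius
  `nuclear_radius_mean` (default 6 px, SD 0.8) packed by random sequential
  placement to ~40% of nest area with a one-pixel separation; inflammatory
  cells are darker discs at one third of that radius, mirroring the size
  contrast between tumor nuclei and small lymphocytes. Placements that
  would be clipped below 60% of their nominal disc area by the compartment
  boundary are rejected, so no sliver cells exist in the ground truth.
* **Inflammation density.** Inflammatory discs are added until they cover
  `stromal_inflammation_density` of the stromal area. The stored
  `true_si` is then *recomputed exactly* from the final masks, so it is
  consistent with the rendering by construction even when dense packing
  saturates below the requested target.
* **Stains.** Colors come from a four-entry palette (epithelial nuclei,
  cytoplasm, stromal matrix, inflammatory nuclei) chosen to mimic
  hematoxylin/eosin hue relationships, plus coarse and fine texture noise
  and additive Gaussian noise (`noise_sd`, default 0.02).

The renderer deliberately does **not** attempt photorealism: no stain
variation between "slides", no blur, no folds, no necrosis, no
out-of-focus regions, no non-inflammatory stromal nuclei (fibroblasts,
endothelium), and no IHC rendering — PD-L1 exists only as a case-level
number. Consequences for interpretation: a passing segmentation or
SI-recovery test shows the pipeline's logic is correct and its accuracy
high *under these idealized optics*; it does not certify accuracy on real
H&E, where compartment classification is known to be substantially harder
(particularly separating inflamed epithelium from inflamed stroma).

## 2. The simulated cohort

`generate_cohort()` draws, per case:

* **True SI** from a Beta distribution with moments (`si_mean` = 0.25,
  `si_sd` = 0.20). A Beta keeps SI in [0, 1] without the boundary atoms
  that Gaussian clipping would create.
* **Per-core SI targets**: case SI plus Gaussian noise
  (`core_heterogeneity_sd`, default 0.20, clipped to [0, 1]). The default
  was chosen so that the attenuation var(SI)/(var(SI) + sd²) puts the
  paired-core rank correlation of recorded scores near 0.5, the level at
  which intratumoral heterogeneity becomes a first-order concern. Each
  core's image parameters inherit its SI target as the inflammatory
  density, which is what makes the image pipeline end-to-end testable.
* **PD-L1** with a point mass at 0.00 (probability `pdl1_zero_mass`,
  default 0.60) and a Beta(0.8, 4) tail otherwise, coupled to SI through a
  Gaussian copula. Because the zero point mass ties the lower ranks, the
  latent correlation needed to achieve a target Spearman rho is larger
  than the target; `calibrate_latent_rho()` inverts the attenuation by a
  deterministic Monte-Carlo root-find (fixed internal seed, n = 40,000).
  The default target rho is 0.20 — a deliberately weak association, so
  that SI and PD-L1 carry close to orthogonal information.
* **Covariates**: ordinal stage 1–4 and grade 1–3 entering all models
  linearly, age in years, binary vascular and pleural invasion.
* **Survival** from an exponential proportional-hazards model: hazard
  `baseline_hazard · exp(lp)` with
  `lp = β_si·SI + β_stage·(stage−2) + β_age·(age−65) + β_vasc·vasc +
  β_int·SI·1[PD-L1 high]`, censored by an independent exponential
  (`censoring_rate`). Default log hazard ratios follow the magnitudes of a
  published multivariate lung-SCC model (HR 0.32 per unit SI, 1.59 per
  stage unit, 1.04 per year, 1.84 for vascular invasion, no interaction);
  `baseline_hazard` = 0.015/month and `censoring_rate` = 0.008/month give
  a median survival near 3 years and roughly 60–65% events, typical of a
  long-follow-up surgical cohort. Covariate centering only rescales the
  baseline hazard; it does not change any hazard ratio.

The exponential baseline is the simplest model satisfying the
proportional-hazards assumption that every downstream analysis makes; the
package makes no claim about robustness to non-proportional hazards.

## 3. Segmentation

* **Superpixels** are a k-means (Lloyd, 10 iterations, grid-seeded —
  hence deterministic) clustering in (R, G, B, row, col) space with the
  spatial coordinates weighted by `compactness / target_size`, an
  SLIC-style partition. The default `target_size` of 8 px was calibrated
  on synthetic cores: at 12 px too many superpixels straddle nest
  boundaries and inflammatory cells near borders inherit the epithelial
  label, which depresses both compartment accuracy and SI recovery.
* **The classifier** is a linear discriminant (equal priors) on 14
  per-superpixel descriptors (mean/SD of five channels, dark-pixel
  fraction, gradient statistics, log area). Linear discriminants are
  deterministic, symmetric under label swap, and — because training rows
  are deduplicated first — invariant to duplicated examples, three
  contract properties a bootstrap tree ensemble could not provide.
  Training examples come from `training_examples_from_truth()`, the
  synthetic stand-in for an expert painting example regions.
* **Cells** are detected by Otsu thresholding of tissue luminance (dark =
  hematoxylin-dense), split by distance-transform watershed (tolerance
  0.5, so that two small discs touching diagonally still separate), and
  filtered at a minimum object size of **5 px**. The floor is set below
  the rendered inflammatory-cell area (~9–13 px at default scale) with
  margin: a 10 px floor was observed to silently delete most of the very
  class the SI score counts, and the pre-watershed morphological opening
  usually paired with it erodes 13 px discs to 9 px; speckle suppression
  is the size filter's job. Objects are assigned the majority compartment
  of their pixels; stromal objects at or below `inflammatory_max_area`
  (40 px²) with circularity ≥ 0.4 are inflammatory cells; epithelial
  objects are epithelial nuclei. Disjoint cytoplasmic zones are carved
  from a dilation halo by nearest-nucleus propagation within the
  compartment.
* **The audit** replicates a manual protocol: only superpixels and
  ground-truth cells touching the middle row (`height %/% 2`, 0-based) are
  assessed. A truth cell counts as detected when at least half of its
  pixels are covered by some detected object.

## 4. The feature catalogue

The catalogue is a fixed factorial: 2 compartments × 2 object classes
(nuclear, cytoplasmic) × 96 base measurements × 4 cross-object summaries
(mean, SD, max, min) = 1,536 features, 768 per compartment. The 96 base
measurements are 16 morphometrics (area, perimeter, equivalent diameter,
major/minor axis, eccentricity, solidity, extent, circularity, aspect
ratio, convex area, border length, radius mean/SD, roundness, compactness;
units px and px², no physical calibration) plus 16 intensity statistics on
each of 5 channels (R, G, B, luminance, blue-ratio). The composition was
chosen to cover "size, shape and texture" while hitting the 768-per-
compartment count exactly; the name ordering is versioned by an MD5
checksum in the tests, so any change is a deliberate version bump. A
compartment/class with no objects yields NA for its whole block (not
zero — absence of evidence, not evidence of absence); per-object SDs over
a single object are 0 by convention. Case-level values are the mean of
the two cores, with a single-scored-core fallback and NA only when
neither core is scored — the same rule as the SI score itself.

## 5. The survival screen

Per feature, the statistic is the Cox partial-likelihood efficient score
at β = 0: `d = U / (sqrt(V) + s0)`, with U the sum over deaths of the
feature minus its risk-set mean and V the summed risk-set variances,
Breslow convention for ties. `U/sqrt(V)` squared equals the `coxph` score
test exactly (asserted in the tests at 1e-10), and the statistic is
invariant under monotone time transformations. `s0` defaults to the 5th
percentile of the per-feature standard errors, a variance-stabilizing
constant that keeps near-constant features from dominating the tails; the
permutation count defaults to 1,000; screening is two-sided.

The null is built by jointly permuting `(time, event)` pairs against the
feature rows. The q-value of a feature is the estimated false discovery
rate at its cut-point: π̂₀ times the expected number of null exceedances
of |d| per permutation, divided by the observed exceedance count,
monotonized to be non-increasing in |d| and clipped to [0, 1]. Two
numerical choices deserve comment:

* **Mean, not median, null exceedances** (the median is available via
  `fdr_estimator = "median"`). With only a few hundred features the
  median count at the observed *maximum* is zero in about half of
  pure-null screens — the estimator then reports q = 0 for the top
  feature and manufactures a false hit every time. The mean count does
  not collapse and keeps the realized false-discovery proportion near the
  nominal rate at this scale; both variants are standard summaries in the
  SAM family.
* **π̂₀** is the fraction of observed |d| inside the null interquartile
  range divided by 0.5, capped at 1.

Features missing in more than 20% of cases are dropped; the remainder are
screened on their complete cases. The expression screen applies the same
permutation-FDR machinery to Spearman correlations between case SI and
each gene (ranks precomputed once; permuting SI ranks), with hits
restricted to positive correlations when `positive_only = TRUE`.

## 6. Scoring rules

* **Raw SI** = inflammatory-cell pixels inside the stromal compartment /
  stromal pixels. Inflammatory-like objects inside epithelial nests are
  excluded (peri-tumoral stroma only). The denominator is *all* stromal
  tissue: restricting to desmoplastic stroma specifically is not separable
  by this classifier and is a stated limitation.
* **Quantization** maps raw SI to the nearest point of the 0.05 grid,
  exact midpoints rounding up, implemented as
  `floor(20·x + 0.5 + 1e-9)/20` — the 1e-9 guard absorbs binary
  representation error for values like 0.15 without disturbing any
  genuine midpoint. The human rule ("values estimated between two
  increments are recorded as the middle value") is not machine-executable
  verbatim; nearest-grid with half-up ties is its deterministic analog
  and reproduces the printed example (raw 0.34 → 0.35).
* **Case SI** is the mean of the recorded core scores; if exactly one
  core was scored, that core; NA only when neither was.
* **Delta-value** = |core1 − core2|; the heterogeneity split is at the
  cohort median with ties going to "low" (high means *strictly* greater).
* **PD-L1**: a core needs ≥ 100 viable tumor cells to be scorable, the
  score is stained/viable, cases average their scored cores, and the
  "high" stratum is any score strictly above 0.00.

## 7. Survival battery

Cases surviving less than one month are excluded before modeling. All
Cox fits use the Breslow tie convention (Efron available through the
`ties` argument of the internal wrapper); fits are deterministic. The KM
median split puts ties in "low" (high = strictly above the median SI).
The multivariate model uses the fixed covariate set {stage, age, vascular
invasion, SI, pleural invasion, grade} on complete cases, reports the
complete-case n, warns below 10 cases per covariate, flags rank-deficient
design matrices, and orders its report by p-value. The interaction model
contains SI, a PD-L1-high indicator, and their exact product term; the
per-stratum KM splits use the within-stratum median by default
(`global_median = TRUE` switches to the cohort-wide median — which of the
two the original analyses used is not determinable, and the choice is
therefore exposed).

## 8. Problem sizes and calibration experiments in the tests

The test suite runs every stage at sizes chosen to make Monte-Carlo
conclusions stable on a single CPU: 128 px cores; 60 cores across
inflammation densities 0.1–0.6 for SI recovery; null-screen calibration at
200 features × 150 cases with 500 permutations, replicated 300 times (a
50-replicate estimate of the mean false-discovery proportion has a
standard error of ~0.036, too coarse to separate a calibrated screen from
the acceptance bound; 300 replicates bring it to ~0.015); hazard-ratio
recovery over 50 cohorts of n = 400 with only the SI effect active —
a Cox hazard ratio is non-collapsible, so leaving nuisance effects on
would attenuate the univariate estimate even without confounding, and the
experiment is designed to isolate the parameter being recovered; and the
interaction pattern over 25 cohorts with a large SI effect
(log HR = −5 per unit SI) exactly canceled in the PD-L1-high stratum.

## 9. Known limitations

* Synthetic optics are idealized; accuracy numbers on synthetic cores are
  upper bounds for real H&E.
* The renderer draws no non-inflammatory stromal cells, so the stromal
  object population is purer than reality; the inflammatory-cell
  classification rule (small + round) would misclassify some fibroblasts
  and macrophages on real tissue — which the score's definition tolerates,
  since only lymphocyte/plasma-cell-sized round objects are counted.
* PD-L1 is simulated at the case level; no IHC image analysis exists in
  the package.
* The SAM-style q-values are estimates, not guarantees; at very small
  feature counts (tens) any exceedance estimator is granular.
* Superpixel boundary error biases the computed raw SI downward relative
  to ground truth (boundary inflammatory cells inherit the epithelial
  label); the bias is monotone-preserving across cores, which is why the
  package's validation criterion for SI is rank correlation with ground
  truth rather than absolute agreement.
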