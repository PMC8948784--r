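---
title: "Predicting IBD disease course from fecal GC-IMS VOC profiles"
author: "vocims maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting IBD disease course from fecal GC-IMS VOC profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocims)
```

## The problem

Inflammatory bowel disease (IBD) alternates between remission and
exacerbation, and clinical symptoms correlate poorly with the underlying
mucosal inflammation. Volatile organic compounds (VOCs) in feces are
metabolic end-products of the host--microbiome interaction and change with
inflammation, so the *scent pattern* of a stool sample may carry
information about where the disease is heading. `vocims` implements a
complete, testable version of the corresponding analysis: given gas
chromatography--ion mobility spectrometry (GC-IMS) measurements of fecal
samples and longitudinal clinical metadata, it asks whether the VOC
profile of a sample collected *first* predicts the disease-activity state
at the *next* collection.

The pipeline has five stages, each a package module:

1. **Data model / IO** — `GCIMSSpectrum` holds one sample's dense 2-D
   intensity matrix (GC retention time × IMS drift time) with axis
   metadata; an open interchange format (headerless CSV matrix + JSON
   sidecar) replaces the proprietary vendor format, whose conversion is
   assumed to happen upstream.
2. **Disease-state labelling and pairing** — fecal calprotectin (FCP) and
   the clinical activity indices (HBI for Crohn's disease, SCCAI for
   ulcerative colitis) are mapped to REMISSION / ACTIVE /
   INDETERMINATE, and consecutive same-patient samples become transition
   pairs (groups A1–A4 clinical, B1–B4 biochemical).
3. **Preprocessing** — crop, background threshold, flatten to features.
4. **Modelling** — per-fold Wilcoxon rank-sum feature selection with SVM
   and random-forest classification, cross-validated or on a 70/30
   hold-out.
5. **Evaluation** — ROC/AUC with confidence intervals, Youden-optimal
   cut-off metrics, and a rank-sum p-value per comparison.

Because the underlying clinical raw data are not publicly deposited, the
package also ships a **synthetic cohort generator** that emulates the
statistical structure the analysis relies on. All claims made by the test
suite are claims about this stated synthetic world, not about clinical
performance.

## Disease-state machine

Biochemical state from FCP (mg/g): ACTIVE iff FCP ≥ 250, REMISSION iff
FCP < 100, otherwise INDETERMINATE (the definitional gap [100, 250)).
Clinical state: for CD, ACTIVE iff HBI ≥ 5, REMISSION iff HBI < 4 — HBI
= 4 falls in a gap and is INDETERMINATE; for UC/IBD-U, ACTIVE iff SCCAI ≥
3, REMISSION iff SCCAI ≤ 2 (no gap). The cut-offs are configuration
(`stateThresholds()`), not constants, because the surrounding literature
uses endoscopy-correlated FCP cut-offs anywhere in 200–250 µg/g; mg/g and
µg/g are treated as synonymous, with no unit conversion.

Pairing reads "subsequently collected" as *adjacent in collection order*:
each consecutive pair in which both members are determinate becomes a
transition pair, and a middle sample may close one pair and open the
next (an FCP trajectory 300, 260, 80 yields B3 then B4). This maximizes
usable pairs; every exclusion (indeterminate state, missing score) is
logged in the `dropped` attribute rather than raised, because the two
recruiting centers recorded different variables.

```{r states}
classifyBiochemical(c(250, 99.9, 150))
md <- simulateMetadata("B2", nPairs = 3)
pairSamples(md, "BIOCHEMICAL")[, c("patient_id", "group")]
```

## Preprocessing

A real GC-IMS run produces ~11 million datapoints of which only a central
region carries chemical information. The pipeline therefore:

1. **crops** every sample with the same window (`CropWindow`, 1-based
   inclusive indices; in practice such windows are chosen by visual
   inspection of the instrument output, so the window is a required
   configuration value with defaults defined for the synthetic geometry);
2. estimates a per-sample **background model** over chemically empty
   regions — by default the pre-RIP drift columns plus the last 10% of
   retention rows — and removes noise at the threshold
   τ = μ_bg + 2σ_bg (sample SD, n−1 denominator, fixed for
   bit-reproducibility);
3. **flattens** the window row-major into a feature vector, carrying the
   bijective map back to (retention, drift) cells so selected features can
   be replotted onto the raw spectrum (`replotFeatures`).

Two decisions that written descriptions of this procedure usually leave
open are fixed here and matter for
reproducibility: values below the threshold are **zeroed, not
subtracted**, and the threshold is **per sample**, not cohort-wide
(per-run quality control suggests per-sample handling, and it absorbs
baseline drift). A "feature" is one cell of the cropped matrix, optionally
mean-pooled over `binSize × binSize` blocks (default 1); cells are the
minimal faithful reading of "features with exportable locations", since no
peak-picking step is defined.

## Modelling

`runCV()` performs stratified, seeded 10-fold cross-validation. Inside
each fold — and only inside it — features are ranked by two-sided
Wilcoxon rank-sum p-value on the training rows, the top `nFeatures`
(default 100) are kept, classifiers are fitted on the training rows of
those columns, and the held-out samples receive class-1 probabilities.
Out-of-fold probabilities are pooled before ROC analysis (pooling, rather
than averaging per-fold curves, is this package's documented choice).
`runHoldout()` implements the alternative protocol of a single stratified
70/30 split. Both protocols are in circulation for this kind of analysis;
CV is the default and every report names its mode.

Design decisions:

* **Stratified folds, keyed by sample id.** Minority groups of 7–8
  samples make unstratified folds frequently single-class. Rows are
  canonically ordered before fold assignment, so results are invariant to
  input row order given the seed.
* **Patient-level grouping** (`groupFoldsByPatient`, default on): when one
  patient contributes several pairs, all of them stay in one fold,
  avoiding twin-sample leakage; the safe default was chosen.
* **Wilcoxon p-values**: exact (null rank-sum distribution) when both
  groups have ≤ 25 samples and there are no ties; exact by complete
  enumeration of all group assignments for tied data with ≤ 10 total
  samples; otherwise the tie- and continuity-corrected normal
  approximation. The small-sample enumeration path exists so that *every*
  small input — tied or not — is exact and oracle-checkable; thresholded
  spectra are full of zero ties, and silently dropping to an approximation
  for exactly those cases would make the small-sample tests vacuous.
  Ties in p are broken by ascending feature index.
* **Classifiers.** No SVM or random-forest implementation is available in
  the dependency budget, so both are implemented in compiled code within
  the package: an RBF-kernel C-SVC trained by SMO (cost 1, γ = 1/p,
  features standardized with training-fold statistics) with Platt sigmoid
  calibration on 3-fold cross-validated decision values, and a CART/gini
  random forest (500 trees, `mtry = floor(sqrt(p))`, trees grown to
  purity, probability = vote fraction). All hyperparameters are pinned
  and documented, since nothing about this procedure dictates them. Both consume R's RNG, so
  `set.seed` makes them bit-reproducible.
* **Leakage sentinel.** `selectionScope = "all"` deliberately ranks
  features on the whole data set before cross-validation. It exists only
  so the test suite can demonstrate that the leakage guard matters: on
  pure-noise data with many more features than samples the correct
  pipeline stays at AUC ≈ 0.5 while the leaky variant exceeds 0.65.

## Evaluation

For each comparison and classifier the report contains: AUC (Mann–Whitney
identity: the probability a random case outranks a random control, ties
half); a 95% confidence interval from the DeLong placement-value variance,
mapped through the logit scale by the delta method — the plain Wald form
undercovers noticeably at the small, imbalanced group sizes relevant here
(8 cases vs 41 controls), while the logit form stays near nominal, as the
package's own Monte-Carlo coverage test verifies; the cut-off maximizing
Youden's J = sensitivity + specificity − 1 over observed probability
values (ties broken by higher sensitivity, then lower cut-off; predicted
positive means probability ≥ cut-off, which keeps the confusion matrix
integer-valued and reproduces the spec = 1 ⇒ PPV = 1 pattern); and a
two-sided Mann–Whitney p-value comparing the held-out probability
distributions of the two classes — the minimal rank-based choice, coherent
with the AUC through U = AUC·n₁·n₀; a label-permutation alternative is
available (`method = "permutation"`).

No multiple-testing correction is applied across comparisons; pilot
analyses of this kind typically report uncorrected per-comparison
p-values, and correction policy is left to the caller.

## The synthetic world

`cohortDesign()` states the world the tests live in:

| parameter | default | why |
|---|---|---|
| matrix shape | 200 × 150 | desk-scale stand-in for ~11M datapoints; all algorithms are shape-agnostic |
| RIP | full-height ridge, drift col 30, amplitude 5000 | mimics the carrier-gas reactant-ion peak; gives the crop something to cut |
| shared peaks | 60, early-retention biased | light volatiles elute early; identical across groups |
| effect peaks | 5, amplitude 150 | the planted discriminatory signal |
| effect multiplier | 3 (group 1) | concentration changes scale IMS peak height, so the group effect is multiplicative |
| noise | i.i.d. Gaussian, SD 10, truncated at 0 | simplest model that exercises the 2-SD threshold |
| baseline | 50 | keeps truncation rare but real |

The generator does *not* emulate peak tailing, dimer ions, retention
drift, inter-batch effects, or heteroscedastic noise; a green recovery
test therefore establishes that the pipeline's algorithms recover planted
multiplicative signal under homoscedastic noise — not that the assay works
clinically. Ground truth for recovery is the set of cells within 2σ of an
effect-peak center (`effectFootprint`).

With `effectMultiplier = 1` the generator is exchangeable across groups,
which the suite uses for null calibration: out-of-fold AUC at chance,
comparison p-values uniform at the nominal type-I error.

## Numerical choices and degenerate inputs

* All randomness flows through R's RNG; every user-facing entry point
  takes or documents a seed. Running the full pipeline twice with one
  seed produces byte-identical predictions and report CSVs.
* Spectra are serialized with 17 significant digits, so write→read is
  bit-exact.
* A constant feature gets rank-sum p = 1 (no information), and an
  all-constant training matrix still yields a fitted classifier with
  constant probabilities rather than an error.
* Degenerate AUC variance (all probabilities equal, or perfect
  separation) collapses the confidence interval to the point estimate
  with a warning.
* The SVM's Platt calibration falls back to in-sample decision values
  when the minority class has fewer than 3 training members.

## Known limitations

* The interchange format is this package's invention; the instrument's
  native files must be converted upstream.
* Feature = cell is the minimal definition of a locatable feature; a peak
  detection step would change selected-feature semantics.
* The 70/30 hold-out and 10-fold CV protocols answer slightly different
  questions and give different uncertainty behaviour; the package
  implements both and every report names its mode.
* Clinical effect sizes, intensity distributions and inter-instrument
  variability are unknown; none of the synthetic defaults were tuned to
  reproduce any published metric value, and no clinical number is treated
  as a reproduction target.
* The per-comparison p-value is computed, as specified, on pooled
  out-of-fold probabilities. Such scores are not exchangeable — all test
  samples of a fold share one fitted model — and the package's own null
  simulations show the resulting rank test is anti-conservative at small,
  imbalanced group sizes (empirical type-I error ≈ 0.14 at α = 0.05 for
  41 vs 8; the null AUC standard deviation is ≈ 0.15 where an i.i.d. rank
  test assumes 0.113). The corresponding calibration test in the suite
  documents this honestly and fails by design; treat CV-mode p-values as
  descriptive. The hold-out mode, whose test samples share no training
  data with each other, does not have this pathology, and the p-value
  machinery itself is verified to be calibrated on i.i.d. inputs.
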