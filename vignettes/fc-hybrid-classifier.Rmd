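---
title: "Functional-connectivity classification: model, augmentation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-connectivity classification: model, augmentation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdiag)
```

## The problem and the model

Resting-state fMRI preprocessing pipelines reduce each scan to an
ROI-by-time matrix: `m` region-averaged signals observed at `T` timepoints.
Functional connectivity — here, the Pearson correlation between every pair
of regional series — is a widely used substrate for classifying clinical
populations such as autism-spectrum patients against controls, because the
discriminative signal is believed to live in how regions co-fluctuate
rather than in any single regional signal.

`fcdiag` implements a hybrid classifier over these correlations:

* Each subject contributes the strictly upper triangle of their `m × m`
  correlation matrix, a vector of `q = m(m−1)/2` values in `[−1, 1]`
  (19,900 for a 200-region parcellation). Ordering is row-major over pairs
  `(i, j)` with `i < j`; `pair_index()` makes the layout explicit.
* Feature selection keeps the most positive and most negative
  *training-average* correlations (a quarter of `q` from each extreme by
  default, i.e. half of all features). The premise is that strong
  correlations and strong anti-correlations are where group differences are
  expressed; near-zero correlations mostly carry sampling noise. The
  fraction is tunable (`fraction` argument): more aggressive masking speeds
  training and regularizes, at the risk of discarding informative pairs.
* A **tied-weight autoencoder** (`h = tanh(W x + b_enc)`,
  `x' = Wᵀ h + b_dec`) compresses the masked features non-linearly; tying
  the decoder to `Wᵀ` halves the parameter count and acts as a
  regularizer. The bottleneck defaults to half the input dimension,
  continuing the halving cadence of the feature pipeline; it is the single
  most consequential capacity knob.
* A **single-layer perceptron** reads the bottleneck and emits a patient
  probability through a sigmoid. Both networks are trained **jointly** on
  `mse_weight · MSE + ce_weight · BCE` (default weights 1:1), so the
  bottleneck is shaped to be simultaneously reconstructive and
  discriminative; afterwards the SLP alone is fine-tuned on the
  cross-entropy with the encoder frozen bit-for-bit.
* Prediction thresholds the probability at 0.5, with the boundary mapped to
  the patient class.

## Similarity-guided augmentation

Cohorts at a single site are often small (tens of subjects), which starves
the network. The package doubles each training fold by SMOTE-style
interpolation: for every training sample, one of its `k = 5` nearest
*same-class* neighbours is drawn uniformly, and a synthetic point
`α p + (1−α) q` with `α ~ U(0, 1)` inherits the seed sample's label.
Because both parents share the class, every synthetic point is a convex
combination within a class region of feature space.

Proximity is measured with the Extended Frobenius Norm (EROS) over each
subject's covariance eigenstructure rather than Euclidean distance on the
(long) feature vectors: subjects are summarised once by the leading
eigenvalues/eigenvectors of their `m × m` covariance, and
`EROS(A, B, w) = Σ w_i |⟨a_i, b_i⟩|` scores the alignment of
rank-corresponding eigenvectors. The weight vector comes from the training
set's eigenvalue spectra: normalize each subject's retained spectrum to sum
1, aggregate across subjects per rank (mean by default), renormalize. Two
components (`eros_n = 2`) are retained by default — a speed simplification
that empirically preserves neighbour rankings; when fewer than `m`
components are kept, the per-subject normalization divides by the sum of
the *retained* eigenvalues, which keeps the weights summing to exactly 1.

Two conventions deserve note. First, synthetic samples are generated once
per fold (a dataset-level doubling), not re-drawn each epoch, and
participate in both loss terms. Second, the EROS weights are computed from
the training fold only; weighting over the whole dataset would leak
held-out eigen-spectra into training-time decisions, so it is not the
default (it can be reproduced by calling `eros_weights()` on all subjects
manually).

## Evaluation protocol

`cross_validate()` runs stratified k-fold cross-validation: 10 folds suit
pooled multi-site cohorts, 5 folds small single-site cohorts where a larger
`k` would leave only 2–3 test subjects per fold. Stratification is by class
label (optionally also by site), which guarantees both classes appear in
every test fold so that sensitivity, specificity and AUC are defined.
Within each fold, the feature mask, EROS weights, augmentation and model
all derive from training subjects only; the returned `details` retain the
per-fold mask, weights, augmentation provenance `(seed_index,
neighbor_index, alpha)` and subject-level scores so that leakage audits can
recompute each ingredient from the recorded training ids. Subjects are
sorted by id before fold assignment, making every result invariant to the
order subjects are supplied in.

Metrics follow the clinical conventions: sensitivity is patient recall,
specificity control recall, and a rate with an empty denominator is
reported as `NA`, never silently 0. The ROC sweeps all distinct score
thresholds (`prediction = score ≥ threshold`) and the trapezoidal area
equals the tie-aware concordance `P(score⁺ > score⁻) + ½ P(tie)`; the test
suite cross-checks this against both a brute-force pairwise count and an
independent ROC implementation (pROC).

## The synthetic generator

`synthetic_spec()` / `make_dataset()` draw two classes of zero-mean
Gaussian series: controls from a unit-variance covariance with constant
background correlation (0.1), patients from the same matrix with the
correlations at a known set of region pairs shifted by ±`delta`
(alternating signs, so both the positive and negative arms of the mask are
exercised). The defaults — 20 regions, 150 timepoints, 50 subjects per
class, 12 perturbed pairs, `delta = 0.6` — give a desk-scale cohort whose
effect size is unambiguous relative to correlation sampling noise at
`T = 150` (s.e. ≈ 0.08 per subject), so the pipeline is expected to
recover the planted pairs and classify held-out subjects nearly perfectly;
`delta = 0` collapses both classes onto one distribution and calibrates
the null (accuracy ≈ 0.5).

When the generator chooses the pairs itself, it lays them out as disjoint
paths of at most two edges over shuffled regions. The signed perturbation
then has spectral norm `delta·√2`, so the patient covariance is positive
definite by construction whenever `delta < (1 − base_correlation)/√2`
≈ 0.64, and the planted correlation shifts are *exact* — no ridge
adjustment distorts them. Explicitly supplied pairs may violate that
bound; both class matrices are then ridge-shrunk toward the identity
(preserving unit variances) until the smallest eigenvalue exceeds 1e−6,
and an irreparable perturbation errors with advice to lower `delta`.

What the generator deliberately does not emulate: hemodynamic
autocorrelation beyond an optional AR(1) smoothing, motion and scanner
artifacts, site-specific covariance structure (pseudo-sites are i.i.d.
unless a mean shift is requested), and realistic effect sizes — planted
`±0.6` shifts are far stronger than group differences in real cohorts.
Passing the end-to-end checks therefore demonstrates that the machinery is
correct and leakage-free, not that real-data accuracies are reproducible.

## Numerical choices

* **Classification loss.** Standard binary cross-entropy with logarithms
  and probabilities clipped to `[1e−7, 1 − 1e−7]`. The clip keeps the loss
  finite when the sigmoid saturates; its gradient uses the unclipped form
  `(p − y)/N`, exact everywhere the clip is inactive.
* **Optimizer.** Full-batch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8) at
  learning rate 1e−3, 25 joint epochs + 5 fine-tuning epochs. These
  defaults were chosen for stability at desk scale (hundreds of samples,
  ~100 masked features) and verified to converge on the default synthetic
  conditions; minibatch training (`batch_size`) is available for larger
  cohorts. A non-finite loss raises a divergence error naming the epoch.
* **Initialization.** Uniform `(−1/√fan_in, 1/√fan_in)` weights, zero
  biases, reproducible from a seed.
* **Gradients.** Analytic, with the tied weight accumulating the encoder-
  and decoder-path terms; verified against central finite differences to
  1e−5 relative error in the test suite.
* **Tie-breaks.** Mask ranking and neighbour ranking both break ties by
  lower index, for cross-platform determinism. On heavily tied inputs the
  two mask extremes could nominate the same index; the smallest-value arm
  then draws from the remaining indices so the mask size is always exactly
  `2⌊q·fraction⌋`.
* **Degenerate inputs.** Zero-variance (constant) regional series yield
  correlation 0 by convention (neutral for extreme-value masking) with a
  message, rather than aborting a fold; non-finite values in input files
  are a hard error, since preprocessed series are assumed complete.
  An all-zero eigenvalue spectrum is a degenerate-item error in the EROS
  weighting. A training sample whose class has no other member is skipped
  by augmentation with a warning.
* **Eigenvector conventions.** Components are ordered by descending
  eigenvalue and paired across subjects by rank; signs are canonicalized
  (largest-magnitude entry positive), though EROS itself is sign-invariant
  through the absolute value.
* **Indexing.** Mask and provenance indices are 1-based throughout, the R
  convention.

## Problem sizes used by the checks

The test suite exercises the end-to-end pipeline at the default synthetic
conditions (20 regions, 150 timepoints, 100 subjects): 5-fold
cross-validation over 5 seeds for recovery, mask-recovery over 10 seeds,
and 10 null-calibration runs at `delta = 0` — roughly 75 fold-trainings,
about half a minute on one core. Unit oracles run at toy sizes (4–10
timepoints, 2–6 regions) where every quantity is hand-checkable.

## Known limitations

* The joint loss weights reconstruction and classification 1:1; no
  annealing schedule is provided.
* The autoencoder is a single hidden layer by design; stacked or denoising
  variants are out of scope.
* Connectivity is plain Pearson correlation — no partial correlation or
  tangent-space embedding.
* Hyperparameter search is the caller's responsibility; the harness
  exposes seeds and configs but no grid-search driver.
* Real multi-site heterogeneity (scanner protocols, demographics) is not
  modelled by the generator; per-site results on real data will vary far
  more than the synthetic checks suggest.
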