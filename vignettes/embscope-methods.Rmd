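---
title: "Methods: interpretable convolutional classification of endomyocardial biopsy ROIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable convolutional classification of endomyocardial biopsy ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Histopathological assessment of endomyocardial biopsies (EMB) — deciding
whether a small H&E-stained myocardial sample comes from a failing or a
non-failing heart — is labor-intensive and suffers from high inter-rater
variability. `embscope` implements a complete, interpretable image-analysis
pipeline for this task. The unit of analysis is the ROI: a small square
patch (nominally 250 × 250 px ≙ 50 × 50 µm²) sampled within the myocardium,
with 11 ROIs per patient ("case"). Classification happens per ROI; a
case-level risk score aggregates the 11 ROI decisions.

Three properties drive the design:

1. **No case-level crosstalk.** Every split — development vs held-out test,
   cross-validation folds, training vs validation — is drawn over *case
   ids*, never over ROIs, so ROIs from one patient can never appear on both
   sides of any boundary.
2. **Interpretability.** Grad-CAM attention maps localise the image regions
   responsible for a prediction; UMAP embeddings of the deep features
   visualise the global structure of what the network has learned.
3. **Ensembling as consultation.** A C(K, m) multi-model ensemble mimics a
   panel of experts: each sub-model sees a different subset of the
   development cases, and their averaged opinions are both more accurate
   and more informative (disagreement flags ambiguous cases).

## The classifier

The model is a conventional convolutional feature extractor followed by a
global average pooling (GAP) layer and a two-node softmax head. The
`"vgg19"` preset mirrors the canonical 16-convolution / 5-max-pool layout
(stages of 2, 2, 4, 4, 4 convolutions with 64–512 channels): a
224 × 224 × 3 input yields a 7 × 7 × 512 feature tensor **F**, a length-512
GAP "deep feature", and a Bernoulli output (p_N, p_F), where p_F is the
predicted probability that the ROI comes from a failing heart. The
`"mini"` preset keeps the identical contract — 3 × 3 same-padding
convolutions, ReLU, 2 × 2 floor-division max pooling, GAP, two-node
softmax — at a fraction of the width (2 convolutions per stage, ≤ 32
channels), so that the full pipeline can be exercised on one CPU. The
architecture, not the parameter count, is the contract: every shape law
(`feature side = floor(input / 2^stages)`) holds for both presets.

Because no deep-learning framework is assumed, the network — forward pass,
exact backpropagation, and the Adam optimiser — is implemented natively in
R. Convolutions are evaluated as nine shifted GEMMs against the zero-padded
activation, which delegates all heavy arithmetic to BLAS; an analytical
gradient check against central finite differences is part of the test
suite.

Training minimises the label-set-normalised cross-entropy
`L = (1/|C|) Σ_c −y_c log ŷ_c` (|C| = 2) with Adam at a constant learning
rate (default 1e-4, the reference protocol; the desk-scale tests use 1e-3,
appropriate for the much smaller mini network), with predictions clamped at
1e-12 inside the log. Augmentation comprises a random square crop (224 px
at full scale), independent probability-0.5 horizontal and vertical flips,
and stain jitter: the image is color-deconvolved with the standard
Ruifrok–Johnston H&E stain matrix, each stain channel is scaled and biased
by small uniform draws (±5% by default), and the image is recomposed.
Validation loss is computed on unaugmented centre crops at the end of every
epoch, and the parameters from the epoch with the lowest validation loss
are retained. Validation-without-augmentation and the centre crop at
inference are deliberate choices (the full-scale protocol specifies random
cropping only for training); they make evaluation deterministic.

## Grad-CAM

For regional interpretability the package follows the gradient-weighted
class-activation-mapping recipe with the gradient taken with respect to the
softmax *probability* (not the logit): G = ∂p_F/∂F, w = spatial GAP of G
(one weight per channel), and the attention map

A = ReLU(F ⊗ w),

where ⊗ is the 1 × 1 convolution, i.e. the channel-weighted sum
Σ_c w_c F[,,c]. With a GAP + linear + softmax head, p_F is an explicit
function of F, so G is available in closed form:
`G[i,j,c] = (p_F(1−p_F) W[c,F] − p_F p_N W[c,N]) / (hw)`, constant over
spatial positions. The implementation uses this exact form and the test
suite verifies it against central finite differences of p_F through the
head, and the F ⊗ w convolution form against the channel-weighted sum. For
display, A is bilinearly upsampled (half-pixel-centred) to the input size,
divided by its maximum when positive (an all-zero map is left at zero), and
rendered red (high) to green (low) over the image.

## UMAP embedding of deep features

Each ROI's deep feature is the length-C GAP vector taken immediately before
the classification layer. The package computes all pairwise Euclidean
distances between these vectors and hands the precomputed distance matrix
to UMAP (via `uwot`, single-threaded so a seed fully determines the
layout), producing one 2-D point per ROI. Hyperparameters are the common
defaults `n_neighbors = 15` (clamped to n − 1) and `min_dist = 0.1`; they
are not tuned. The embedding is visualisation only — it never feeds back
into classification. A useful diagnostic contrast, mirrored in the tests,
is the class-label silhouette of the embedding under the trained model
versus under a random initialisation of the same architecture. One finding
from the synthetic experiments is worth recording: this contrast is only
informative when the planted morphology is subtle. At large effect sizes
even an untrained network's GAP features separate the classes (any
consistent pixel-level difference survives random projections, and UMAP
amplifies it), while a trained network compresses its features towards the
decision axis, which can embed *worse*. The tests therefore evaluate the
trained-vs-random contrast at effect size 1 with a model trained on that
same distribution — the direct analogue of comparing a task-retrained
network against one not trained on the task.

## The C(K, m) ensemble

The development cases are dealt into K = 5 folds, stratified by label:
cases are shuffled within each label (seeded) and dealt round-robin, so
per-label fold sizes differ by at most one — with 57 + 47 development cases
this reproduces the (12,12,11,11,11)/(10,10,9,9,9) pattern up to
relabelling. One sub-model is trained for every m = 3-element subset of
folds (its complement is its validation set): C(5,3) = 10 sub-models, and
every fold validates exactly C(4,3) = 4 of them. Sub-models are trained
sequentially with per-subset derived seeds for reproducibility.

Predictions are organised as per-case grids (rows = ROIs, columns =
sub-models). A development case receives columns only from the sub-models
whose training folds exclude its fold (4 columns) — the only leakage-free
reading — and the constructor enforces this invariant as a hard error. A
held-out test case receives all 10 columns. The ensemble score of a ROI is
the row mean; the case score is computed from the averaged per-ROI
probabilities (averaging probabilities first, then aggregating to case
level, was chosen over averaging per-model case scores; the alternative is
a one-line change on the prediction table).

## Evaluation

The case-level risk score is the proportion of the case's ROIs whose
predicted failure probability exceeds a threshold (default 0.5, the
softmax-argmax reading of a "positive prediction"; configurable). ROC
curves sweep all distinct score thresholds with ties treated as a single
simultaneous crossing (diagonal segments), and the AUC is computed both by
the trapezoidal rule and as the tie-corrected Mann–Whitney rank statistic;
the two are cross-checked to 1e-10 in the tests and against `pROC`.
Confusion matrices (truth × prediction, N/F) use the same thresholds.

## The synthetic data generator

Real EMB data cannot be bundled, so the package ships a generator of
stylised H&E-like ROIs: an eosin-pink textured background (smooth low-
frequency field plus faint sinusoidal fiber striations), hematoxylin-dark
nuclear disks, and additive Gaussian pixel noise. It is a statistical
proxy, not photorealistic histology: no scanner artefacts, no tissue folds,
no chromatin texture. Its purpose is controllable class structure with
exact ground truth.

Failure morphology is planted through three mechanisms, all scaled by one
`effect_size` parameter (0 makes the class-conditional image distributions
identical): a subset (~30%) of nuclei is hypertrophied towards the failure
radius distribution; an infiltration-like cluster of small dark cells
appears with probability `min(1, 0.5 · effect_size)`; and perinuclear
vacuolation-like clearings (flat, faintly lightened halos) appear likewise.
Two design points matter:

* **Stain-budget matching.** The non-hypertrophied nuclei are attenuated so
  that the total nuclear area (plus any infiltration area) matches the
  non-failure rendering of the same seeds. Without this, total stain
  quantity alone separates the classes and even an untrained network's
  features classify perfectly — the signal is meant to be morphological
  (size dispersion, clusters, clearings), as in real tissue, where failing
  and non-failing myocardium are not distinguishable by global color.
* **Label-flip discipline.** Every random draw for a ROI happens in a fixed
  order independent of the label, and per-ROI seeds are derived as
  `mix(seed, case_seed, roi_index)`. Rendering the same seeds under the
  opposite label therefore changes *only* the planted-structure pixels;
  the lesion mask marks exactly those pixels (hypertrophy and attenuation
  annuli, infiltration cells, vacuole halos). This gives pixel-exact ground
  truth for the attention-localization tests.

Default geometry emulates the reference collection (250 px ROIs, 11 per
case, ~40 nuclei proposed per ROI with minimum-separation thinning so
planted structures never overlap). What passing tests on these images show
is that the pipeline recovers *planted, well-separated* morphology; they do
not certify performance on real histology, where lesions are subtler,
stains vary, and labels are noisy.

## Desk-scale study conditions

The stochastic properties (learnability, localization, feature-space
restructuring, ensemble gain) are tested under fixed desk-scale conditions
chosen once: 64 px ROIs randomly cropped to a 56 px input — the same 0.9
crop ratio as the full-scale 250 → 224 protocol, and 56/2³ reproduces the
7 × 7 feature map — a 3-pool-stage mini backbone (F = 7 × 7 × 32; an
8 × 8 upsampling block per attention cell, fine enough for localization),
nucleus radii 2.4 ± 0.5 px (non-failure) vs 3.2 ± 0.6 px (failure at
effect size 1), 14 nuclei proposed per ROI, Adam 1e-3, batch 32. Training
fixtures use 40 training / 20 validation cases at effect size 2 (≤ 10
epochs); the ensemble properties use 10 sub-models over K = 5 folds at
effect sizes 1 (ensemble-vs-members) and 2 (end-to-end, 60 cases). These
sizes are the package's own desk-scale choice of study conditions; all
seeds are fixed in the tests and derived per component, so every run is
reproducible.

## Numerical choices and degenerate inputs

* Pooling uses floor semantics (a trailing odd row/column is dropped), so
  the shape law is exactly `floor(input / 2^stages)` for any input size.
* Predictions are clamped at 1e-12 inside the loss; `p_N + p_F = 1` is
  guaranteed by the softmax up to floating-point error (< 1e-6 asserted).
* An all-zero attention map is rendered as uniformly low attention rather
  than normalised (division by a zero maximum is never taken).
* Bilinear resizing uses half-pixel-centred coordinates with edge
  clamping, so the hottest attention cell maps into its own upsampled
  block.
* Cases with other than 11 ROIs are accepted with a warning; aggregation
  uses the actual count. Empty ROI sets, single-class score vectors,
  overlapping train/validation cases, out-of-range splits, and leaking
  prediction grids are hard errors.
* Derived seeds are produced by a small multiplicative mixer whose products
  stay below 2^53, keeping the arithmetic exact in doubles and the results
  identical across platforms.

## Known limitations

* The generator's morphology is stylised; effect sizes calibrate test
  difficulty, not clinical difficulty.
* ImageNet-pretrained weights are supported only as a user-supplied
  plug-in (`build_model(..., init = "pretrained_vgg19", weights = ...)`);
  none are bundled, so the vgg19 preset is practically used as a shape and
  interpretability contract, not a trained classifier.
* The native R engine is adequate for the mini preset and for vgg19
  inference-scale checks; full-scale vgg19 fine-tuning is outside its
  intended envelope.
* Case-level decision thresholds (ROI positivity 0.5, case positivity 0.5)
  are conventions, configurable but not calibrated against any external
  cohort.
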