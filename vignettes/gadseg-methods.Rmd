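---
title: "Methods: two-stage detection of enhancing MS lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage detection of enhancing MS lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the model, its assumptions, the tunable parameters,
and the design decisions taken where the problem left genuine choices. It
states no empirical result beyond what the package's tests and acceptance
script themselves compute.

## Problem and model

Gadolinium-enhancing lesions in multiple sclerosis are sparse, small (from
the 5-voxel detection floor to several hundred voxels), morphologically
variable (ovoid or ring-enhancing), and embedded in scans whose acquisition
protocols vary between sites and visits. The pipeline treats detection as
two separable problems:

1. **Voxel classification.** A 2D UNet maps each axial slice's channel
   stack (up to five MRI contrasts plus five tissue probability maps, all
   co-registered) to a lesion-probability image. Working slice-wise keeps
   the parameter-to-input ratio high and makes the model indifferent to
   slice count; the cost is that each slice is classified without 3D
   context.
2. **Candidate classification.** The 3D context is restored afterwards:
   binarized predictions are split into 6-connected components and a
   random forest classifies each candidate from 75 aggregate features.
   The forest can use exactly the cues a 2D voxel classifier cannot —
   through-plane extent, per-scan candidate counts, and shell contrast.

### Architecture

Five encoder depths (filter widths 32, 64, 128, 256, 512; two 3×3
convolutions per depth, each followed by batch normalization then ReLU),
2×2 max pooling between depths, and a decoder that upsamples 2×2 without
parameters, concatenates the encoder skip, and applies two convolution
units at the skip's width. A 1×1 convolution and sigmoid produce the
probability map. Three points were genuinely open and were fixed as
follows:

- *Kernel size* is not dictated by the architecture description; 3×3 is
  the UNet convention and is what makes the trainable-parameter total come
  out at ≈7.85 million for the 10-channel default — consistent with the
  ≈7.8M total that characterizes the full-scale architecture.
- *Upsampling* is parameter-free (nearest-neighbour). A transposed
  convolution would add parameters and break the ≈7.8M accounting; the
  parameter count is the reason this reading was adopted.
- *Batch-norm placement* follows the textual order convolution →
  normalization → activation.

The builder is deterministic given a seed (He-uniform initialization), and
`count_parameters()` computes the total in closed form; a test asserts the
closed form equals the instantiated network's count, and the numerical
gradient check asserts the hand-written backward pass matches central
differences on every layer type.

### Losses

All three losses treat a training batch as a flat bag of N voxels. The
bootstrapped cross-entropy averages the K largest per-voxel losses. Two
details deserve note:

- The hard-voxel selection is over the *largest* per-voxel losses (the
  voxels least likely to be labelled correctly), i.e. standard online hard
  example mining: the selection threshold is the (K+1)-th largest loss.
- Ties at the threshold are resolved by stable voxel order so that exactly
  K voxels enter the 1/K average; this keeps the normalizer well defined
  when several voxels share the threshold loss.
- K applies per batch (all slices pooled); the full-scale reference budgets
  K ∈ {256, 1536, 3072} at batch size 16 are the `train_config()`
  reference points. Predictions are clamped to [1e-7, 1−1e-7] before the
  logarithm.

### Training protocol

Defaults follow the full-scale clinical protocol: batch size 16 of consecutive
slices within one scan (non-overlapping windows — "consecutive sets" is
read as a partition), Adam with first-moment decay 0.5 and learning rate
1e-4, lesion-containing batches always used, lesion-free batches retained
with probability `keep_empty_prob` (default 0.1; only "randomly excluding"
is specified, so the rate is exposed as configuration). Validation is mean
3D Dice over the validation scans at the 0.5 binarization threshold (the
canonical choice; also exposed), and the best-validating epoch's
parameters are returned. Batches never span scan boundaries.

### Candidate features

The 75-vector is 9 location + 1 count + 5 shape + 60 intensity features.
Choices where the feature list admitted readings:

- "Depth in x, y, z" is taken as bounding-box extent on the 0-based voxel
  grid with half-open boxes; centroids are voxel-unit coordinates, with z
  the slice (3 mm) axis.
- The shape eigenvalues come from the 3×3 second central moment of voxel
  coordinates *in millimetres* (spacing-weighted); "axial diffusivity" is
  the largest eigenvalue and "radial diffusivity" the mean of the two
  smaller — the only reading under which that DTI vocabulary is meaningful
  for a shape. The eigenvalue SD uses the population (1/n) form so a
  single-voxel candidate is exactly degenerate (all zeros).
- "Surrounding" is a one-voxel face-adjacent dilation shell clipped to the
  grid — the smallest well-defined neighbourhood; the width is exposed.
- Under reduced contrast configurations, absent channels contribute zeros
  so the 75-length layout is invariant within an experiment.

The candidate filter's labels use the same one-voxel overlap rule as the
evaluation; the forest defaults (100 trees, 0.5 score threshold) are
standard rather than claimed faithful, since the reference pipeline leaves
this stage's hyperparameters unspecified.

### Evaluation conventions

The counting convention is hybrid and was fixed by arithmetic: TP/FN are
counted over manual lesions, FP over predicted components. This is the
only convention that reproduces the reference clinical table totals (151/179 =
0.844 sensitivity with 67/218 = 0.307 FDR), and the package's acceptance
tests recompute those totals from the printed per-group counts.
Confusion-matrix percentages are normalized by true-category column totals
(again verified arithmetically: 2381/2661 = 89.5%). Undefined ratios (0/0)
are reported as `NA`, never 0 or 1. Two conventions are necessarily the
package's own, as no standard definition exists: per-size-group Dice uses
the masks restricted to that group's manual lesions and their matched
predicted components, and the overall mean Dice averages per-image Dice
over images with at least one manual lesion (lesion-free images make the
per-image ratio 0/0 and are excluded).

## The phantom generator

The generator's job is to emulate the *structure* of the clinical data —
geometry, channel set, lesion size spectrum and morphology, protocol
variability — not MR physics. It renders:

- nested ellipsoids for brain/GM/WM with two lateral-ventricle ellipsoids;
  smoothed indicators give the five probability channels (clinically these
  come from template warping, which is out of scope), normalized so the
  GM+WM+CSF sum never exceeds 1;
- a periventricular lesion-prior channel (smoothed shell around the
  ventricles within WM), matching where enhancing lesions concentrate;
- ovoid lesions as anisotropic Gaussians thresholded to an *exact* target
  voxel count, and ring lesions as a shell minus a concentric core (rings
  only at ≥ 21 voxels; a 5-voxel ring is not meaningful). Lesions are
  placed disjointly with a one-voxel margin and verified 6-connected, so
  the ground-truth component count and size table are exact by
  construction — a property the tests check through the candidates module;
- contrast behaviour: enhancing voxels hyperintense on post-contrast T1
  (additive `lesion_boost`, default 0.5 against O(1) tissue intensities;
  lesion contrast-to-noise is monotone in it), whole lesions hyperintense
  on FLAIR/T2, ring cores hypointense on post-contrast T1;
- vessel-like distractor blobs, bright on *both* pre- and post-contrast T1
  (default 3 per scan). These are the classic clinical false-positive
  source and give the random-forest stage genuine negatives to learn from;
- protocol non-standardization as per-scan, per-contrast log-normal gain
  (SD 0.1) and offset jitter plus Gaussian noise (SD 0.05). Probability
  channels are left clean, as warped template priors would be.

Cohorts draw lesion presence per scan at a configurable prevalence
(default 6.5%, the routine-practice rate) and uniform counts up to the
template's maximum, yielding ground-truth 0 / 1 / ≥2 categories.

What the phantoms do **not** model — partial volume beyond smoothing,
acquisition artefacts, anatomical variability, realistic lesion texture —
bounds what passing tests show: the pipeline's machinery is correct and
its stages interact as designed, but phantom performance numbers say
nothing quantitative about clinical performance.

## Desk-scale study sizes and numerical choices

The package's tests and example pipeline run at sizes chosen for a single
CPU: phantoms of 16×64×64 voxels, 12-scan cohorts (8 train / 2 validation
/ 2 held-out), a width-4 UNet (≈124k parameters), batch size 8, learning
rate 1e-3, 10 epochs. Two deliberate departures from the full-scale
defaults, both recorded here as the package's own choices:

- **Dice loss for the desk-scale run.** With only ~100 optimizer steps,
  the bootstrapped loss — which supervises just K voxels per step — leaves
  most of the background untouched and near its initialization, flooding
  the output with false positives; it needs the long training schedules it
  was designed for. The Dice loss handles the extreme class imbalance
  immediately and is the default for `pipeline_config()`. The bootstrapped
  loss remains the reference default in `train_config()` and is exercised
  (and oracle-checked) by the loss tests.
- **Learning rate 1e-3** rather than the full-scale 1e-4, proportionate to
  the tiny step budget.

Other numerical choices: probability clamp 1e-7; batch-norm epsilon 1e-5
and running-statistic momentum 0.1; Adam epsilon 1e-8 with bias
correction; max-pool ties resolved to the first maximum in scan order;
binarization threshold 0.5. Degenerate inputs are defined rather than
accidental: empty/empty Dice is an error at smoothing 0 (and `NA` in the
3D evaluation), 0/0 ratios are `NA`, `K ≥ N` reduces the bootstrapped loss
to plain cross-entropy, and single-voxel candidates have exactly zero
shape eigenvalues.

## Known limitations

- Training at full clinical scale (hundreds of 64×256×256 scans, width-32
  network) is out of reach of a pure-R implementation on one CPU; the
  package reproduces the architecture, losses, and procedures exactly, and
  the behaviour end to end at reduced scale.
- The clinical preprocessing chain (bias-field correction, registration,
  skull stripping, intensity normalization) is intentionally absent;
  inputs are assumed co-registered in template space. A non-template grid
  is accepted silently (the model is fully convolutional); enable
  `options(gadseg.warn_geometry = TRUE)` to be warned.
- The on-disk orientation convention is whatever the NIfTI header
  declares; the package records and preserves it without reorienting.
- Ring lesions' ground truth is the enhancing shell only; the hypointense
  core is background, which is the convention a contrast-enhancement mask
  implies but differs from a "whole lesion" reading.
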