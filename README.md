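# gadseg

Automatic segmentation and counting of gadolinium-enhancing multiple-sclerosis
(MS) lesions from routine multi-contrast brain MRI.

Enhancing lesions — regions where blood–brain-barrier breakdown lets a
gadolinium contrast agent leak in — mark active inflammation and drive
treatment decisions in MS. They are hard targets for automation: sizes run
from ~5 to well over 100 voxels, shapes from ovoid blobs to hollow rings, and
routine clinical scans are acquired with non-standardized protocols. `gadseg`
implements a two-stage detection pipeline for this problem, aimed at image
analysts and methods researchers who want a fully inspectable, pure-R
implementation they can run, retrain, and evaluate end to end.

## The method

**Stage 1 — voxel classification.** A 2D UNet consumes up to ten co-registered
channels per axial slice — five MRI contrasts (T1 post-contrast, T1
pre-contrast, FLAIR, T2, PD) and five tissue probability maps (GM, WM, CSF,
lateral ventricles, lesion prior) — and outputs a voxel-wise lesion
probability map. Encoder and decoder have five depths of two 3×3
convolution + batch-norm + ReLU units (encoder widths 32–512), 2×2 max
pooling, parameter-free 2×2 upsampling with skip concatenation, and a 1×1
sigmoid head; the default architecture has ≈7.85 million trainable
parameters. Forward and backward passes are implemented on base matrix
algebra (im2col + BLAS), so no deep-learning runtime is needed.

Training supports three losses over the batch's voxels *x* (manual mask) and
*x̂* (predicted probability):

- Dice loss: `L = 1 − 2 Σ x·x̂ / (Σ x + Σ x̂)`
- cross-entropy: `L = (1/N) Σ p_j`, with `p_j = −x_j log x̂_j − (1−x_j) log(1−x̂_j)`
- bootstrapped cross-entropy: `L = (1/K) Σ_{top-K} p_j` — the mean over only
  the K *hardest* voxels of the batch (largest per-voxel loss), which
  emphasizes lesion boundaries and small lesions.

Because enhancing lesions are spatially sparse, batches (consecutive slice
runs) containing lesion voxels are always used; lesion-free batches are
randomly subsampled.

**Stage 2 — false-positive filtering.** The binarized 3D prediction is split
into 6-connected components (≥ 5 voxels); each candidate is described by 75
features — 9 location (centroid, bounding-box start and extent in x/y/z), the
scan's candidate count, 5 shape (size; mean/SD of the eigenvalues of the
coordinate second-moment tensor; axial and radial "diffusivity" as shape
descriptors) and 60 intensity statistics (mean/SD/sum inside and in a
one-voxel shell, per channel) — and a random forest removes candidates
scored as false positives.

**Evaluation** is lesion-wise: a manual lesion is detected (TP) if any
predicted component overlaps it by ≥ 1 voxel; sensitivity = TP/(TP+FN) and
false detection rate FDR = FP/(FP+TP) are stratified by lesion size (5–10,
11–20, 21–50, 51–100, >100 voxels) alongside 3D Dice. Per-scan lesion counts
are binned 0 / 1 / ≥2 — the granularity of radiology reports — and compared
in a column-normalized confusion matrix.

Because clinical data cannot ship with the package, a **phantom generator**
renders brain-like multi-contrast volumes (nested ellipsoid tissues, ovoid
and ring-enhancing lesions of exact voxel counts, vessel-like bright
distractors, per-scan protocol jitter) with ground-truth masks, so the whole
pipeline is testable from scratch.

## Worked example

A desk-scale end-to-end run — 12 small phantoms (16×64×64, three lesions of
51+ voxels each), a narrow UNet trained for 10 epochs on CPU (~2–3 minutes):

```r
library(gadseg)

cfg <- pipeline_config(
  seed = 42L, n_train = 8L, n_val = 2L, n_eval = 2L,
  phantom = list(shape = c(16L, 64L, 64L), n_lesions = 3L,
                 groups = c("51-100", ">100")),
  train = list(loss = "dice", batch_size = 8L, lr = 1e-3,
               epochs = 10L, base_filters = 4L))
res <- run_pipeline(cfg, verbose = TRUE)
print(res$eval_pre)   # before the random-forest filter
print(res$eval_post)  # after
```

```
Lesion-wise evaluation (6-connectivity, one-voxel overlap rule)
  group n_lesions TP FN FP sensitivity   FDR  dice
   5-10         0  0  0  4          NA 1.000    NA
  11-20         0  0  0  4          NA 1.000    NA
  21-50         0  0  0  2          NA 1.000    NA
 51-100         4  4  0  0           1 0.000 0.067
   >100         2  2  0  0           1 0.000 0.057
  Total         6  6  0 10           1 0.625 0.240
Lesion-wise evaluation (6-connectivity, one-voxel overlap rule)
  group n_lesions TP FN FP sensitivity FDR  dice
   5-10         0  0  0  0          NA  NA    NA
  11-20         0  0  0  0          NA  NA    NA
  21-50         0  0  0  0          NA  NA    NA
 51-100         4  4  0  0           1   0 0.067
   >100         2  2  0  0           1   0 0.057
  Total         6  6  0  0           1   0 0.258
```

Reading the output: all six held-out lesions are detected before and after
filtering (sensitivity 1.0); the UNet alone also produces ten small false
positives (FDR 0.625), every one of which the random forest removes
(FDR 0.000) without costing a detection. The low Dice reflects the tiny
training budget — the lesion-wise detection statistics, not voxel overlap,
are the clinically relevant endpoint here. `NA` marks undefined ratios
(no lesions in that stratum), which are never coerced to 0 or 1.

The command-line wrapper in `inst/cli/gadseg.R` exposes the same stages as
subcommands (`simulate | train | segment | filter | evaluate | count |
pipeline`) over NIfTI volumes, CSV reports, and YAML configs.

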