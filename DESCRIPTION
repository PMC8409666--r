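Package: gadseg
Title: Two-Stage Segmentation and Counting of Gadolinium-Enhancing MS Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for automatic segmentation and counting of
    gadolinium-enhancing multiple-sclerosis lesions from co-registered
    multi-contrast brain MRI. Stage one is a 2D encoder-decoder (UNet)
    voxel classifier trained with Dice, cross-entropy, or bootstrapped
    cross-entropy (hard-voxel) losses over up to ten input channels (five
    MRI contrasts plus five tissue probability maps). Stage two extracts
    3D lesion candidates by 6-connectivity, describes each with 75
    hand-crafted location, shape, and intensity features, and removes
    false positives with a random-forest classifier. Includes lesion-wise
    evaluation (sensitivity, false detection rate, Dice by lesion-size
    group), per-scan count categorization (0 / 1 / >=2) with confusion
    matrices, and a synthetic multi-contrast phantom generator so the
    whole pipeline can be exercised without clinical data. The network
    forward and backward passes are implemented on base matrix algebra,
    so no external deep-learning runtime is required.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    randomForest,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
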