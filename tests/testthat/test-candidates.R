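test_that("6-connectivity joins faces but not diagonals", {
  m <- array(0, c(3, 3, 3))
  m[1, 1, 1] <- 1; m[2, 2, 1] <- 1        # edge-diagonal contact only
  cc <- connected_components_6(m)
  expect_equal(cc$n_components, 2L)
  m2 <- array(0, c(2, 1, 1)); m2[] <- 1    # face-adjacent pair
  expect_equal(connected_components_6(m2)$n_components, 1L)
  expect_error(connected_components_6(array(2, c(2, 2, 2))), "binary")
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(99)
  for (rep in 1:20) {
    m <- array(rbinom(8 * 8 * 4, 1, 0.35), c(8, 8, 4))
    cc <- connected_components_6(m)
    oracle <- flood_fill_cc(m)
    expect_true(same_partition(cc$labels, oracle))
    expect_equal(cc$n_components, max(oracle))
    expect_equal(sort(cc$sizes), sort(tabulate(oracle[oracle > 0])))
  }
})

test_that("minimum-size filter keeps the 5-voxel boundary inclusive", {
  m <- array(0, c(10, 10, 3))
  m[1:4, 1, 1] <- 1                        # 4 voxels: below the floor
  m[1:5, 5, 2] <- 1                        # 5 voxels: smallest stratum
  cc <- connected_components_6(m)
  f <- filter_min_size(cc, 5L)
  expect_equal(f$n_components, 1L)
  expect_equal(f$sizes, 5L)
  expect_equal(filter_min_size(cc, 1L)$n_components, cc$n_components)
  expect_error(filter_min_size(cc, 0L), "min_size")
})

test_that("single-voxel candidates have degenerate geometry features", {
  st <- make_toy_stack(6, 16, 16, n_channels = 10)
  f <- extract_features(matrix(c(3L, 5L, 7L), 1), st, 1L)
  expect_length(f, 75L)
  expect_identical(names(f), feature_layout())
  expect_equal(unname(f[c("bbox_extent_x", "bbox_extent_y", "bbox_extent_z")]),
               c(1, 1, 1))
  expect_equal(unname(f[c("eig_mean", "eig_sd", "axial_diffusivity",
                          "radial_diffusivity")]), rep(0, 4))
  expect_equal(unname(f["size_voxels"]), 1)
  # 0-based coordinates: array index (slice=3, row=5, col=7) -> x=4,y=6,z=2
  expect_equal(unname(f[c("centroid_x", "centroid_y", "centroid_z")]),
               c(4, 6, 2))
})

test_that("shape-tensor eigenvalues match a direct eigen-decomposition", {
  # prolate blob elongated along the row (x) axis
  st <- make_toy_stack(8, 24, 24, n_channels = 3)
  vox <- as.matrix(expand.grid(s = 4:5, r = 5:18, c = 11:13))
  f <- extract_features(vox, st, 1L)
  xyz <- cbind(vox[, 2] - 1, vox[, 3] - 1, vox[, 1] - 1) *
    rep(st$spacing[c(2, 3, 1)], each = nrow(vox))
  ev <- sort(eigen(stats::cov(xyz) * (nrow(xyz) - 1) / nrow(xyz),
                   only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(unname(f["axial_diffusivity"]), ev[1], tolerance = 1e-10)
  expect_equal(unname(f["radial_diffusivity"]), mean(ev[2:3]),
               tolerance = 1e-10)
  expect_gte(f[["axial_diffusivity"]], f[["radial_diffusivity"]])
})

test_that("intensity features: uniform channel and the sum identity", {
  S <- 6L; H <- 12L; W <- 12L
  chans <- GAD_CHANNELS[1:3]
  vols <- setNames(lapply(chans, function(ch) array(2.5, c(S, H, W))), chans)
  vols$flair <- array(rnorm(S * H * W), c(S, H, W))
  st <- stack_channels(vols, contrast_config(chans))
  vox <- as.matrix(expand.grid(s = 3:4, r = 5:7, c = 6:7))
  f <- extract_features(vox, st, 2L)
  expect_equal(unname(f["t1_post_in_mean"]), 2.5)
  expect_equal(unname(f["t1_post_shell_mean"]), 2.5)
  expect_equal(unname(f["t1_post_in_sd"]), 0)
  # sum = mean * size, exactly, for every channel present
  for (ch in chans)
    expect_equal(unname(f[paste0(ch, "_in_sum")]),
                 unname(f[paste0(ch, "_in_mean")]) * nrow(vox))
  # channels absent from the configuration contribute zeros
  expect_equal(unname(f["pd_in_sum"]), 0)
})

test_that("extract_candidates reports a consistent per-scan table", {
  ph <- generate_phantom(phantom_spec(shape = c(12L, 48L, 48L),
                                      n_lesions = 2L,
                                      groups = c("21-50", "51-100"),
                                      seed = 17L))
  cand <- extract_candidates(ph$mask, ph$stack)
  expect_equal(nrow(cand$candidates), 2L)
  expect_true(all(cand$candidates$n_candidates == 2))
  expect_equal(sort(cand$candidates$size_voxels),
               sort(ph$sizes$size_voxels))
  expect_true(all(feature_layout() %in% names(cand$candidates)))
})
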