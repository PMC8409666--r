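# Candidate labeling and the random-forest false-positive filter.

# synthetic labeled candidate table with a separable feature
.sep_candidates <- function(n_per_class = 30L, seed = 1L) {
  set.seed(seed)
  feats <- matrix(rnorm(2 * n_per_class * 75), 2 * n_per_class, 75,
                  dimnames = list(NULL, feature_layout()))
  feats[seq_len(n_per_class), "t1_post_in_mean"] <- rnorm(n_per_class, 5)
  feats[n_per_class + seq_len(n_per_class), "t1_post_in_mean"] <-
    rnorm(n_per_class, -5)
  df <- as.data.frame(feats)
  df$scan_id <- "syn"; df$component_id <- seq_len(nrow(df))
  df$label <- factor(rep(c("lesion", "fp"), each = n_per_class),
                     levels = c("fp", "lesion"))
  df
}

test_that("candidate labeling applies the one-voxel overlap rule", {
  manual <- array(0, c(8, 16, 16))
  manual[2:3, 4:8, 4:8] <- 1
  pred <- array(0, c(8, 16, 16))
  pred[2:3, 4:6, 4:6] <- 1            # fully inside the manual lesion
  pred[5, 10:14, 10] <- 1             # disjoint, 5 voxels
  pred[2, 8, 8:12] <- 1               # shares exactly one voxel (2,8,8)
  st <- make_toy_stack(8, 16, 16, n_channels = 3)
  cand <- extract_candidates(pred, st, min_size = 5L)
  lab <- label_candidates(cand, manual)
  overlaps <- vapply(cand$components, function(v) sum(manual[v]), numeric(1))
  expect_equal(lab$label == "lesion", overlaps >= 1)
  expect_true(any(overlaps == 1))     # the boundary case is exercised
  expect_error(label_candidates(cand, array(0, c(4, 4, 4))), "shape")
})

test_that("forest training on separable features reaches accuracy 1", {
  df <- .sep_candidates()
  rf <- fit_rf(df, rf_config(n_trees = 50, seed = 3))
  pred <- predict(rf$forest, df[, feature_layout()])
  expect_equal(mean(pred == df$label), 1)
  expect_length(rf$importance, 75L)
  expect_equal(names(rf$importance)[1], "t1_post_in_mean")
  # deterministic given the seed
  rf2 <- fit_rf(df, rf_config(n_trees = 50, seed = 3))
  expect_identical(predict(rf$forest, df[, feature_layout()], type = "prob"),
                   predict(rf2$forest, df[, feature_layout()], type = "prob"))
  df1 <- df[df$label == "fp", ]
  expect_error(fit_rf(df1, rf_config()), "single-class")
})

test_that("filtering thresholds behave at their extremes and only remove", {
  df <- .sep_candidates(seed = 5)
  rf <- fit_rf(df, rf_config(n_trees = 50, seed = 1))
  manual <- array(0, c(10, 16, 16)); manual[2:3, 3:7, 3:7] <- 1
  pred <- array(0, c(10, 16, 16))
  pred[2:3, 3:7, 3:7] <- 1
  pred[7:8, 10:13, 10:12] <- 1
  st <- make_toy_stack(10, 16, 16, n_channels = 10, seed = 6)
  cand <- extract_candidates(pred, st)
  out_lo <- apply_rf(rf, cand, score_threshold = 1e-9)
  expect_equal(sort(out_lo$kept_ids), seq_along(cand$components))
  expect_equal(out_lo$mask, pred > 0)
  out_hi <- apply_rf(rf, cand, score_threshold = 1 - 1e-9)
  expect_length(out_hi$kept_ids, 0L)
  expect_equal(sum(out_hi$mask), 0)
  # any threshold: filtered mask is a subset of the input mask
  out_mid <- apply_rf(rf, cand, score_threshold = 0.5)
  expect_true(all(pred[out_mid$mask] == 1))
  expect_false(any(out_mid$mask[pred == 0]))
})

test_that("a phantom-trained forest separates lesions from distractors", {
  # candidates from the union of true lesions and off-prior distractor
  # blobs; the forest should rank enhancement-related features highly
  phs <- lapply(1:4, function(i) generate_phantom(
    phantom_spec(shape = c(12L, 48L, 48L), n_lesions = 2L,
                 groups = c("21-50", "51-100"), ring_fraction = 0,
                 n_distractors = 4L, seed = 60L + i)))
  labeled <- do.call(rbind, lapply(phs, function(ph) {
    st <- ph$stack
    i_post <- match("t1_post", st$channels)
    i_pre <- match("t1_pre", st$channels)
    post <- array(st$data[i_post, , , ], dim(st$data)[2:4])
    pre <- array(st$data[i_pre, , , ], dim(st$data)[2:4])
    # crude stand-in for stage-one output: bright-on-post blobs
    pred <- post > quantile(post, 0.985)
    cand <- extract_candidates(pred, st, min_size = 5L)
    label_candidates(cand, ph$mask)
  }))
  expect_true(all(c("fp", "lesion") %in% labeled$label))
  rf <- fit_rf(labeled, rf_config(n_trees = 100, seed = 2))
  oob_acc <- 1 - rf$forest$err.rate[rf$forest$ntree, "OOB"]
  expect_gt(oob_acc, 0.7)
  top <- names(rf$importance)[1:15]
  expect_true(any(grepl("t1_pre|t1_post|p_lesion|centroid|_z", top)))
})
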