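test_that("lesion matching follows the one-voxel overlap rule", {
  m <- array(0, c(10, 10, 4))
  m[1:5, 1, 1] <- 1; m[1:6, 5, 2] <- 1; m[3:9, 9, 3] <- 1
  tab <- match_lesions(m, m)
  expect_equal(sum(tab$type == "TP"), 3L)
  expect_equal(sum(tab$type %in% c("FP", "FN")), 0L)
  empty <- array(0, dim(m))
  m2 <- array(0, dim(m)); m2[1:5, 1, 1] <- 1; m2[1:7, 8, 4] <- 1
  tab2 <- match_lesions(empty, m2)
  expect_equal(sum(tab2$type == "FN"), 2L)
})

test_that("matching counts agree with a brute-force pairwise oracle", {
  set.seed(5)
  for (rep in 1:10) {
    pred <- array(rbinom(12^3, 1, 0.18), c(12, 12, 12))
    manual <- array(rbinom(12^3, 1, 0.15), c(12, 12, 12))
    tab <- match_lesions(pred, manual)
    got <- c(TP = sum(tab$type == "TP"), FN = sum(tab$type == "FN"),
             FP = sum(tab$type == "FP"))
    expect_equal(got, match_brute_oracle(pred, manual))
  }
})

test_that("TP + FN always equals the number of manual lesions", {
  set.seed(12)
  for (rep in 1:8) {
    pred <- array(rbinom(10 * 12 * 8, 1, 0.2), c(10, 12, 8))
    manual <- array(rbinom(10 * 12 * 8, 1, 0.15), c(10, 12, 8))
    mcc <- filter_min_size(connected_components_6(manual), 5L)
    pcc <- filter_min_size(connected_components_6(pred), 5L)
    tab <- match_lesions(pred, manual)
    expect_equal(sum(tab$type %in% c("TP", "FN")), mcc$n_components)
    expect_lte(sum(tab$type == "FP"), pcc$n_components)
  }
})

test_that("report ratios reproduce from their own counts", {
  set.seed(21)
  sizes <- c(5, 8, 14, 30, 77, 120, 200)
  tab <- data.frame(
    type = sample(c("TP", "FN", "FP"), 40, TRUE),
    size = sample(sizes, 40, TRUE), id = 1:40)
  rep <- lesion_metrics(tab)
  bg <- rep$by_group
  tot <- bg[bg$group == "Total", ]
  expect_equal(tot$sensitivity, tot$TP / (tot$TP + tot$FN))
  expect_equal(tot$FDR, tot$FP / (tot$FP + tot$TP))
  # group counts sum to totals
  grp <- bg[bg$group != "Total", ]
  expect_equal(sum(grp$TP), tot$TP)
  expect_equal(sum(grp$FP), tot$FP)
  expect_equal(sum(grp$FN), tot$FN)
})

test_that("undefined ratios are reported as NA, never 0 or 1", {
  tab <- data.frame(type = "FN", size = 10, id = 1L)
  rep <- lesion_metrics(tab)
  tot <- rep$by_group[rep$by_group$group == "Total", ]
  expect_true(is.na(tot$FDR))          # TP = FP = 0
  expect_equal(tot$sensitivity, 0)
  empty_grp <- rep$by_group[rep$by_group$group == "21-50", ]
  expect_true(is.na(empty_grp$sensitivity))
  expect_true(is.na(empty_grp$FDR))
})

test_that("3D Dice matches closed forms and is symmetric", {
  a <- array(0, c(4, 4, 4)); a[1:2, 1:2, 1] <- 1
  expect_equal(dice_3d(a, a), 1)
  b <- array(0, c(4, 4, 4)); b[3:4, 3:4, 2] <- 1
  expect_equal(dice_3d(a, b), 0)
  # |A|=8, |B|=8, overlap 6 -> 12/16
  a2 <- array(0, c(2, 4, 4)); a2[1, 1:2, 1:4] <- 1
  b2 <- array(0, c(2, 4, 4)); b2[1, 1:2, 1:3] <- 1; b2[1, 3, 1:2] <- 1
  expect_equal(sum(a2), 8); expect_equal(sum(b2), 8)
  expect_equal(dice_3d(a2, b2), 0.75)
  expect_equal(dice_3d(b2, a2), dice_3d(a2, b2))
  expect_true(is.na(dice_3d(a * 0, a * 0)))
})

test_that("count categorization bins 0 / 1 / >=2", {
  expect_equal(categorize_count(0), "0")
  expect_equal(categorize_count(1), "1")
  expect_equal(categorize_count(2), ">=2")
  expect_equal(categorize_count(7), ">=2")
  expect_error(categorize_count(-1), ">= 0")
})

test_that("count confusion: perfect predictions and basic invariants", {
  truth <- c(rep("0", 5), rep("1", 3), rep(">=2", 4))
  cm <- count_confusion(truth, truth)
  expect_equal(cm$accuracy, 100)
  expect_equal(sum(cm$matrix) - sum(diag(cm$matrix)), 0L)
  # shuffled predictions: entries still sum to n, columns to 100%
  set.seed(3)
  pred <- sample(truth)
  cm2 <- count_confusion(pred, truth)
  expect_equal(sum(cm2$matrix), length(truth))
  expect_equal(unname(colSums(cm2$normalized)), rep(100, 3))
  expect_equal(cm2$accuracy, 100 * sum(diag(cm2$matrix)) / length(truth))
  expect_error(count_confusion(c("0", "3"), c("0", "1")), "category")
})

test_that("count confusion grouping splits by scan attribute", {
  truth <- c("0", "0", "1", ">=2", "0", "1")
  pred <- c("0", "1", "1", ">=2", "0", "0")
  grp <- c("a", "a", "a", "b", "b", "b")
  out <- count_confusion(pred, truth, group_by = grp)
  expect_named(out, c("a", "b"))
  expect_equal(out$a$n + out$b$n, 6L)
})
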