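# Lesion-wise and voxel-wise evaluation, plus count categorization.
#
# Counting convention (the one that reproduces the reference clinical tables):
# true positives and false negatives are counted over *manual* lesions
# (a manual lesion is detected iff >= 1 predicted voxel overlaps it);
# false positives are counted over *predicted* components (a predicted
# component overlapping no manual lesion). TP/FN carry the manual
# lesion's size; FP carries the predicted component's size.

#' Match predicted components against manual lesions
#'
#' Both masks are decomposed into 6-connected components with a minimum
#' size of `min_size` voxels; overlap of a single voxel counts as
#' detection.
#'
#' @param pred_mask,manual_mask binary 3D arrays on one grid.
#' @param min_size minimum lesion/candidate size (default 5).
#' @return data.frame with one row per event: `type` (`"TP"`, `"FN"`,
#'   `"FP"`), `size` (voxels; manual size for TP/FN, predicted size for
#'   FP), and `id` (component label in its own mask).
#' @export
match_lesions <- function(pred_mask, manual_mask, min_size = 5L) {
  if (!identical(dim(pred_mask), dim(manual_mask)))
    stop("prediction and manual mask differ in shape")
  mcc <- filter_min_size(connected_components_6(manual_mask), min_size)
  pcc <- filter_min_size(connected_components_6(pred_mask), min_size)
  rows <- list()
  pred_fg <- pcc$labels > 0L
  for (k in seq_len(mcc$n_components)) {
    les <- mcc$labels == k
    detected <- any(pred_fg[les])
    rows[[length(rows) + 1L]] <- data.frame(
      type = if (detected) "TP" else "FN", size = mcc$sizes[k], id = k)
  }
  man_fg <- mcc$labels > 0L
  for (k in seq_len(pcc$n_components)) {
    comp <- pcc$labels == k
    if (!any(man_fg[comp]))
      rows[[length(rows) + 1L]] <- data.frame(
        type = "FP", size = pcc$sizes[k], id = k)
  }
  if (!length(rows))
    return(data.frame(type = character(0), size = integer(0),
                      id = integer(0)))
  do.call(rbind, rows)
}

.group_of <- function(size) {
  g <- size_groups()
  for (nm in names(g)) if (size >= g[[nm]][1] && size <= g[[nm]][2]) return(nm)
  NA_character_
}

.ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Size-stratified lesion-wise evaluation report
#'
#' Aggregates match tables (one per image) into per-size-group and total
#' TP/FP/FN counts, sensitivity `TP/(TP+FN)` and false detection rate
#' `FP/(FP+TP)`. Undefined ratios (0/0) are reported as `NA`, never as 0
#' or 1. When predicted/manual mask pairs are supplied, per-image and
#' per-group Dice coefficients are included.
#'
#' @param matches a match table from [match_lesions()], or a list of them
#'   (one per image).
#' @param masks optional list of `list(pred = , manual = )` binary mask
#'   pairs aligned with `matches`, enabling the Dice columns.
#' @param min_size minimum lesion size for the Dice computation.
#' @return Object of class `lesion_eval`: data.frame `by_group` (rows =
#'   groups + Total; columns n_lesions, TP, FN, FP, sensitivity, FDR,
#'   dice), `per_image_dice`, `overall_dice` (mean over images with >= 1
#'   manual lesion).
#' @export
lesion_metrics <- function(matches, masks = NULL, min_size = 5L) {
  if (is.data.frame(matches)) matches <- list(matches)
  all_m <- do.call(rbind, matches)
  gnames <- names(size_groups())
  all_m$group <- vapply(all_m$size, .group_of, character(1))
  tab <- data.frame(group = c(gnames, "Total"), n_lesions = 0L, TP = 0L,
                    FN = 0L, FP = 0L, sensitivity = NA_real_,
                    FDR = NA_real_, dice = NA_real_)
  for (i in seq_len(nrow(tab))) {
    g <- tab$group[i]
    sub <- if (g == "Total") all_m else all_m[all_m$group %in% g, ]
    tp <- sum(sub$type == "TP"); fn <- sum(sub$type == "FN")
    fp <- sum(sub$type == "FP")
    tab$TP[i] <- tp; tab$FN[i] <- fn; tab$FP[i] <- fp
    tab$n_lesions[i] <- tp + fn
    tab$sensitivity[i] <- .ratio(tp, tp + fn)
    tab$FDR[i] <- .ratio(fp, fp + tp)
  }
  per_image_dice <- NULL
  overall_dice <- NA_real_
  if (!is.null(masks)) {
    per_image_dice <- vapply(masks, function(mp)
      dice_3d(mp$pred, mp$manual), numeric(1))
    has_lesion <- vapply(masks, function(mp) any(mp$manual != 0), logical(1))
    if (any(has_lesion))
      overall_dice <- mean(per_image_dice[has_lesion], na.rm = TRUE)
    tab$dice[tab$group == "Total"] <- overall_dice
    for (g in gnames)
      tab$dice[tab$group == g] <- group_dice(masks, g, min_size)
  }
  structure(list(by_group = tab, per_image_dice = per_image_dice,
                 overall_dice = overall_dice),
            class = "lesion_eval")
}

#' @export
print.lesion_eval <- function(x, digits = 3, ...) {
  cat("Lesion-wise evaluation (6-connectivity, one-voxel overlap rule)\n")
  tab <- x$by_group
  tab$sensitivity <- round(tab$sensitivity, digits)
  tab$FDR <- round(tab$FDR, digits)
  tab$dice <- round(tab$dice, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' 3D Dice coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; `NA` when both masks are empty.
#'
#' @param a,b binary 3D arrays of one shape.
#' @return Scalar in `[0, 1]`, or `NA` for the empty/empty case.
#' @export
dice_3d <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

# Dice restricted to one size group: manual sub-mask = union of that
# group's manual lesions; predicted sub-mask = union of predicted
# components overlapping those lesions. The restriction is a design
# choice — the group-wise Dice definition is not standardized.
group_dice <- function(masks, group, min_size = 5L) {
  b <- size_groups()[[group]]
  num <- 0; den <- 0
  for (mp in masks) {
    mcc <- filter_min_size(connected_components_6(mp$manual), min_size)
    in_g <- which(mcc$sizes >= b[1] & mcc$sizes <= b[2])
    if (!length(in_g)) next
    man_sub <- array(mcc$labels %in% in_g, dim(mcc$labels))
    pcc <- filter_min_size(connected_components_6(mp$pred), min_size)
    pred_sub <- array(FALSE, dim(pcc$labels))
    for (k in seq_len(pcc$n_components)) {
      comp <- pcc$labels == k
      if (any(man_sub[comp])) pred_sub <- pred_sub | comp
    }
    num <- num + 2 * sum(pred_sub & man_sub)
    den <- den + sum(pred_sub) + sum(man_sub)
  }
  if (den == 0) NA_real_ else num / den
}

#' Categorize a lesion count as 0, 1, or >=2
#'
#' The granularity of routine radiology reports.
#'
#' @param n_lesions non-negative integer count.
#' @return `"0"`, `"1"`, or `">=2"`.
#' @export
categorize_count <- function(n_lesions) {
  if (is.na(n_lesions) || n_lesions < 0) stop("lesion count must be >= 0")
  if (n_lesions == 0) "0" else if (n_lesions == 1) "1" else ">=2"
}

#' Confusion matrix over lesion-count categories
#'
#' 3x3 matrix (predicted x true) over the categories 0 / 1 / >=2, with
#' column-normalized percentages (each true-category column sums to 100%)
#' and overall accuracy (diagonal sum over total). With `group_by`, one
#' matrix per subgroup (e.g. field strength or vendor) is returned.
#'
#' @param pred,truth character vectors of categories (`"0"`, `"1"`,
#'   `">=2"`), equal length.
#' @param group_by optional vector of subgroup labels, same length.
#' @return Object of class `count_confusion` (or a named list of them,
#'   one per subgroup): fields `matrix` (integer counts), `normalized`
#'   (column percentages), `accuracy` (percent), `n`.
#' @export
count_confusion <- function(pred, truth, group_by = NULL) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  lev <- c("0", "1", ">=2")
  if (!all(pred %in% lev) || !all(truth %in% lev))
    stop("unknown count category; expected 0, 1, >=2")
  if (!is.null(group_by)) {
    if (length(group_by) != length(pred))
      stop("group_by length differs")
    return(lapply(split(seq_along(pred), group_by), function(ix)
      count_confusion(pred[ix], truth[ix])))
  }
  m <- table(factor(pred, lev), factor(truth, lev))
  m <- matrix(as.integer(m), 3, 3, dimnames = list(pred = lev, true = lev))
  cs <- colSums(m)
  norm <- sweep(m, 2, ifelse(cs == 0, NA, cs), "/") * 100
  structure(list(matrix = m, normalized = norm,
                 accuracy = 100 * sum(diag(m)) / sum(m), n = sum(m)),
            class = "count_confusion")
}

#' Build a count confusion matrix from printed cell counts
#'
#' Convenience constructor for recomputing the summary statistics of a
#' reported confusion matrix from its nine integer cells.
#'
#' @param cells 3x3 integer matrix, predicted categories in rows, true
#'   categories in columns, both ordered 0 / 1 / >=2.
#' @return A `count_confusion`.
#' @export
count_confusion_from_cells <- function(cells) {
  stopifnot(is.matrix(cells), all(dim(cells) == c(3L, 3L)), all(cells >= 0))
  lev <- c("0", "1", ">=2")
  pred <- unlist(lapply(1:3, function(j) rep(lev, cells[, j])))
  truth <- unlist(lapply(1:3, function(j) rep(lev[j], sum(cells[, j]))))
  count_confusion(pred, truth)
}

#' @export
print.count_confusion <- function(x, ...) {
  cat("Lesion-count confusion matrix (n =", x$n, "scans)\n")
  show <- matrix(sprintf("%d (%.1f%%)", x$matrix, x$normalized), 3, 3,
                 dimnames = dimnames(x$matrix))
  print(show, quote = FALSE)
  cat(sprintf("overall accuracy: %.1f%%\n", x$accuracy))
  invisible(x)
}
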