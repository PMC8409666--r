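# Random-forest false-positive filter over the 75 candidate features.

#' Random-forest filter configuration
#'
#' @param n_trees number of trees.
#' @param score_threshold probability cut for keeping a candidate.
#' @param seed RNG seed for forest construction.
#' @return List of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100L, score_threshold = 0.5, seed = 1L) {
  stopifnot(n_trees >= 1L, score_threshold > 0, score_threshold < 1)
  structure(list(n_trees = as.integer(n_trees),
                 score_threshold = score_threshold,
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Label candidates against a manual mask
#'
#' A candidate is a true lesion iff it overlaps the manual segmentation in
#' at least one voxel — the same one-voxel overlap rule used in
#' evaluation — otherwise a false positive.
#'
#' @param cand result of [extract_candidates()].
#' @param manual_mask binary 3D array on the candidate grid.
#' @return The candidate data.frame with a `label` factor column
#'   (`"lesion"` / `"fp"`).
#' @export
label_candidates <- function(cand, manual_mask) {
  if (!identical(dim(cand$labels), dim(manual_mask)))
    stop("candidate grid and manual mask differ in shape")
  lab <- vapply(cand$components, function(vox)
    any(manual_mask[vox] != 0), logical(1))
  df <- cand$candidates
  df$label <- factor(ifelse(lab, "lesion", "fp"), levels = c("fp", "lesion"))
  df
}

#' Fit the random-forest candidate classifier
#'
#' @param labeled data.frame from [label_candidates()] (possibly several
#'   scans' worth, row-bound); must contain both classes.
#' @param cfg an [rf_config()].
#' @return Object of class `gad_rf`: the forest, the feature layout it was
#'   trained on, its config, and a named importance table (mean decrease
#'   in Gini, ordered).
#' @export
fit_rf <- function(labeled, cfg = rf_config()) {
  stopifnot(inherits(cfg, "rf_config"))
  if (!"label" %in% names(labeled)) stop("candidates are not labeled")
  if (nlevels(droplevels(labeled$label)) < 2L)
    stop("single-class training set: need both true lesions and false positives")
  feats <- labeled[, feature_layout(), drop = FALSE]
  set.seed(cfg$seed)
  forest <- randomForest::randomForest(
    x = feats, y = labeled$label, ntree = cfg$n_trees)
  imp <- randomForest::importance(forest)[, 1]
  structure(list(forest = forest, layout = feature_layout(), config = cfg,
                 importance = sort(imp, decreasing = TRUE)),
            class = "gad_rf")
}

#' @export
print.gad_rf <- function(x, ...) {
  cat("<gad_rf> ", x$config$n_trees, " trees, threshold ",
      x$config$score_threshold, "\n  top features: ",
      paste(names(x$importance)[1:min(5, length(x$importance))],
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score and filter candidates with a trained forest
#'
#' Keeps candidates whose lesion-class probability reaches the score
#' threshold; the filtered 3D mask is the union of the kept components.
#' Filtering only removes voxels, never adds them.
#'
#' @param rf a `gad_rf` from [fit_rf()].
#' @param cand result of [extract_candidates()].
#' @param score_threshold override of the config threshold (optional).
#' @return List with `candidates` (data.frame plus `rf_score` and `kept`
#'   columns), `mask` (filtered logical 3D array) and `kept_ids`.
#' @export
apply_rf <- function(rf, cand, score_threshold = NULL) {
  stopifnot(inherits(rf, "gad_rf"))
  thr <- score_threshold %||% rf$config$score_threshold
  df <- cand$candidates
  mask <- array(FALSE, dim(cand$labels))
  if (nrow(df) == 0L)
    return(list(candidates = cbind(df, rf_score = numeric(0),
                                   kept = logical(0)),
                mask = mask, kept_ids = integer(0)))
  if (!all(rf$layout %in% names(df)))
    stop("candidate table does not carry the feature layout the forest expects")
  score <- unname(predict(rf$forest, df[, rf$layout, drop = FALSE],
                          type = "prob")[, "lesion"])
  kept <- score >= thr
  for (k in which(kept)) mask[cand$components[[k]]] <- TRUE
  df$rf_score <- as.numeric(score)
  df$kept <- kept
  list(candidates = df, mask = mask, kept_ids = which(kept))
}
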