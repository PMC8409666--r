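# Training losses for the voxel classifier.
#
# All three losses treat the batch as a flat bag of voxels: x is the binary
# manual mask, x_hat the predicted probability per voxel. The bootstrapped
# variant averages only the K hardest voxels (largest per-voxel
# cross-entropy), the standard online-hard-example-mining form.

.CLAMP_DELTA <- 1e-7

.clamp_prob <- function(p) pmin(pmax(p, .CLAMP_DELTA), 1 - .CLAMP_DELTA)

.check_shapes <- function(x, x_hat) {
  if (!identical(dim(x) %||% length(x), dim(x_hat) %||% length(x_hat)))
    stop("shape mismatch between target and prediction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dice coefficient loss
#'
#' `1 - 2 * sum(x * x_hat) / (sum(x) + sum(x_hat))`, the soft-Dice loss.
#' Zero for identical binary masks, one for disjoint supports (as the
#' smoothing term goes to zero).
#'
#' @param x binary target mask (any numeric array; values 0/1).
#' @param x_hat predicted probabilities, same shape.
#' @param smooth smoothing constant added to numerator and denominator
#'   (default 0: the plain ratio; the empty/empty case then errors).
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(x, x_hat, smooth = 0) {
  .check_shapes(x, x_hat)
  stopifnot(smooth >= 0)
  num <- 2 * sum(x * x_hat) + smooth
  den <- sum(x) + sum(x_hat) + smooth
  if (den == 0)
    stop("Dice loss undefined: both masks empty and smooth = 0")
  1 - num / den
}

#' Per-voxel binary cross-entropy
#'
#' `p_j = -x_j log(x_hat_j) - (1 - x_j) log(1 - x_hat_j)`, with the
#' prediction clamped away from 0 and 1 for numerical stability.
#'
#' @inheritParams dice_loss
#' @return Array of per-voxel losses, same shape as the input.
#' @export
per_voxel_ce <- function(x, x_hat) {
  .check_shapes(x, x_hat)
  p <- .clamp_prob(x_hat)
  -x * log(p) - (1 - x) * log(1 - p)
}

#' Mean binary cross-entropy over a batch
#'
#' @inheritParams dice_loss
#' @return Scalar, the mean of [per_voxel_ce()] over all N voxels.
#' @export
cross_entropy_loss <- function(x, x_hat) {
  mean(per_voxel_ce(x, x_hat))
}

#' Bootstrapped (top-K) cross-entropy
#'
#' Cross-entropy averaged over only the K voxels of the batch with the
#' largest per-voxel loss — the voxels hardest to label, typically lesion
#' boundaries and small lesions. The selection threshold is the (K+1)-th
#' largest loss; ties at the threshold are broken by voxel order so that
#' exactly K voxels enter the 1/K average. With `K >= N` this reduces to
#' the plain mean cross-entropy.
#'
#' @inheritParams dice_loss
#' @param K integer voxel budget, `K >= 1`.
#' @return Scalar loss.
#' @export
bootstrapped_ce <- function(x, x_hat, K) {
  if (length(K) != 1L || is.na(K) || K < 1) stop("K must be a single integer >= 1")
  K <- as.integer(K)
  p <- as.vector(per_voxel_ce(x, x_hat))
  N <- length(p)
  if (K >= N) return(mean(p))
  idx <- topk_voxels(p, K)
  sum(p[idx]) / K
}

# Indices of the K largest per-voxel losses, stable in voxel order.
# sort(partial=) would suffice for the value; the index set is needed for
# the training gradient, so use a full order() here (radix, stable).
topk_voxels <- function(p, K) {
  K <- as.integer(K)
  if (K >= length(p)) return(seq_along(p))
  order(p, decreasing = TRUE, method = "radix")[seq_len(K)]
}
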