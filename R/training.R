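# Training: lesion-balanced batch sampling over consecutive slice runs,
# Adam optimization of the UNet under the selected loss, validation by
# mean 3D Dice, best-checkpoint selection.

#' Training configuration
#'
#' Defaults follow the full-scale clinical training protocol: batch size 16, Adam
#' with first-moment decay (momentum) 0.5 and learning rate 1e-4,
#' bootstrapped cross-entropy with a per-batch hard-voxel budget K.
#' Batches are non-overlapping runs of consecutive slices within a scan;
#' every batch containing lesion voxels is used each epoch, while
#' lesion-free batches are kept independently with `keep_empty_prob`.
#'
#' @param loss one of `"dice"`, `"ce"`, `"bootstrap_ce"`.
#' @param K hard-voxel budget for `bootstrap_ce` (ignored otherwise).
#'   Full-scale reference budgets are 256, 1536, 3072 at batch size 16.
#' @param batch_size slices per batch.
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decays (`beta1` is the momentum value).
#' @param epochs training epochs.
#' @param keep_empty_prob retention probability for lesion-free batches.
#' @param threshold probability cut used to binarize predictions.
#' @param base_filters first-depth width of the network (32 = full clinical
#'   scale; reduce for desk-scale runs).
#' @param seed RNG seed controlling initialization and batch sampling.
#' @return List of class `train_config`.
#' @export
train_config <- function(loss = "bootstrap_ce", K = 3072L, batch_size = 16L,
                         lr = 1e-4, beta1 = 0.5, beta2 = 0.999,
                         epochs = 10L, keep_empty_prob = 0.1,
                         threshold = 0.5, base_filters = 32L, seed = 1L) {
  loss <- match.arg(loss, c("dice", "ce", "bootstrap_ce"))
  stopifnot(batch_size >= 1L, keep_empty_prob >= 0, keep_empty_prob <= 1,
            threshold > 0, threshold < 1)
  structure(list(loss = loss, K = as.integer(K),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, epochs = as.integer(epochs),
                 keep_empty_prob = keep_empty_prob, threshold = threshold,
                 base_filters = as.integer(base_filters),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Partition each scan's slices into consecutive non-overlapping windows and
# flag whether the window contains any lesion voxel.
.slice_windows <- function(scans, batch_size) {
  out <- list()
  for (si in seq_along(scans)) {
    st <- scans[[si]]
    if (is.null(st$mask)) stop("scan '", st$scan_id, "' has no mask")
    S <- dim(st$data)[2]
    if (batch_size > S)
      stop("batch_size (", batch_size, ") exceeds slice count (", S, ")")
    starts <- seq(1L, S, by = batch_size)
    for (b in starts) {
      idx <- b:min(b + batch_size - 1L, S)
      has <- any(st$mask[idx, , ] != 0)
      out[[length(out) + 1L]] <- list(scan = si, slices = idx,
                                      has_lesion = has)
    }
  }
  out
}

#' Lesion-balanced stream of training batches for one epoch
#'
#' Every batch (a run of consecutive slices within one scan) that contains
#' at least one lesion voxel is emitted; each lesion-free batch is emitted
#' independently with probability `cfg$keep_empty_prob`. Order is shuffled.
#' Uses the current RNG state; seed it for reproducibility.
#'
#' @param scans list of `volume_stack` objects with masks.
#' @param cfg a [train_config()].
#' @return List of batches: `scan` (index into `scans`), `slices`
#'   (slice indices), `has_lesion`.
#' @export
batch_stream <- function(scans, cfg) {
  if (length(scans) == 0L) stop("no scans")
  wins <- .slice_windows(scans, cfg$batch_size)
  keep <- vapply(wins, function(w) {
    w$has_lesion || runif(1) < cfg$keep_empty_prob
  }, logical(1))
  wins <- wins[keep]
  wins[sample.int(length(wins))]
}

# (H, W, n, C) input and (H, W, n) target for one batch.
.batch_tensors <- function(stack, slices) {
  d <- dim(stack$data)
  x <- stack$data[, slices, , , drop = FALSE]       # C x n x H x W
  x <- aperm(x, c(3, 4, 2, 1))
  m <- stack$mask[slices, , , drop = FALSE]
  m <- aperm(array(as.numeric(m != 0), dim(m)), c(2, 3, 1))
  list(x = x, target = m)
}

# Gradient of the selected loss at the pre-sigmoid logit.
.loss_and_dz <- function(cfg, target, p) {
  N <- length(p)
  tv <- as.vector(target); pv <- as.vector(p)
  if (cfg$loss == "ce") {
    loss <- cross_entropy_loss(tv, pv)
    dz <- (pv - tv) / N
  } else if (cfg$loss == "dice") {
    smooth <- 1
    I <- sum(tv * pv); S <- sum(tv) + sum(pv) + smooth
    loss <- 1 - (2 * I + smooth) / S
    dp <- -2 * (tv * S - (2 * I + smooth) / 2) / S^2
    dz <- dp * pv * (1 - pv)
  } else {
    pj <- per_voxel_ce(tv, pv)
    K <- min(cfg$K, N)
    idx <- topk_voxels(pj, K)
    loss <- sum(pj[idx]) / K
    dz <- numeric(N)
    dz[idx] <- (pv[idx] - tv[idx]) / K
  }
  list(loss = loss, dz = array(dz, c(dim(p)[1:3], 1L)))
}

.adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0L)
}

.adam_step <- function(par, grads, opt, cfg, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - cfg$beta1^opt$t
  c2 <- 1 - cfg$beta2^opt$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- cfg$beta1 * opt$m[[nm]] + (1 - cfg$beta1) * g
    opt$v[[nm]] <- cfg$beta2 * opt$v[[nm]] + (1 - cfg$beta2) * g * g
    par[[nm]] <- par[[nm]] -
      cfg$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(par = par, opt = opt)
}

#' Train the UNet on a set of scans
#'
#' Optimizes the network under the configured loss with lesion-balanced
#' batch sampling, evaluates mean 3D Dice on the validation scans after
#' every epoch, and returns the parameters of the best-validating epoch.
#' Deterministic given `cfg$seed`.
#'
#' @param scans list of training `volume_stack` objects (with masks).
#' @param val_scans list of validation `volume_stack` objects (with masks);
#'   must be non-empty and disjoint from `scans`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return An object of class `unet_fit`: fields `net` (best checkpoint),
#'   `log` (per-epoch data.frame: epoch, train_loss, val_dice),
#'   `best_epoch`, `config`.
#' @export
train_unet <- function(scans, val_scans, cfg = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(val_scans) == 0L) stop("empty validation set")
  in_ch <- dim(scans[[1]]$data)[1]
  net <- build_unet(unet_spec(in_ch, cfg$base_filters), seed = cfg$seed)
  opt <- .adam_init(net$par)
  set.seed(cfg$seed + 1L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_dice = numeric())
  best <- list(dice = -Inf, par = net$par, state = net$state, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    batches <- batch_stream(scans, cfg)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      bt <- .batch_tensors(scans[[b$scan]], b$slices)
      fw <- unet_forward(net, bt$x, training = TRUE, grad = TRUE)
      net <- fw$net
      ld <- .loss_and_dz(cfg, bt$target, fw$p)
      if (!is.finite(ld$loss))
        stop("non-finite training loss at epoch ", ep, ", batch ", bi)
      grads <- unet_backward(net, fw, ld$dz)
      upd <- .adam_step(net$par, grads, opt, cfg)
      net$par <- upd$par
      opt <- upd$opt
      losses[bi] <- ld$loss
    }
    vd <- vapply(val_scans, function(vs) {
      pm <- predict_volume(net, vs, cfg$threshold)
      dice_3d(pm$binary, vs$mask != 0)
    }, numeric(1))
    val_dice <- mean(vd, na.rm = TRUE)
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                 val_dice = val_dice))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val Dice %.3f",
                      ep, mean(losses), val_dice))
    if (is.finite(val_dice) && val_dice > best$dice)
      best <- list(dice = val_dice, par = net$par, state = net$state,
                   epoch = ep)
  }
  net$par <- best$par
  net$state <- best$state
  structure(list(net = net, log = log, best_epoch = best$epoch,
                 config = cfg),
            class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  cat("<unet_fit> loss:", x$config$loss,
      if (x$config$loss == "bootstrap_ce") paste0("(K=", x$config$K, ")"),
      "\n  epochs:", nrow(x$log),
      " best epoch:", x$best_epoch,
      sprintf(" (val Dice %.3f)\n", x$log$val_dice[x$best_epoch]))
  invisible(x)
}

#' @export
summary.unet_fit <- function(object, ...) {
  print(object)
  print(object$log)
  invisible(object$log)
}

#' Predict a 3D probability map for a volume stack
#'
#' Runs slice-wise inference and restacks the per-slice 2D maps into a 3D
#' probability volume, then binarizes at `threshold`.
#'
#' @param net a `unet2d` or `unet_fit`.
#' @param stack a `volume_stack` whose channels match the network input.
#' @param threshold binarization cut on the sigmoid output.
#' @return List with `prob` (3D array, slice x row x column, values in
#'   (0,1)) and `binary` (logical 3D array).
#' @export
predict_volume <- function(net, stack, threshold = 0.5) {
  if (inherits(net, "unet_fit")) net <- net$net
  stopifnot(inherits(net, "unet2d"), inherits(stack, "volume_stack"))
  d <- dim(stack$data)
  if (d[1] != net$spec$in_channels)
    stop("stack has ", d[1], " channels; network expects ",
         net$spec$in_channels)
  x <- aperm(stack$data, c(3, 4, 2, 1))       # H x W x S x C
  out <- unet_forward(net, x, training = FALSE, grad = FALSE)
  prob <- aperm(array(out$p, dim(out$p)[1:3]), c(3, 1, 2))
  list(prob = prob, binary = prob >= threshold)
}
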