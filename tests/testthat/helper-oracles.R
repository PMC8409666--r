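# Independent oracles: deliberately naive scalar-loop / brute-force
# implementations used only to check the package's vectorized code paths.

# scalar-loop binary cross-entropy, clamped like the implementation
ce_loop_oracle <- function(x, x_hat, delta = 1e-7) {
  x <- as.vector(x); x_hat <- as.vector(x_hat)
  tot <- 0
  for (j in seq_along(x)) {
    p <- min(max(x_hat[j], delta), 1 - delta)
    tot <- tot + (-x[j] * log(p) - (1 - x[j]) * log(1 - p))
  }
  tot / length(x)
}

# scalar-loop Dice loss
dice_loop_oracle <- function(x, x_hat) {
  x <- as.vector(x); x_hat <- as.vector(x_hat)
  num <- 0; dx <- 0; dh <- 0
  for (j in seq_along(x)) {
    num <- num + x[j] * x_hat[j]
    dx <- dx + x[j]; dh <- dh + x_hat[j]
  }
  1 - 2 * num / (dx + dh)
}

# full-sort bootstrapped cross-entropy: mean of the K largest per-voxel
# losses (descending sort, take first K)
boot_sort_oracle <- function(x, x_hat, K, delta = 1e-7) {
  x <- as.vector(x); x_hat <- as.vector(x_hat)
  p <- pmin(pmax(x_hat, delta), 1 - delta)
  pj <- -x * log(p) - (1 - x) * log(1 - p)
  pj <- sort(pj, decreasing = TRUE)
  mean(pj[seq_len(min(K, length(pj)))])
}

# breadth-first flood-fill 6-connected labeling
flood_fill_cc <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] != 0 && lab[i, j, k] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j, k))
      lab[i, j, k] <- nxt
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (o in seq_len(6)) {
          w <- v + offs[o, ]
          if (all(w >= 1) && all(w <= d) &&
              mask[w[1], w[2], w[3]] != 0 && lab[w[1], w[2], w[3]] == 0L) {
            lab[w[1], w[2], w[3]] <- nxt
            queue[[length(queue) + 1L]] <- w
          }
        }
      }
    }
  }
  lab
}

# are two labelings identical up to relabeling?
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  fg <- a > 0
  pairs <- unique(cbind(a[fg], b[fg]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}

# brute-force lesion-wise matching: enumerate all (manual, predicted)
# component pairs and test voxel overlap directly
match_brute_oracle <- function(pred, manual, min_size = 5L) {
  pcc <- filter_min_size(connected_components_6(pred), min_size)
  mcc <- filter_min_size(connected_components_6(manual), min_size)
  overlap <- matrix(FALSE, mcc$n_components, pcc$n_components)
  for (a in seq_len(mcc$n_components)) for (b in seq_len(pcc$n_components))
    overlap[a, b] <- any(mcc$labels == a & pcc$labels == b)
  tp <- sum(apply(overlap, 1, any))
  c(TP = tp,
    FN = mcc$n_components - tp,
    FP = if (pcc$n_components)
      sum(!apply(overlap, 2, any)) else 0L)
}

# minimal volume_stack for tests that only need data/mask geometry
make_toy_stack <- function(S = 8L, H = 16L, W = 16L, n_channels = 3L,
                           mask = NULL, seed = 1L) {
  set.seed(seed)
  chans <- GAD_CHANNELS[seq_len(n_channels)]
  vols <- setNames(lapply(chans, function(ch)
    array(rnorm(S * H * W), c(S, H, W))), chans)
  cfgobj <- contrast_config(chans, name = "toy")
  if (is.null(mask)) mask <- array(FALSE, c(S, H, W))
  stack_channels(vols, cfgobj, mask = mask, scan_id = paste0("toy", seed))
}

# small lesion-bearing phantom set shared by training/pipeline tests
toy_phantoms <- function(n, seed0 = 300L, shape = c(16L, 64L, 64L),
                         groups = c("51-100", ">100")) {
  lapply(seq_len(n), function(i) generate_phantom(
    phantom_spec(shape = shape, n_lesions = 3L, groups = groups,
                 seed = seed0 + i)))
}
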