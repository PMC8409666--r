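# 2D UNet: declarative architecture spec, parameter accounting, builder,
# and forward/backward passes over the layers in nn_ops.R.
#
# Five depths; each depth is two 3x3 conv + batch-norm + ReLU units.
# Encoder filter widths 32..512 (scaled by base_filters/32); 2x2 max
# pooling between encoder depths; the decoder upsamples (non-learned,
# nearest-neighbour 2x2), concatenates the encoder skip, and applies two
# conv units at the skip's width; a 1x1 convolution plus sigmoid produces
# the voxel-wise lesion probability map. With 10 input channels and
# base width 32 the trainable-parameter total is ~7.85 million, matching
# the reference clinical architecture (~7.8M).

#' Declare the UNet architecture
#'
#' @param in_channels number of input channels (5-10 depending on the
#'   contrast configuration).
#' @param base_filters width of the first encoder depth; subsequent depths
#'   double it (default 32, giving encoder widths 32, 64, 128, 256, 512).
#'   Reduce for desk-scale experiments.
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(in_channels = 10L, base_filters = 32L) {
  stopifnot(in_channels >= 1L, base_filters >= 1L)
  enc <- as.integer(base_filters * c(1L, 2L, 4L, 8L, 16L))
  structure(list(
    in_channels = as.integer(in_channels),
    depths = 5L,
    encoder_filters = enc,
    decoder_filters = rev(enc),
    convs_per_depth = 2L,
    kernel = c(3L, 3L)
  ), class = "unet_spec")
}

#' @export
print.unet_spec <- function(x, ...) {
  cat("<unet_spec> in_channels:", x$in_channels,
      " encoder:", paste(x$encoder_filters, collapse = "-"),
      "\n  parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

# Per-unit channel plan: list of (name, cin, cout) for every conv unit.
.unet_units <- function(spec) {
  f <- spec$encoder_filters
  units <- list()
  cin <- spec$in_channels
  for (i in 1:5) {
    units[[paste0("e", i, "a")]] <- c(cin, f[i])
    units[[paste0("e", i, "b")]] <- c(f[i], f[i])
    cin <- f[i]
  }
  prev <- f[5]
  for (j in 4:1) {
    units[[paste0("d", j, "a")]] <- c(prev + f[j], f[j])
    units[[paste0("d", j, "b")]] <- c(f[j], f[j])
    prev <- f[j]
  }
  units
}

#' Count trainable parameters of a UNet spec
#'
#' Closed-form accounting over the conv units (3x3 weights + bias), the
#' batch-normalization scale/shift pairs, and the 1x1 sigmoid head.
#' Batch-norm running statistics are not trainable and are excluded.
#'
#' @param spec a [unet_spec()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  units <- .unet_units(spec)
  total <- 0
  for (u in units) {
    cin <- u[1]; cout <- u[2]
    total <- total + 9 * cin * cout + cout + 2 * cout
  }
  total + spec$encoder_filters[1] * 1 + 1      # 1x1 head
}

#' Build a UNet with freshly initialized weights
#'
#' Weights are He-uniform; the build is deterministic given `seed`.
#'
#' @param spec a [unet_spec()].
#' @param seed integer RNG seed for initialization.
#' @return An object of class `unet2d` holding the parameter list and
#'   batch-norm running statistics.
#' @export
build_unet <- function(spec = unet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  set.seed(seed)
  units <- .unet_units(spec)
  par <- list()
  state <- list()
  for (nm in names(units)) {
    cin <- units[[nm]][1]; cout <- units[[nm]][2]
    cv <- conv3x3_init(cin, cout)
    par[[paste0(nm, ".W")]] <- cv$W
    par[[paste0(nm, ".b")]] <- cv$b
    par[[paste0(nm, ".g")]] <- rep(1, cout)
    par[[paste0(nm, ".be")]] <- numeric(cout)
    state[[paste0(nm, ".rm")]] <- numeric(cout)
    state[[paste0(nm, ".rv")]] <- rep(1, cout)
  }
  f1 <- spec$encoder_filters[1]
  lim <- sqrt(6 / f1)
  par[["head.W"]] <- matrix(runif(f1, -lim, lim), f1, 1)
  par[["head.b"]] <- 0
  structure(list(spec = spec, par = par, state = state), class = "unet2d")
}

#' @export
print.unet2d <- function(x, ...) {
  cat("<unet2d> ")
  print(x$spec)
  invisible(x)
}

#' Number of trainable parameters in a built network
#'
#' @param net a `unet2d`.
#' @return Integer; equals [count_parameters()] on the network's spec.
#' @export
n_parameters <- function(net) {
  stopifnot(inherits(net, "unet2d"))
  sum(vapply(net$par, length, integer(1)))
}

.check_unet_input <- function(net, x) {
  d <- dim(x)
  if (length(d) != 4L)
    stop("input must be a 4D (H, W, N, C) array")
  if (d[4] != net$spec$in_channels)
    stop("input has ", d[4], " channels; network expects ",
         net$spec$in_channels)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("spatial size ", d[1], "x", d[2],
         " not divisible by 16 (four poolings)")
}

# One conv + BN + ReLU unit. Returns activation, per-unit cache, and the
# (possibly updated) running stats.
.unit_fwd <- function(net, nm, x, training, cache) {
  par <- list(W = net$par[[paste0(nm, ".W")]], b = net$par[[paste0(nm, ".b")]])
  y <- conv3x3_fwd(x, par, cache = cache)
  conv_cache <- attr(y, "cache"); attr(y, "cache") <- NULL
  bnpar <- list(gamma = net$par[[paste0(nm, ".g")]],
                beta = net$par[[paste0(nm, ".be")]],
                run_mean = net$state[[paste0(nm, ".rm")]],
                run_var = net$state[[paste0(nm, ".rv")]])
  bn <- bn_fwd(y, bnpar, training = training)
  a <- relu_fwd(bn$y)
  list(a = a,
       cache = if (cache) list(conv = conv_cache, bn = bn$cache, a = a),
       rm = bn$par$run_mean, rv = bn$par$run_var)
}

# Full forward pass. training=TRUE uses batch statistics, updates running
# stats, and (when grad=TRUE) retains the caches needed by unet_backward().
unet_forward <- function(net, x, training = FALSE, grad = FALSE) {
  .check_unet_input(net, x)
  caches <- if (grad) list()
  skips <- list()
  h <- x
  pools <- list()
  for (i in 1:5) {
    for (s in c("a", "b")) {
      nm <- paste0("e", i, s)
      u <- .unit_fwd(net, nm, h, training, grad)
      h <- u$a
      if (training) {
        net$state[[paste0(nm, ".rm")]] <- u$rm
        net$state[[paste0(nm, ".rv")]] <- u$rv
      }
      if (grad) caches[[nm]] <- u$cache
    }
    if (i < 5) {
      skips[[i]] <- h
      p <- pool2_fwd(h)
      h <- p$y
      if (grad) pools[[i]] <- p$cache
    }
  }
  widths <- net$spec$encoder_filters
  for (j in 4:1) {
    h <- up2_fwd(h)
    h <- concat_ch(skips[[j]], h)
    for (s in c("a", "b")) {
      nm <- paste0("d", j, s)
      u <- .unit_fwd(net, nm, h, training, grad)
      h <- u$a
      if (training) {
        net$state[[paste0(nm, ".rm")]] <- u$rm
        net$state[[paste0(nm, ".rv")]] <- u$rv
      }
      if (grad) caches[[nm]] <- u$cache
    }
  }
  d <- dim(h)
  Hm <- .nn_as_mat(h)
  z <- Hm %*% net$par[["head.W"]] + net$par[["head.b"]]
  p <- sigmoid(z)
  pmap <- .nn_as_map(p, d[1], d[2], d[3])
  if (!grad) return(list(p = pmap, net = net))
  list(p = pmap, net = net,
       caches = list(units = caches, pools = pools, head_in = Hm,
                     dims = d))
}

.unit_bwd <- function(net, nm, dy, cache) {
  dy <- relu_bwd(dy, cache$a)
  bnpar <- list(gamma = net$par[[paste0(nm, ".g")]])
  bb <- bn_bwd(dy, bnpar, cache$bn)
  cv <- conv3x3_bwd(bb$dx,
                    list(W = net$par[[paste0(nm, ".W")]]),
                    cache$conv)
  list(dx = cv$dx,
       grads = stats::setNames(
         list(cv$dW, cv$db, bb$dgamma, bb$dbeta),
         paste0(nm, c(".W", ".b", ".g", ".be"))))
}

# Backward pass from dL/dz (gradient at the pre-sigmoid logit, as an
# (H, W, N, 1) array). Returns gradients named like the parameters.
unet_backward <- function(net, fw, dz) {
  grads <- list()
  dzm <- .nn_as_mat(dz)
  grads[["head.W"]] <- crossprod(fw$caches$head_in, dzm)
  grads[["head.b"]] <- sum(dzm)
  dh <- .nn_as_map(dzm %*% t(net$par[["head.W"]]),
                   fw$caches$dims[1], fw$caches$dims[2], fw$caches$dims[3])
  widths <- net$spec$encoder_filters
  dskips <- list()
  for (j in 1:4) {
    for (s in c("b", "a")) {
      nm <- paste0("d", j, s)
      u <- .unit_bwd(net, nm, dh, fw$caches$units[[nm]])
      dh <- u$dx
      grads <- c(grads, u$grads)
    }
    sp <- split_ch(dh, widths[j])
    dskips[[j]] <- sp[[1]]
    dh <- up2_bwd(sp[[2]])
  }
  for (i in 5:1) {
    if (i < 5) {
      dh <- pool2_bwd(dh, fw$caches$pools[[i]])
      dh <- dh + dskips[[i]]
    }
    for (s in c("b", "a")) {
      nm <- paste0("e", i, s)
      u <- .unit_bwd(net, nm, dh, fw$caches$units[[nm]])
      dh <- u$dx
      grads <- c(grads, u$grads)
    }
  }
  grads
}

#' Run the network on a batch of 2D multi-channel images
#'
#' Inference-mode forward pass (batch-norm uses running statistics).
#'
#' @param object a `unet2d`.
#' @param x array of shape (H, W, N, C) — rows, columns, batch, channels —
#'   or (H, W, C) for a single image.
#' @param ... unused.
#' @return Probability array of shape (H, W, N), values in (0, 1).
#' @export
predict.unet2d <- function(object, x, ...) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  out <- unet_forward(object, x, training = FALSE, grad = FALSE)
  array(out$p, dim(out$p)[1:3])
}
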