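# Minimal 2D neural-network layers on base matrix algebra.
#
# Feature maps are arrays of shape (H, W, N, C): rows, columns, batch,
# channels. Channel-last keeps every layer a plain matrix op on the
# (H*W*N) x C matrix view — reshapes are free, no aperm() in the hot path.
# Convolutions use im2col (9 shifted copies for a 3x3 kernel) and a single
# BLAS GEMM; the backward pass scatters gradients back with 9 shifted adds.

.nn_as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

.nn_as_map <- function(m, H, W, N) {
  dim(m) <- c(H, W, N, ncol(m) %||% 1L)
  m
}

# ---- 3x3 "same" convolution -------------------------------------------------

# weight: (9*Cin) x Cout matrix, rows ordered offset-major
# (offset k in column-major 3x3 order, then channel within offset).
conv3x3_init <- function(cin, cout, rng_scale = TRUE) {
  fan_in <- 9L * cin
  limit <- sqrt(6 / fan_in)            # He-uniform
  W <- matrix(runif(fan_in * cout, -limit, limit), fan_in, cout)
  list(W = W, b = numeric(cout))
}

.im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  xp <- array(0, c(H + 2L, Wd + 2L, N, C))
  xp[2:(H + 1L), 2:(Wd + 1L), , ] <- x
  M <- H * Wd * N
  X <- matrix(0, M, 9L * C)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    blk <- xp[di + seq_len(H), dj + seq_len(Wd), , , drop = FALSE]
    X[, ((k - 1L) * C + 1L):(k * C)] <- blk
  }
  X
}

conv3x3_fwd <- function(x, par, cache = FALSE) {
  d <- dim(x)
  X <- .im2col3(x)
  Y <- X %*% par$W
  Y <- Y + rep(par$b, each = nrow(Y))
  out <- .nn_as_map(Y, d[1], d[2], d[3])
  if (cache) attr(out, "cache") <- list(X = X, dims = d)
  out
}

conv3x3_bwd <- function(dy, par, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  dYm <- .nn_as_mat(dy)
  dW <- crossprod(cache$X, dYm)
  db <- colSums(dYm)
  dXc <- dYm %*% t(par$W)                 # M x 9C
  dxp <- array(0, c(H + 2L, Wd + 2L, N, C))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    blk <- dXc[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
    dim(blk) <- c(H, Wd, N, C)
    dxp[di + seq_len(H), dj + seq_len(Wd), , ] <-
      dxp[di + seq_len(H), dj + seq_len(Wd), , , drop = FALSE] + blk
  }
  dx <- dxp[2:(H + 1L), 2:(Wd + 1L), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization ----------------------------------------------------

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

bn_fwd <- function(x, par, training = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  Xm <- .nn_as_mat(x)
  M <- nrow(Xm)
  if (training) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2L, mu)
    va <- colMeans(xc * xc)               # biased, as in training-time BN
    par$run_mean <- (1 - momentum) * par$run_mean + momentum * mu
    par$run_var  <- (1 - momentum) * par$run_var  + momentum * va
  } else {
    mu <- par$run_mean
    va <- par$run_var
    xc <- sweep(Xm, 2L, mu)
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  Y <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
  out <- .nn_as_map(Y, d[1], d[2], d[3])
  list(y = out, par = par,
       cache = list(xhat = xhat, invstd = invstd, dims = d))
}

bn_bwd <- function(dy, par, cache) {
  d <- cache$dims
  dYm <- .nn_as_mat(dy)
  M <- nrow(dYm)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  # dx = gamma*invstd/M * (M*dy - sum(dy) - xhat * sum(dy*xhat))
  t1 <- M * dYm
  t1 <- sweep(t1, 2L, dbeta)
  t1 <- t1 - sweep(cache$xhat, 2L, dgamma, "*")
  dx <- sweep(t1, 2L, par$gamma * cache$invstd / M, "*")
  list(dx = .nn_as_map(dx, d[1], d[2], d[3]),
       dgamma = dgamma, dbeta = dbeta)
}

# ---- activations ------------------------------------------------------------

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(dy, y) {
  dy[y <= 0] <- 0
  dy
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- 2x2 max pooling --------------------------------------------------------

pool2_fwd <- function(x) {
  d <- dim(x); H <- d[1]; Wd <- d[2]
  stopifnot(H %% 2L == 0L, Wd %% 2L == 0L)
  io <- seq(1L, H, 2L); ie <- seq(2L, H, 2L)
  jo <- seq(1L, Wd, 2L); je <- seq(2L, Wd, 2L)
  a <- list(x[io, jo, , , drop = FALSE], x[io, je, , , drop = FALSE],
            x[ie, jo, , , drop = FALSE], x[ie, je, , , drop = FALSE])
  m <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  k1 <- a[[1]] == m
  k2 <- (a[[2]] == m) & !k1
  k3 <- (a[[3]] == m) & !(k1 | k2)
  k4 <- !(k1 | k2 | k3)
  list(y = m, cache = list(k = list(k1, k2, k3, k4), dims = d))
}

pool2_bwd <- function(dy, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]
  io <- seq(1L, H, 2L); ie <- seq(2L, H, 2L)
  jo <- seq(1L, Wd, 2L); je <- seq(2L, Wd, 2L)
  dx <- array(0, d)
  k <- cache$k
  dx[io, jo, , ] <- dy * k[[1]]
  dx[io, je, , ] <- dy * k[[2]]
  dx[ie, jo, , ] <- dy * k[[3]]
  dx[ie, je, , ] <- dy * k[[4]]
  dx
}

# ---- 2x2 nearest-neighbour upsampling (parameter-free) ----------------------

up2_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
  io <- seq(1L, 2L * d[1], 2L); ie <- io + 1L
  jo <- seq(1L, 2L * d[2], 2L); je <- jo + 1L
  y[io, jo, , ] <- x; y[io, je, , ] <- x
  y[ie, jo, , ] <- x; y[ie, je, , ] <- x
  y
}

up2_bwd <- function(dy) {
  d <- dim(dy)
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  dy[io, jo, , , drop = FALSE] + dy[io, je, , , drop = FALSE] +
    dy[ie, jo, , , drop = FALSE] + dy[ie, je, , , drop = FALSE]
}

# ---- channel concatenation (channel-last makes this a vector c()) -----------

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[1:3], db[1:3]))
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

split_ch <- function(x, c1) {
  d <- dim(x)
  list(x[, , , seq_len(c1), drop = FALSE],
       x[, , , (c1 + 1L):d[4], drop = FALSE])
}
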