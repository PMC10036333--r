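# Building blocks for the denoising network. Tensors are numeric arrays
# with dim c(H, W, N, C): each channel of each image is a contiguous
# H x W block, which keeps channel-wise statistics and the C++ kernels
# cache-friendly. The heavy elementwise/channel ops live in src/.

nn_tensor <- function(x, H, W, N, C) {
  dim(x) <- c(H, W, N, C)
  x
}

# He-initialized convolution parameters: weight is a (k*k*Cin) x Cout
# matrix matching the im2col layout in src/conv_ops.cpp.
conv_init <- function(cin, cout, k = 3) {
  fan_in <- k * k * cin
  list(w = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
       b = numeric(cout), k = k)
}

# --- batch normalization ---------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_forward <- function(x, p, train) {
  out <- bn_fwd(x, dim(x), p$gamma, p$beta, p$rmean, p$rvar, train, BN_EPS)
  cache <- if (train) list(xhat = out$xhat, invstd = out$invstd,
                           dims = dim(x)) else NULL
  stats <- if (train) list(mu = out$mu, v = out$v) else NULL
  list(y = out$y, cache = cache, stats = stats)
}

bn_backward <- function(dy, p, cache) {
  out <- bn_bwd(dy, cache$dims, p$gamma, cache$xhat, cache$invstd)
  list(dx = out$dx, dgamma = out$dgamma, dbeta = out$dbeta)
}

# --- spatial ops -----------------------------------------------------------

maxpool2 <- function(x) {
  out <- maxpool_fwd(x, dim(x))
  list(y = out$y, which = out$which, dims = dim(x))
}

maxpool2_backward <- function(dy, cache) {
  maxpool_bwd(dy, cache$which, cache$dims)
}

upsample2 <- function(x) upsample_fwd(x, dim(x))

upsample2_backward <- function(dy) upsample_bwd(dy, dim(dy))

# Plain convolution wrapper (tests and one-off use).
conv_apply <- function(x, w, b = numeric(ncol(w)), k = 3L) {
  conv_fwd(x, dim(x), NULL, 0L, w, b, as.integer(k), keep_col = FALSE, reuse = NULL)$y
}

# --- activations and dropout ----------------------------------------------

softplus <- function(x) {
  y <- x
  pos <- x > 0
  y[pos] <- x[pos] + log1p(exp(-x[pos]))
  y[!pos] <- log1p(exp(x[!pos]))
  y
}

softplus_grad <- function(x) 1 / (1 + exp(-x))

dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array(rbinom(length(x), 1L, 1 - rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

# --- Adam optimizer --------------------------------------------------------

adam_step <- function(value, grad, m, v, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad * grad
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  list(value = value - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}
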