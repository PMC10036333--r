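# Reference hot-pixel removers and the Gaussian smoothing baseline.

# Replicate-pad a matrix by r pixels on every side.
pad_replicate <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq_len(H + 2L * r) - r, 1L), H)
  ci <- pmin(pmax(seq_len(W + 2L * r) - r, 1L), W)
  img[ri, ci, drop = FALSE]
}

#' Gaussian smoothing baseline
#'
#' Separable 2D Gaussian convolution with a kernel normalized to sum 1 and
#' replicate-padded borders. Defaults follow the reference configuration
#' (5x5 kernel, sigma 0.8); a sigma-1 variant is reachable through the
#' arguments.
#'
#' @param img numeric matrix.
#' @param kernel_size odd window size.
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(img, kernel_size = 5, sigma = 0.8) {
  stopifnot(is.matrix(img))
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd", call. = FALSE)
  r <- (kernel_size - 1L) / 2L
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(img, r)
  H <- nrow(img); W <- ncol(img)
  # horizontal pass on padded rows, then vertical pass
  tmp <- matrix(0, H + 2L * r, W)
  for (u in seq_len(kernel_size))
    tmp <- tmp + k[u] * p[, u:(u + W - 1L), drop = FALSE]
  out <- matrix(0, H, W)
  for (u in seq_len(kernel_size))
    out <- out + k[u] * tmp[u:(u + H - 1L), , drop = FALSE]
  out
}

# The 8 neighbor matrices of every pixel under replicate padding, as a
# (H*W) x 8 matrix. Direction order: relative offsets
# (-1,-1),(-1,0),(-1,1),(0,-1),(0,1),(1,-1),(1,0),(1,1) in (row, col).
.neighbor_offsets <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

.neighbor_stack <- function(img) {
  H <- nrow(img); W <- ncol(img)
  p <- pad_replicate(img, 1L)
  out <- matrix(0, H * W, 8L)
  for (i in 1:8) {
    dr <- .neighbor_offsets[i, 1L]; dc <- .neighbor_offsets[i, 2L]
    out[, i] <- as.numeric(p[(2L + dr):(H + 1L + dr),
                             (2L + dc):(W + 1L + dc), drop = FALSE])
  }
  out
}

#' Neighbor-based threshold hot-pixel removal (NTHM)
#'
#' Classic single-pass rule: a pixel whose value exceeds the maximum of its
#' 8 in-bounds neighbors by more than `threshold` is clipped to that
#' neighbor maximum. Adjacent hot pixels shield each other and survive a
#' single pass, which is the method's documented weakness.
#'
#' @param raw numeric count matrix.
#' @param threshold positive scalar in count units.
#' @return filtered matrix.
#' @export
nthm <- function(raw, threshold = 50) {
  stopifnot(is.matrix(raw))
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  H <- nrow(raw); W <- ncol(raw)
  # -Inf padding so replicated borders never let a pixel be its own neighbor
  p <- matrix(-Inf, H + 2L, W + 2L)
  p[2:(H + 1L), 2:(W + 1L)] <- raw
  nb_max <- matrix(-Inf, H, W)
  for (i in 1:8) {
    dr <- .neighbor_offsets[i, 1L]; dc <- .neighbor_offsets[i, 2L]
    nb_max <- pmax(nb_max, p[(2L + dr):(H + 1L + dr),
                             (2L + dc):(W + 1L + dc), drop = FALSE])
  }
  hit <- raw > nb_max + threshold
  out <- raw
  out[hit] <- nb_max[hit]
  out
}

#' Median-based threshold hot-pixel removal (MTHM)
#'
#' A pixel whose excess over the median of its `window` x `window`
#' neighborhood (center included, replicate-padded borders) exceeds
#' `threshold` is replaced by that median. Not locally adaptive: a bright
#' but genuine pixel on a tissue/background border whose window median is
#' background-level can be removed erroneously.
#'
#' @param raw numeric count matrix.
#' @param threshold positive scalar in count units.
#' @param window odd window size (default 3).
#' @return filtered matrix.
#' @export
mthm <- function(raw, threshold = 50, window = 3) {
  stopifnot(is.matrix(raw))
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  med <- window_median(raw, window)
  hit <- raw - med > threshold
  out <- raw
  out[hit] <- med[hit]
  out
}

# Full-window running median with replicate padding (window odd).
window_median <- function(img, window = 3) {
  H <- nrow(img); W <- ncol(img)
  r <- (window - 1L) / 2L
  p <- pad_replicate(img, r)
  cols <- matrix(0, H * W, window * window)
  k <- 0L
  for (dc in -r:r) for (dr in -r:r) {
    k <- k + 1L
    cols[, k] <- as.numeric(p[(1L + r + dr):(H + r + dr),
                              (1L + r + dc):(W + r + dc), drop = FALSE])
  }
  matrix(row_medians(cols), H, W)
}
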