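# DeepSNiF: self-supervised shot-noise filtering.
#
# The hot-pixel-removed image is its own training target: a few pixels per
# patch are masked (replaced by random neighbors) and the network learns
# to predict their original values from context. Under a Poisson noise
# model the maximum-likelihood-consistent data term is the I-divergence,
# evaluated on the masked pixels only; a Hessian-norm regularizer on the
# whole prediction encodes the continuity of biological structures.

.rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

.orientations <- function(m) {
  r1 <- .rot90(m); r2 <- .rot90(r1); r3 <- .rot90(r2)
  fl <- m[nrow(m):1, , drop = FALSE]
  f1 <- .rot90(fl); f2 <- .rot90(f1); f3 <- .rot90(f2)
  list(m, r1, r2, r3, fl, f1, f2, f3)
}

#' Extract, filter, augment and split training patches
#'
#' Tiles each image into non-overlapping `patch_size` x `patch_size`
#' patches (partial border tiles are dropped), discards patches whose
#' zero-pixel fraction exceeds `rho` (background-dominated regions would
#' dominate training otherwise), augments the survivors by the three 90
#' degree rotations and the mirrored versions of all four orientations
#' (8 total), percentile-normalizes everything with one shared scale, and
#' assigns a seeded 85/15 train/validation split.
#'
#' @param images list of numeric matrices (hot-pixel-removed counts).
#' @param rho maximum tolerated zero-pixel fraction in `(0, 1]`.
#' @param percentile normalization percentile (99.9--99.999 typical).
#' @param patch_size patch side (default 64).
#' @param train_frac training fraction of the augmented set (default 0.85).
#' @param seed seed for the split shuffle (and the `max_base` subsample).
#' @param max_base optional cap on the number of base tiles kept after
#'   filtering (seeded random subsample); useful to bound training cost.
#' @param channel_id label stored in the normalization record.
#' @return `patch_set`: list with `patches` (array `patch_size x
#'   patch_size x P`, normalized), `split` (character "train"/"val"),
#'   `record`, `n_base` (pre-augmentation count).
#' @export
extract_patches <- function(images, rho = 0.8, percentile = 99.99,
                            patch_size = 64L, train_frac = 0.85,
                            seed = 1, max_base = Inf, channel_id = NULL) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(rho > 0, rho <= 1)
  base <- list()
  for (img in images) {
    H <- nrow(img); W <- ncol(img)
    for (bi in seq_len(H %/% patch_size)) {
      for (bj in seq_len(W %/% patch_size)) {
        p <- img[((bi - 1) * patch_size + 1):(bi * patch_size),
                 ((bj - 1) * patch_size + 1):(bj * patch_size)]
        if (mean(p == 0) <= rho) base[[length(base) + 1L]] <- p
      }
    }
  }
  if (length(base) == 0)
    stop("no patches passed the background filter: empty training set",
         call. = FALSE)
  set.seed(seed)
  if (length(base) > max_base)
    base <- base[sort(sample.int(length(base), max_base))]
  norm <- percentile_normalize(
    do.call(cbind, base), percentile = percentile, channel_id = channel_id)
  aug <- list()
  for (p in base) {
    p <- p / norm$record$scale_value
    aug <- c(aug, .orientations(p))
  }
  n <- length(aug)
  if (n < 5000)
    warning("fewer than 5000 patches; at least 5000 are recommended ",
            "for good generalization", call. = FALSE)
  patches <- array(unlist(aug), c(patch_size, patch_size, n))
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- max(1L, min(n - 1L, round(train_frac * n)))
  split <- rep("val", n)
  split[ord[seq_len(n_train)]] <- "train"
  structure(list(patches = patches, split = split, record = norm$record,
                 n_base = length(base), patch_size = patch_size),
            class = "patch_set")
}

#' Blind-spot masking with stratified sampling
#'
#' Masks `round(rate * npixels)` pixels of a patch, one per stratum of an
#' even grid partition (so masked pixels are spread over the patch rather
#' than clumped), and replaces each by a uniformly drawn neighbor from its
#' 5x5 window excluding the center. At the default 0.2% rate a 64x64 patch
#' gets exactly 8 masked pixels.
#'
#' @param patch numeric matrix.
#' @param rate masking rate in `(0, 0.1)`.
#' @return list with `masked` (patch with replacements), `plan` holding
#'   the logical `mask`, per-pixel replacement `offsets` and the rate.
#' @export
make_mask <- function(patch, rate = 0.002) {
  stopifnot(rate > 0, rate < 0.1)
  H <- nrow(patch); W <- ncol(patch)
  k <- max(1L, round(rate * H * W))
  # stratum grid: divisor pair of k with aspect closest to the patch's
  divs <- which(k %% seq_len(k) == 0)
  pairs <- cbind(divs, k %/% divs)
  best <- which.min(abs(log(pairs[, 1] / pairs[, 2]) - log(H / W)))
  gr <- pairs[best, 1]; gc <- pairs[best, 2]
  row_edges <- round(seq(0, H, length.out = gr + 1))
  col_edges <- round(seq(0, W, length.out = gc + 1))
  mask <- matrix(FALSE, H, W)
  offsets <- matrix(0L, k, 2)
  masked <- patch
  i <- 0L
  for (a in seq_len(gr)) {
    for (b in seq_len(gc)) {
      i <- i + 1L
      r <- sample((row_edges[a] + 1L):row_edges[a + 1L], 1L)
      c <- sample((col_edges[b] + 1L):col_edges[b + 1L], 1L)
      repeat {
        dr <- sample(-2:2, 1L); dc <- sample(-2:2, 1L)
        if ((dr != 0L || dc != 0L) && r + dr >= 1L && r + dr <= H &&
            c + dc >= 1L && c + dc <= W) break
      }
      mask[r, c] <- TRUE
      offsets[i, ] <- c(dr, dc)
      masked[r, c] <- patch[r + dr, c + dc]
    }
  }
  list(masked = masked, plan = list(mask = mask, offsets = offsets,
                                    rate = rate))
}

#' I-divergence data term on masked pixels
#'
#' `sum_p M_p * [r_p log(r_p / F_p) - r_p + F_p] / sum_p M_p` with the
#' convention `0 * log(0/F) = 0`. This is the Poisson maximum-likelihood
#' loss up to constants; it ignores every unmasked pixel.
#'
#' @param pred strictly positive prediction.
#' @param target non-negative target (same shape).
#' @param M logical/0-1 mask (same shape) selecting the masked pixels.
#' @return scalar loss.
#' @export
i_divergence <- function(pred, target, M) {
  if (any(pred <= 0)) stop("prediction must be strictly positive",
                           call. = FALSE)
  m <- as.logical(M)
  r <- as.numeric(target)[m]
  f <- as.numeric(pred)[m]
  if (length(r) == 0) return(0)
  term <- ifelse(r > 0, r * log(r / pmax(f, 1e-8)), 0) - r + f
  sum(term) / length(r)
}

#' Hessian-norm regularizer
#'
#' Per-pixel second derivatives by central finite differences
#' (`f_xx`, `f_yy` and the cross term `f_xy`), combined as
#' `|f_xx| + |f_yy| + 2 |f_xy|` and averaged over interior pixels (the
#' one-pixel border, where central differences are undefined, is
#' excluded). Batched arrays average over all slices.
#'
#' @param pred numeric matrix, or 3D/4D array of stacked images.
#' @return scalar `>= 0`; exactly 0 for constant and planar images.
#' @export
hessian_norm <- function(pred) {
  if (is.matrix(pred)) return(.hessian_norm_mat(pred))
  d <- dim(pred)
  slices <- prod(d[-(1:2)])
  tot <- 0
  flat <- array(pred, c(d[1], d[2], slices))
  for (s in seq_len(slices)) tot <- tot + .hessian_norm_mat(flat[, , s])
  tot / slices
}

.hessian_norm_mat <- function(f) {
  H <- nrow(f); W <- ncol(f)
  if (H < 3 || W < 3) return(0)
  i <- 2:(H - 1); j <- 2:(W - 1)
  fxx <- f[i + 1, j] - 2 * f[i, j] + f[i - 1, j]
  fyy <- f[i, j + 1] - 2 * f[i, j] + f[i, j - 1]
  fxy <- (f[i + 1, j + 1] - f[i + 1, j - 1] - f[i - 1, j + 1] +
            f[i - 1, j - 1]) / 4
  mean(abs(fxx) + abs(fyy) + 2 * abs(fxy))
}

# Subgradient of hessian_norm for a single matrix.
.hessian_grad_mat <- function(f) {
  H <- nrow(f); W <- ncol(f)
  g <- matrix(0, H, W)
  if (H < 3 || W < 3) return(g)
  i <- 2:(H - 1); j <- 2:(W - 1)
  n_int <- (H - 2) * (W - 2)
  sxx <- sign(f[i + 1, j] - 2 * f[i, j] + f[i - 1, j])
  syy <- sign(f[i, j + 1] - 2 * f[i, j] + f[i, j - 1])
  sxy <- sign(f[i + 1, j + 1] - f[i + 1, j - 1] - f[i - 1, j + 1] +
                f[i - 1, j - 1])
  # adjoint of the three stencils
  g[i + 1, j] <- g[i + 1, j] + sxx
  g[i - 1, j] <- g[i - 1, j] + sxx
  g[i, j] <- g[i, j] - 2 * sxx
  g[i, j + 1] <- g[i, j + 1] + syy
  g[i, j - 1] <- g[i, j - 1] + syy
  g[i, j] <- g[i, j] - 2 * syy
  g[i + 1, j + 1] <- g[i + 1, j + 1] + 0.5 * sxy
  g[i - 1, j - 1] <- g[i - 1, j - 1] + 0.5 * sxy
  g[i + 1, j - 1] <- g[i + 1, j - 1] - 0.5 * sxy
  g[i - 1, j + 1] <- g[i - 1, j + 1] - 0.5 * sxy
  g / n_int
}

#' Combined DeepSNiF loss
#'
#' `i_divergence + lambda_h * hessian_norm`. With `lambda_h = 0` this is
#' the unregularized blind-spot loss (the "no regularization" variant).
#'
#' @inheritParams i_divergence
#' @param lambda_h non-negative regularization weight (default 3e-6).
#' @return scalar loss.
#' @export
total_loss <- function(pred, target, M, lambda_h = 3e-6) {
  i_divergence(pred, target, M) + lambda_h * hessian_norm(pred)
}

# Loss + gradient for a training batch given as (H, W, N, 1) arrays.
.batch_loss_grad <- function(pred, target, M, lambda_h) {
  d <- dim(pred)
  m <- M > 0
  n_mask <- sum(m)
  f <- pred[m]
  r <- target[m]
  idiv <- if (n_mask == 0) 0 else
    sum(ifelse(r > 0, r * log(r / pmax(f, 1e-8)), 0) - r + f) / n_mask
  dpred <- array(0, d)
  if (n_mask > 0) dpred[m] <- (1 - r / pmax(f, 1e-8)) / n_mask
  hess <- 0
  if (lambda_h > 0) {
    N <- d[3]
    for (n in seq_len(N)) {
      fm <- matrix(pred[, , n, 1], d[1], d[2])
      hess <- hess + .hessian_norm_mat(fm)
      dpred[, , n, 1] <- dpred[, , n, 1] +
        lambda_h * .hessian_grad_mat(fm) / N
    }
    hess <- hess / N
  }
  list(loss = idiv + lambda_h * hess, dpred = dpred)
}

#' Train the self-supervised denoiser
#'
#' Every epoch the masks are re-drawn per patch (maximizing pixel
#' coverage), the combined loss is minimized with Adam on the training
#' split and evaluated on the validation split (network in inference mode,
#' regularizer included), and the learning rate is multiplied by
#' `lr_decay` when the validation loss has not improved for `lr_patience`
#' epochs. Fully deterministic given `seed`.
#'
#' @param patchset a `patch_set` from [extract_patches()].
#' @param base_filters encoder width at full resolution (reference
#'   configuration 32; 8 gives a small-capacity desk model).
#' @param epochs,batch_size,lr,lr_decay,lr_patience optimizer schedule
#'   (reference values 200 / 128 / 0.001 / 0.6 / 20).
#' @param lambda_hessian regularization weight (default 3e-6; 0 disables).
#' @param masking_rate blind-spot masking rate (default 0.002).
#' @param seed integer seed for weights, masks and shuffling.
#' @param verbose print per-epoch losses.
#' @return `trained_denoiser`: list with `net`, the normalization
#'   `record`, `history` (per-epoch train/validation loss, learning rate)
#'   and `config`.
#' @export
deepsnif_train <- function(patchset, base_filters = 32L, epochs = 200L,
                           batch_size = 128L, lr = 0.001, lr_decay = 0.6,
                           lr_patience = 20L, lambda_hessian = 3e-6,
                           masking_rate = 0.002, seed = 1L,
                           verbose = FALSE) {
  stopifnot(inherits(patchset, "patch_set"))
  ps <- patchset$patch_size
  idx_train <- which(patchset$split == "train")
  idx_val <- which(patchset$split == "val")
  if (length(idx_train) == 0) stop("empty training split", call. = FALSE)
  set.seed(seed)
  net <- net_init(base_filters = as.integer(base_filters))
  opt <- list(m = lapply(net$params, function(p) p * 0),
              v = lapply(net$params, function(p) p * 0), t = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  best_val <- Inf
  wait <- 0L
  cur_lr <- lr

  run_batch <- function(ids, train) {
    n <- length(ids)
    x <- array(0, c(ps, ps, n, 1))
    tgt <- array(0, c(ps, ps, n, 1))
    msk <- array(FALSE, c(ps, ps, n, 1))
    for (b in seq_len(n)) {
      p <- patchset$patches[, , ids[b]]
      mm <- make_mask(p, rate = masking_rate)
      x[, , b, 1] <- mm$masked
      tgt[, , b, 1] <- p
      msk[, , b, 1] <- mm$plan$mask
    }
    fw <- net_forward(net, x, train = train, keep_cache = train)
    lg <- .batch_loss_grad(fw$pred, tgt, msk, lambda_hessian)
    list(fw = fw, loss = lg$loss, dpred = lg$dpred)
  }

  for (ep in seq_len(epochs)) {
    ord <- sample(idx_train)
    n_batches <- ceiling(length(ord) / batch_size)
    ep_loss <- 0
    for (bi in seq_len(n_batches)) {
      ids <- ord[((bi - 1) * batch_size + 1):min(bi * batch_size,
                                                 length(ord))]
      rb <- run_batch(ids, train = TRUE)
      if (!is.finite(rb$loss))
        stop("divergent loss at epoch ", ep, " (non-finite); ",
             "lower the learning rate", call. = FALSE)
      ep_loss <- ep_loss + rb$loss * length(ids)
      bw <- net_backward(net, rb$fw, rb$dpred)
      net <- net_update_bn(net, bw$bn_stats)
      opt$t <- opt$t + 1L
      for (nm in names(net$params)) {
        g <- bw$grads[[nm]]
        if (is.null(g)) next
        st <- adam_step(net$params[[nm]], g, opt$m[[nm]], opt$v[[nm]],
                        opt$t, cur_lr)
        net$params[[nm]] <- st$value
        opt$m[[nm]] <- st$m
        opt$v[[nm]] <- st$v
      }
    }
    ep_loss <- ep_loss / length(ord)
    val_loss <- if (length(idx_val)) {
      vb <- run_batch(idx_val, train = FALSE)
      vb$loss
    } else ep_loss
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = ep_loss, val_loss = val_loss, lr = cur_lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f  lr %.2g",
                      ep, ep_loss, val_loss, cur_lr))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= lr_patience) {
        cur_lr <- cur_lr * lr_decay
        wait <- 0L
      }
    }
  }
  structure(list(net = net, record = patchset$record, history = history,
                 config = list(base_filters = base_filters, epochs = epochs,
                               batch_size = batch_size, lr = lr,
                               lr_decay = lr_decay,
                               lr_patience = lr_patience,
                               lambda_hessian = lambda_hessian,
                               masking_rate = masking_rate, seed = seed)),
            class = "trained_denoiser")
}

#' Denoise an image with a trained model
#'
#' Pads the image with replicated border pixels so both sides are
#' multiples of 16 (the network's four down-samplings), normalizes by the
#' stored channel scale, runs the network in inference mode, re-scales and
#' crops back to the original shape. The softplus head guarantees a
#' strictly positive output.
#'
#' @param model a `trained_denoiser`.
#' @param img numeric matrix (hot-pixel-removed counts).
#' @return denoised matrix, same shape as `img`, all values `> 0`.
#' @export
deepsnif_predict <- function(model, img) {
  stopifnot(inherits(model, "trained_denoiser"), is.matrix(img))
  H <- nrow(img); W <- ncol(img)
  if (H == 0 || W == 0) stop("empty image", call. = FALSE)
  Hp <- 16L * ceiling(H / 16L)
  Wp <- 16L * ceiling(W / 16L)
  ri <- pmin(seq_len(Hp), H)
  ci <- pmin(seq_len(Wp), W)
  padded <- img[ri, ci, drop = FALSE] / model$record$scale_value
  x <- array(padded, c(Hp, Wp, 1, 1))
  fw <- net_forward(model$net, x, train = FALSE, keep_cache = FALSE)
  out <- matrix(fw$pred[, , 1, 1], Hp, Wp)[seq_len(H), seq_len(W),
                                           drop = FALSE]
  out * model$record$scale_value
}

#' Save / load a trained denoiser
#'
#' Stored with R's native serialization; the file carries the weights,
#' batch-norm state, normalization record and full training configuration.
#'
#' @param model a `trained_denoiser`.
#' @param path file path (`.rds` suggested).
#' @return `path` / the restored model.
#' @export
deepsnif_save <- function(model, path) {
  stopifnot(inherits(model, "trained_denoiser"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname deepsnif_save
#' @export
deepsnif_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_denoiser"))
    stop("file does not contain a trained_denoiser", call. = FALSE)
  model
}

#' @export
print.trained_denoiser <- function(x, ...) {
  cat(sprintf(
    "trained_denoiser: base_filters %d, %d epoch(s), final val loss %.6g\n",
    x$config$base_filters, nrow(x$history),
    tail(x$history$val_loss, 1)))
  invisible(x)
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf(
    "patch_set: %d patches (%d base x 8 augmentations), %d train / %d val\n",
    dim(x$patches)[3], x$n_base, sum(x$split == "train"),
    sum(x$split == "val")))
  invisible(x)
}
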