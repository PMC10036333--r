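# Independent brute-force reference implementations used as oracles.
# These deliberately use naive loops / formulas so they share no code
# path with the package internals they check.

oracle_rmse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}

oracle_stdb <- function(img, mask) {
  v <- c()
  for (i in seq_along(img)) if (mask[i]) v <- c(v, img[i])
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / length(v))
}

oracle_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

oracle_f1_jaccard <- function(pred, truth) {
  tp <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1
    if (pred[i] && !truth[i]) fp <- fp + 1
    if (!pred[i] && truth[i]) fn <- fn + 1
  }
  c(f1 = 2 * tp / (2 * tp + fp + fn), jaccard = tp / (tp + fp + fn))
}

oracle_idiv <- function(pred, target, M) {
  s <- 0; n <- 0
  for (i in seq_along(pred)) {
    if (M[i]) {
      n <- n + 1
      r <- target[i]; f <- pred[i]
      s <- s + (if (r > 0) r * log(r / f) else 0) - r + f
    }
  }
  s / n
}

oracle_hessian <- function(f) {
  H <- nrow(f); W <- ncol(f)
  tot <- 0; n <- 0
  for (i in 2:(H - 1)) for (j in 2:(W - 1)) {
    fxx <- f[i + 1, j] - 2 * f[i, j] + f[i - 1, j]
    fyy <- f[i, j + 1] - 2 * f[i, j] + f[i, j - 1]
    fxy <- (f[i + 1, j + 1] - f[i + 1, j - 1] - f[i - 1, j + 1] +
              f[i - 1, j - 1]) / 4
    tot <- tot + abs(fxx) + abs(fyy) + 2 * abs(fxy)
    n <- n + 1
  }
  tot / n
}

# Aggregate statistic for one pixel: enumerate the 8 (d_i, Delta_i)
# pairs, stable-sort by Delta (ties by direction index), sum the d of
# the first l.
oracle_t_l <- function(d8, centers, l) {
  delta <- abs(d8 - centers)
  ord <- order(delta)  # stable, ties by index
  sum(d8[ord[seq_len(l)]])
}

# Naive full-window median replacement from a frozen copy.
oracle_median_replace <- function(img, mask) {
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j]) next
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), H)
      jj <- min(max(j + dj, 1), W)
      vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- median(vals)
  }
  out
}

# Naive dense convolution matching the network's layout conventions.
oracle_conv <- function(x, w, b, k) {
  d <- dim(x); r <- (k - 1) / 2; cout <- ncol(w)
  y <- array(0, c(d[1], d[2], d[3], cout))
  for (n in seq_len(d[3])) for (co in seq_len(cout)) {
    for (h in seq_len(d[1])) for (wd in seq_len(d[2])) {
      s <- 0
      for (ci in seq_len(d[4])) for (kc in -r:r) for (kr in -r:r) {
        hh <- h + kr; ww <- wd + kc
        v <- if (hh >= 1 && hh <= d[1] && ww >= 1 && ww <= d[2])
          x[hh, ww, n, ci] else 0
        row <- (kr + r) + k * (kc + r) + k * k * (ci - 1) + 1
        s <- s + v * w[row, co]
      }
      y[h, wd, n, co] <- s + b[co]
    }
  }
  y
}

oracle_conv_grads <- function(x, w, dy, k) {
  d <- dim(x); r <- (k - 1) / 2; cout <- ncol(w)
  dx <- array(0, d); dw <- w * 0; db <- numeric(cout)
  for (n in seq_len(d[3])) for (co in seq_len(cout)) {
    for (h in seq_len(d[1])) for (wd in seq_len(d[2])) {
      g <- dy[h, wd, n, co]
      db[co] <- db[co] + g
      for (ci in seq_len(d[4])) for (kc in -r:r) for (kr in -r:r) {
        hh <- h + kr; ww <- wd + kc
        if (hh >= 1 && hh <= d[1] && ww >= 1 && ww <= d[2]) {
          row <- (kr + r) + k * (kc + r) + k * k * (ci - 1) + 1
          dw[row, co] <- dw[row, co] + x[hh, ww, n, ci] * g
          dx[hh, ww, n, ci] <- dx[hh, ww, n, ci] + w[row, co] * g
        }
      }
    }
  }
  list(dx = dx, dw = dw, db = db)
}
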