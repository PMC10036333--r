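# DIMR: differential intensity map-based restoration.
#
# Hot pixels are local maxima uncorrelated with tissue structure. After
# Anscombe stabilization, the difference between adjacent pixels is close
# to a generalized Gaussian, so an outlier statistic built from the
# neighbor differences separates hot pixels from tissue without any
# user-set intensity threshold.

#' Directional difference maps in the Anscombe domain
#'
#' For each of the 8 neighbor directions of a 3x3 window, computes
#' `d_i(p) = t(p) - t(neighbor_i(p))` with replicate-padded borders.
#' Pixels whose transformed value is below `bg_cutoff` are excluded from
#' the valid mask: they can neither be outlier candidates nor contribute to
#' the robust per-direction centers, but they still serve as neighbors so
#' that differences see the true local context. The center of each
#' direction's distribution is estimated by its median over valid pixels.
#'
#' @param t matrix of Anscombe-transformed intensities, at least 3x3.
#' @param bg_cutoff background cut in the transformed domain (default 4,
#'   the value used for IMC).
#' @return list with `maps` ((H*W) x 8 matrix of differences), `valid_mask`
#'   (logical matrix), `robust_centers` (length-8 medians; `NA` when no
#'   valid pixel exists) and the image dimensions.
#' @export
compute_difference_maps <- function(t, bg_cutoff = 4) {
  stopifnot(is.matrix(t))
  if (nrow(t) < 3 || ncol(t) < 3)
    stop("image must be at least 3x3", call. = FALSE)
  nb <- .neighbor_stack(t)
  maps <- as.numeric(t) - nb
  valid <- t >= bg_cutoff
  centers <- if (any(valid)) {
    apply(maps[as.numeric(valid) > 0, , drop = FALSE], 2, median)
  } else rep(NA_real_, 8)
  structure(list(maps = maps, valid_mask = valid, robust_centers = centers,
                 dim = dim(t), bg_cutoff = bg_cutoff),
            class = "difference_map_set")
}

#' Aggregate minimum-distance difference statistic
#'
#' For every valid pixel, the distances `Delta_i = |d_i - center_i|` are
#' sorted ascending (stable, ties broken by direction index) and the signed
#' differences `d_i` of the `l` entries with smallest `Delta_i` are summed.
#' Normal pixels have several neighbors close to their direction centers,
#' so their sums concentrate near zero; hot pixels exceed all neighbors and
#' land far in the right tail.
#'
#' @param dm a `difference_map_set`.
#' @param l number of closest directions to sum (default 4: at least half
#'   the neighbors of a normal pixel are assumed close to it).
#' @return list with `values` (vector of t_l, one per valid pixel),
#'   `index` (linear pixel indices of the valid pixels) and `l`.
#' @export
aggregate_min_differences <- function(dm, l = 4) {
  stopifnot(inherits(dm, "difference_map_set"))
  if (l < 1 || l > 8) stop("l must lie in [1, 8]", call. = FALSE)
  idx <- which(as.logical(dm$valid_mask))
  if (length(idx) == 0)
    return(list(values = numeric(0), index = integer(0), l = l))
  d <- dm$maps[idx, , drop = FALSE]
  delta <- abs(sweep(d, 2, dm$robust_centers))
  n <- nrow(d)
  # stable per-row ordering: primary key row, secondary key delta; ties in
  # delta fall back to direction (column) order because order() is stable
  row_id <- rep(seq_len(n), times = 8)
  o <- order(row_id, as.numeric(delta))
  sel <- o[(rep(seq_len(n) - 1L, each = l) * 8L) + rep(seq_len(l), times = n)]
  # d and delta share column-major layout, so flattened indices carry over
  vals <- rowSums(matrix(d[sel], ncol = l, byrow = TRUE))
  list(values = vals, index = idx, l = l)
}

#' Gaussian kernel density estimate on a unit-spaced grid
#'
#' Fits a Gaussian-kernel KDE to a sample and evaluates it on an
#' integer-spaced grid spanning `[min - 3h, max + 3h]`. Unit spacing
#' matches the discreteness of count data and lets threshold detection use
#' simple finite differences. The bandwidth is Silverman's rule of thumb
#' floored at the grid spacing: derivatives are read off at unit
#' resolution, so a narrower kernel would expose sampling wiggles as
#' spurious curvature sign changes and trigger false detections.
#'
#' @param values numeric sample of at least 10 points.
#' @param min_bandwidth bandwidth floor (default 1, the grid spacing).
#' @return list of class `kde_curve` with `grid`, `density` and
#'   `bandwidth`, or `NULL` (with a warning) when the sample is too small
#'   or degenerate, in which case detection is skipped for the iteration.
#' @export
fit_kde <- function(values, min_bandwidth = 1) {
  values <- as.numeric(values)
  if (length(values) < 10) {
    warning("fewer than 10 samples: KDE skipped, no outliers flagged")
    return(NULL)
  }
  h <- tryCatch(stats::bw.nrd0(values), error = function(e) 0)
  if (!is.finite(h) || h <= 0) {
    warning("degenerate sample (zero spread): KDE skipped")
    return(NULL)
  }
  h <- max(h, min_bandwidth)
  lo <- floor(min(values) - 3 * h)
  hi <- ceiling(max(values) + 3 * h)
  n <- as.integer(hi - lo) + 1L
  fit <- density(values, bw = h, kernel = "gaussian", from = lo, to = hi,
                 n = n)
  structure(list(grid = fit$x, density = fit$y, bandwidth = h),
            class = "kde_curve")
}

#' Locate the outlier threshold on a fitted density curve
#'
#' Scans rightward from the global mode and returns the first grid point
#' at which either the first derivative has vanished (the distribution has
#' ended) or the curvature changes sign from convex to concave (a separate
#' right-tail bump begins). Derivatives use central finite differences on
#' the unit-spaced grid. Returns `Inf` when no point qualifies, the
#' "nothing detected" sentinel.
#'
#' @param curve a `kde_curve`.
#' @param dx grid spacing (1 for count data).
#' @param eps_deriv_frac "derivative has vanished" tolerance, as a fraction
#'   of the peak density (default 1e-6).
#' @return scalar threshold `x_T` (possibly `Inf`).
#' @export
find_threshold <- function(curve, dx = 1, eps_deriv_frac = 1e-6) {
  stopifnot(inherits(curve, "kde_curve"))
  g <- curve$density
  x <- curve$grid
  n <- length(g)
  if (n < 3) return(Inf)
  mode_i <- which.max(g)
  eps <- eps_deriv_frac * max(g)
  for (i in seq(max(mode_i + 1L, 2L), n - 1L)) {
    d1 <- (g[i + 1L] - g[i - 1L]) / (2 * dx)
    if (abs(d1) <= eps) return(x[i])
    d2_here <- (g[i + 1L] - 2 * g[i] + g[i - 1L]) / dx^2
    d2_prev <- if (i >= 3L)
      (g[i] - 2 * g[i - 1L] + g[i - 2L]) / dx^2 else NA_real_
    if (!is.na(d2_prev) && i - 1L > mode_i && d2_prev >= 0 && d2_here <= 0)
      return(x[i])
  }
  Inf
}

#' Replace flagged pixels by their 3x3 neighborhood median
#'
#' The median is taken over the full 3x3 window (center included,
#' replicate-padded borders) of the *pre-replacement* image, so the result
#' does not depend on the order in which flagged pixels are visited.
#'
#' @param img numeric matrix.
#' @param mask logical matrix of the same shape; `TRUE` pixels are replaced.
#' @return matrix with flagged pixels replaced.
#' @export
median_replace <- function(img, mask) {
  stopifnot(is.matrix(img), identical(dim(img), dim(mask)))
  idx <- which(as.logical(mask))
  if (length(idx) == 0) return(img)
  p <- pad_replicate(img, 1L)
  H <- nrow(img)
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  win <- matrix(0, length(idx), 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    win[, k] <- p[cbind(rr + 1L + dr, cc + 1L + dc)]
  }
  out <- img
  out[idx] <- row_medians(win)
  out
}

#' DIMR: adaptive hot-pixel removal
#'
#' Per iteration: Anscombe-transform the current image, build the 8
#' directional difference maps with the background cut, form the aggregate
#' statistic `t_l`, fit a KDE and locate the detection threshold `x_T`,
#' flag valid pixels with `t_l > x_T`, and replace them with their 3x3
#' median. Iteration stops early as soon as nothing is flagged. Detection
#' and replacement happen entirely in the Anscombe domain; only the final
#' image is mapped back through the algebraic inverse, so returned values
#' are real (use `round_output = TRUE` to re-round to integer counts).
#'
#' @param raw matrix of non-negative ion counts (>= 3x3).
#' @param n_iter maximum number of iterations (default 3, which removes
#'   single hot pixels and small clusters adequately).
#' @param l neighbor count of the aggregate statistic (default 4).
#' @param bg_cutoff background cut in the Anscombe domain (default 4).
#' @param eps_deriv_frac threshold-detection tolerance, see
#'   [find_threshold()].
#' @param round_output round the restored image back to integers.
#' @return list of class `dimr_result` with `pixels` (restored image) and
#'   `report`, a `hot_pixel_report` carrying per-iteration logical masks,
#'   thresholds, flagged counts, the total flagged mask/count/fraction and
#'   `iterations_run`.
#' @export
dimr <- function(raw, n_iter = 3, l = 4, bg_cutoff = 4,
                 eps_deriv_frac = 1e-6, round_output = FALSE) {
  stopifnot(is.matrix(raw))
  t_img <- anscombe_forward(raw)
  masks <- list(); thresholds <- numeric(0); flagged <- integer(0)
  total_mask <- matrix(FALSE, nrow(raw), ncol(raw))
  iterations_run <- 0L
  for (it in seq_len(n_iter)) {
    iterations_run <- it
    dm <- compute_difference_maps(t_img, bg_cutoff = bg_cutoff)
    agg <- aggregate_min_differences(dm, l = l)
    mask <- matrix(FALSE, nrow(raw), ncol(raw))
    x_t <- Inf
    if (length(agg$values) >= 10) {
      curve <- withCallingHandlers(
        fit_kde(agg$values),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!is.null(curve)) {
        x_t <- find_threshold(curve, dx = 1, eps_deriv_frac = eps_deriv_frac)
        mask[agg$index[agg$values > x_t]] <- TRUE
      }
    }
    masks[[it]] <- mask
    thresholds[it] <- x_t
    flagged[it] <- sum(mask)
    if (flagged[it] == 0L) break
    total_mask <- total_mask | mask
    t_img <- median_replace(t_img, mask)
  }
  report <- structure(
    list(masks = masks, thresholds = thresholds, flagged = flagged,
         total_mask = total_mask, total_flagged = sum(total_mask),
         fraction_flagged = sum(total_mask) / length(raw),
         iterations_run = iterations_run),
    class = "hot_pixel_report")
  out <- anscombe_inverse(t_img)
  out[out < 0] <- 0
  if (round_output) out <- round(out)
  structure(list(pixels = out, report = report), class = "dimr_result")
}

#' @export
print.hot_pixel_report <- function(x, ...) {
  cat(sprintf(
    "hot_pixel_report: %d iteration(s), %d pixel(s) flagged (%.4f%%)\n",
    x$iterations_run, x$total_flagged, 100 * x$fraction_flagged))
  for (i in seq_along(x$flagged))
    cat(sprintf("  iter %d: x_T = %s, flagged = %d\n", i,
                format(x$thresholds[i], digits = 5), x$flagged[i]))
  invisible(x)
}

#' @export
print.dimr_result <- function(x, ...) {
  cat("dimr_result\n")
  print(x$report)
  invisible(x)
}
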