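# Synthetic IMC image generator: structured clean intensity fields,
# Poisson shot noise, and injected hot pixels / small hot clusters with
# ground-truth masks. Stands in for high-SNR reference imagery when
# benchmarking the pipeline.

#' Simulation configuration
#'
#' @param size image side length in pixels (square images).
#' @param kind structure model: `"blobs"` (cell-like anisotropic Gaussian
#'   spots), `"filaments"` (stroma-like smoothed random-walk curves) or
#'   `"mixed"` (both).
#' @param lambda_fg target mean clean intensity (counts) over the
#'   foreground mask.
#' @param lambda_bg background intensity in counts (`< lambda_fg`).
#' @param hot_pixel_density fraction of pixels receiving a single hot
#'   pixel, in `[0, 0.05]`.
#' @param hot_cluster_density fraction of pixels seeding a small hot
#'   cluster, in `[0, 0.05]`.
#' @param cluster_size_range integer range of connected pixels per cluster
#'   (default 2--4, "several consecutive pixels").
#' @param hot_factor_range hot-pixel amplitude factors: the injected value
#'   is `max(local 3x3 max, lambda_fg)` times a uniform draw from this
#'   range.
#' @param n_blobs,n_filaments structure counts; defaults scale with area.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(size = 256, kind = c("blobs", "filaments", "mixed"),
                       lambda_fg = 20, lambda_bg = 1,
                       hot_pixel_density = 0.01, hot_cluster_density = 0,
                       cluster_size_range = c(2L, 4L),
                       hot_factor_range = c(5, 20),
                       n_blobs = NULL, n_filaments = NULL) {
  kind <- match.arg(kind)
  stopifnot(lambda_fg > lambda_bg, lambda_bg >= 0,
            hot_pixel_density >= 0, hot_pixel_density <= 0.05,
            hot_cluster_density >= 0, hot_cluster_density <= 0.05,
            size >= 16)
  if (is.null(n_blobs)) n_blobs <- max(8L, round(60 * (size / 256)^2))
  if (is.null(n_filaments)) n_filaments <- max(2L, round(6 * (size / 256)^2))
  structure(list(size = size, kind = kind, lambda_fg = lambda_fg,
                 lambda_bg = lambda_bg,
                 hot_pixel_density = hot_pixel_density,
                 hot_cluster_density = hot_cluster_density,
                 cluster_size_range = as.integer(cluster_size_range),
                 hot_factor_range = hot_factor_range,
                 n_blobs = n_blobs, n_filaments = n_filaments),
            class = "sim_config")
}

.blob_field <- function(size, n_blobs) {
  field <- matrix(0, size, size)
  xs <- matrix(rep(seq_len(size), size), size)
  ys <- t(xs)
  for (b in seq_len(n_blobs)) {
    cx <- runif(1, 1, size); cy <- runif(1, 1, size)
    s1 <- runif(1, 2, 6); s2 <- s1 * runif(1, 0.4, 1)
    th <- runif(1, 0, pi); amp <- runif(1, 0.4, 1)
    dx <- xs - cx; dy <- ys - cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    field <- field + amp * exp(-(u^2 / (2 * s1^2) + v^2 / (2 * s2^2)))
  }
  field
}

.filament_field <- function(size, n_filaments) {
  canvas <- matrix(0, size, size)
  for (f in seq_len(n_filaments)) {
    x <- runif(1, 1, size); y <- runif(1, 1, size)
    th <- runif(1, 0, 2 * pi)
    steps <- round(size * runif(1, 0.8, 2))
    for (s in seq_len(steps)) {
      th <- th + rnorm(1, 0, 0.25)
      x <- x + cos(th); y <- y + sin(th)
      xi <- round(x); yi <- round(y)
      if (xi >= 1 && xi <= size && yi >= 1 && yi <= size)
        canvas[xi, yi] <- canvas[xi, yi] + 1
    }
  }
  gaussian_smooth(canvas, kernel_size = 7, sigma = 1.3)
}

#' Generate a clean structured intensity field with masks
#'
#' Builds the structure field, then scales it so that the mean clean
#' intensity over the foreground mask equals `lambda_fg` on a base of
#' `lambda_bg`, where the foreground mask is itself defined by thresholding
#' the noiseless field at `(lambda_fg + lambda_bg) / 2` (solved by a short
#' fixed-point iteration since the mask depends on the scaling).
#'
#' @param cfg a `sim_config`.
#' @return list with `clean` (matrix), `fg_mask`, `bg_mask`.
#' @export
generate_clean <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  size <- cfg$size
  s <- switch(cfg$kind,
    blobs = .blob_field(size, cfg$n_blobs),
    filaments = .filament_field(size, cfg$n_filaments),
    mixed = .blob_field(size, cfg$n_blobs) +
      .filament_field(size, cfg$n_filaments))
  if (max(s) <= 0)
    return(list(clean = matrix(cfg$lambda_bg, size, size),
                fg_mask = matrix(FALSE, size, size),
                bg_mask = matrix(TRUE, size, size)))
  s <- s / max(s)
  span <- cfg$lambda_fg - cfg$lambda_bg
  # fixed point: fg = {pixels above the midpoint threshold after scaling}
  fg <- s > 0.5
  for (i in 1:20) {
    m <- mean(s[fg])
    a <- span / m
    fg_new <- cfg$lambda_bg + a * s >= (cfg$lambda_fg + cfg$lambda_bg) / 2
    if (identical(fg_new, fg)) break
    fg <- fg_new
    if (!any(fg)) fg <- s >= max(s) / 2
  }
  clean <- cfg$lambda_bg + (span / mean(s[fg])) * s
  list(clean = clean, fg_mask = fg, bg_mask = !fg)
}

#' Poisson shot noise
#'
#' Independent Poisson draw per pixel with mean equal to the clean value.
#'
#' @param clean non-negative numeric matrix.
#' @return integer-valued count matrix of the same shape.
#' @export
add_shot_noise <- function(clean) {
  stopifnot(all(clean >= 0))
  matrix(rpois(length(clean), as.numeric(clean)), nrow(clean), ncol(clean))
}

#' Inject hot pixels and small hot clusters
#'
#' Single-pixel sites are drawn at `hot_pixel_density`; cluster seeds at
#' `hot_cluster_density` and grown to 2--4 connected pixels. Every injected
#' value is `max(pre-injection 3x3 neighborhood max, lambda_fg)` times a
#' uniform factor (default 5--20), rounded, so each hot pixel strictly
#' exceeds its original neighborhood. Overlapping sites are resolved by
#' union; the returned mask records every altered pixel.
#'
#' @param img count matrix (typically the shot-noise image).
#' @param cfg a `sim_config`.
#' @return list with `pixels` (image with hot pixels) and `hot_mask`.
#' @export
add_hot_pixels <- function(img, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  H <- nrow(img); W <- ncol(img); npix <- H * W
  hot_mask <- matrix(FALSE, H, W)
  sites <- integer(0)
  n_single <- rbinom(1, npix, cfg$hot_pixel_density)
  if (n_single > 0) sites <- sample.int(npix, n_single)
  n_clust <- rbinom(1, npix, cfg$hot_cluster_density)
  if (n_clust > 0) {
    seeds <- sample.int(npix, n_clust)
    for (s in seeds) {
      target <- sample(seq(cfg$cluster_size_range[1],
                           cfg$cluster_size_range[2]), 1)
      members <- s
      while (length(members) < target) {
        grow_from <- members[sample.int(length(members), 1)]
        r <- ((grow_from - 1L) %% H) + 1L
        c <- ((grow_from - 1L) %/% H) + 1L
        k <- sample.int(8, 1)
        rn <- r + .neighbor_offsets[k, 1L]
        cn <- c + .neighbor_offsets[k, 2L]
        if (rn >= 1 && rn <= H && cn >= 1 && cn <= W)
          members <- unique(c(members, (cn - 1L) * H + rn))
      }
      sites <- c(sites, members)
    }
  }
  sites <- unique(sites)
  if (length(sites) == 0)
    return(list(pixels = img, hot_mask = hot_mask))
  p <- pad_replicate(img, 1L)
  out <- img
  for (s in sites) {
    r <- ((s - 1L) %% H) + 1L
    c <- ((s - 1L) %/% H) + 1L
    local_max <- max(p[r:(r + 2L), c:(c + 2L)])
    base <- max(local_max, cfg$lambda_fg)
    out[s] <- round(base * runif(1, cfg$hot_factor_range[1],
                                 cfg$hot_factor_range[2]))
  }
  hot_mask[sites] <- TRUE
  list(pixels = out, hot_mask = hot_mask)
}

#' Simulate a full IMC image triplet
#'
#' Convenience wrapper producing the clean field, its Poisson-corrupted
#' version, the hot-pixel-injected final image and all masks, under one
#' seed.
#'
#' @param cfg a `sim_config`.
#' @param seed integer seed fixing all draws.
#' @return list of class `simulated_triplet` with `clean`, `noisy`, `hot`,
#'   `hot_mask`, `fg_mask`, `bg_mask`, `cfg`, `seed`.
#' @export
simulate_imc <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  g <- generate_clean(cfg)
  noisy <- add_shot_noise(g$clean)
  h <- add_hot_pixels(noisy, cfg)
  structure(list(clean = g$clean, noisy = noisy, hot = h$pixels,
                 hot_mask = h$hot_mask, fg_mask = g$fg_mask,
                 bg_mask = g$bg_mask, cfg = cfg, seed = seed),
            class = "simulated_triplet")
}

#' Write a benchmark grid of simulated triplets to disk
#'
#' Writes `clean` / `noisy` / `hot` / `hot_mask` TIFF layers per instance
#' plus a `manifest.csv` describing the configuration of each instance.
#'
#' @param out_dir output directory (created if missing).
#' @param configs list of `sim_config` objects.
#' @param seeds integer seeds, one per instance per config.
#' @return data frame manifest (also written as `manifest.csv`).
#' @export
simulate_benchmark <- function(out_dir, configs = list(sim_config()),
                               seeds = 1:3) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory")
  rows <- list()
  id <- 0L
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (s in seeds) {
      id <- id + 1L
      trip <- simulate_imc(cfg, seed = s)
      base <- sprintf("sim%03d", id)
      layers <- c(clean = "clean", noisy = "noisy", hot = "hot",
                  hot_mask = "hot_mask")
      paths <- file.path(out_dir, paste0(base, "_", names(layers), ".tiff"))
      write_tiff(trip$clean, paths[1], dtype = "float32")
      write_tiff(trip$noisy, paths[2], dtype = "float32")
      write_tiff(trip$hot, paths[3], dtype = "float32")
      write_tiff(trip$hot_mask * 1, paths[4], dtype = "uint16")
      rows[[id]] <- data.frame(
        id = base, seed = s, size = cfg$size, kind = cfg$kind,
        lambda_fg = cfg$lambda_fg, lambda_bg = cfg$lambda_bg,
        hot_pixel_density = cfg$hot_pixel_density,
        hot_cluster_density = cfg$hot_cluster_density,
        clean = paths[1], noisy = paths[2], hot = paths[3],
        hot_mask = paths[4], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
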