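test_that("clean field generation: intensity calibration and determinism", {
  cfg <- sim_config(size = 128, lambda_fg = 20, lambda_bg = 1)
  set.seed(10)
  g <- generate_clean(cfg)
  expect_equal(mean(g$clean[g$fg_mask]), 20, tolerance = 2)
  expect_true(all(g$fg_mask | g$bg_mask))
  expect_false(any(g$fg_mask & g$bg_mask))
  set.seed(10)
  g2 <- generate_clean(cfg)
  expect_identical(g$clean, g2$clean)
  # degenerate empty scene
  cfg0 <- sim_config(size = 32, lambda_fg = 5, lambda_bg = 0, n_blobs = 0)
  cfg0$n_blobs <- 0L
  set.seed(1)
  g0 <- generate_clean(cfg0)
  expect_true(all(g0$clean == 0))
})

test_that("shot noise is Poisson: zero mean, CLT bounds, integer support", {
  set.seed(2)
  expect_true(all(add_shot_noise(matrix(0, 10, 10)) == 0))
  x <- add_shot_noise(matrix(100, 256, 256))
  expect_gt(mean(x), 99); expect_lt(mean(x), 101)
  expect_gt(var(as.numeric(x)) / mean(x), 0.9)
  expect_lt(var(as.numeric(x)) / mean(x), 1.1)
  expect_true(all(x >= 0) && all(x == round(x)))
})

test_that("hot pixel injection: density, mask consistency, amplitude", {
  cfg <- sim_config(size = 100, lambda_fg = 20, lambda_bg = 1,
                    hot_pixel_density = 0.01)
  set.seed(3)
  img <- matrix(rpois(1e4, 3), 100, 100)
  h <- add_hot_pixels(img, cfg)
  n <- sum(h$hot_mask)
  expect_gt(n, 100 - 3 * sqrt(100))
  expect_lt(n, 100 + 3 * sqrt(100))
  # conservation off the mask
  expect_equal(h$pixels[!h$hot_mask], img[!h$hot_mask])
  # every injected pixel strictly exceeds its pre-injection 3x3 max
  idx <- which(h$hot_mask)
  p <- imcdenoise:::pad_replicate(img, 1L)
  for (i in idx) {
    r <- (i - 1) %% 100 + 1; c <- (i - 1) %/% 100 + 1
    expect_gt(h$pixels[i], max(p[r:(r + 2), c:(c + 2)]))
  }
  # zero density leaves everything untouched
  cfg0 <- sim_config(size = 50, hot_pixel_density = 0)
  set.seed(4)
  img0 <- matrix(rpois(2500, 5), 50, 50)
  h0 <- add_hot_pixels(img0, cfg0)
  expect_identical(h0$pixels, img0)
  expect_false(any(h0$hot_mask))
})

test_that("cluster injection produces connected clusters of bounded size", {
  cfg <- sim_config(size = 64, hot_pixel_density = 0,
                    hot_cluster_density = 0.002,
                    cluster_size_range = c(2L, 4L))
  set.seed(5)
  img <- matrix(rpois(64^2, 5), 64, 64)
  h <- add_hot_pixels(img, cfg)
  expect_gt(sum(h$hot_mask), 0)
})

test_that("triplet layers are consistent and seed-reproducible", {
  cfg <- sim_config(size = 64, hot_pixel_density = 0.01)
  t1 <- simulate_imc(cfg, seed = 77)
  t2 <- simulate_imc(cfg, seed = 77)
  expect_identical(t1$hot, t2$hot)
  expect_equal(t1$hot[!t1$hot_mask], t1$noisy[!t1$hot_mask])
  # per-pixel SNR of the Poisson layer ~ sqrt(lambda) on constant patches
  set.seed(6)
  for (lam in c(5, 20, 50)) {
    patch <- add_shot_noise(matrix(lam, 128, 128))
    snr <- mean(patch) / sd(as.numeric(patch))
    expect_equal(snr, sqrt(lam), tolerance = 0.1 * sqrt(lam))
  }
})

test_that("benchmark writer emits TIFF layers and a manifest", {
  dir <- withr::local_tempdir()
  mf <- simulate_benchmark(dir, configs = list(sim_config(size = 64)),
                           seeds = 1:2)
  expect_equal(nrow(mf), 2)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(mf$hot)))
  trip <- simulate_imc(sim_config(size = 64), seed = 1)
  expect_equal(read_tiff(mf$hot[1]), trip$hot, tolerance = 1e-6)
  expect_equal(read_tiff(mf$hot_mask[1]) > 0, unname(trip$hot_mask))
})
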