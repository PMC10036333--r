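test_that("difference maps: constant image, spike, background cut", {
  t_const <- matrix(5, 6, 6)
  dm <- compute_difference_maps(t_const)
  expect_true(all(dm$maps == 0))
  expect_equal(dm$robust_centers, rep(0, 8))
  expect_true(all(dm$valid_mask))

  t_spike <- matrix(anscombe_forward(5), 5, 5)
  t_spike[3, 3] <- anscombe_forward(10)
  dm <- compute_difference_maps(t_spike)
  center <- dm$maps[3 + 5 * 2, ]  # linear index of (3,3)
  expect_equal(unname(center),
               rep(anscombe_forward(10) - anscombe_forward(5), 8))

  t_low <- matrix(2, 6, 6)  # all below the cutoff of 4
  dm <- compute_difference_maps(t_low)
  expect_false(any(dm$valid_mask))
  agg <- aggregate_min_differences(dm)
  expect_length(agg$values, 0)
  expect_error(compute_difference_maps(matrix(1, 2, 2)), "3x3")
})

test_that("aggregate statistic matches the brute-force 8-neighbor oracle", {
  set.seed(21)
  img <- matrix(rpois(25, 30), 5, 5)
  img[3, 3] <- 400  # spike
  t <- anscombe_forward(img)
  dm <- compute_difference_maps(t)
  agg <- aggregate_min_differences(dm, l = 4)
  # recompute every valid pixel's t_4 via the oracle
  for (j in seq_along(agg$index)) {
    idx <- agg$index[j]
    expect_equal(agg$values[j],
                 oracle_t_l(dm$maps[idx, ], dm$robust_centers, 4),
                 tolerance = 1e-12)
  }
  expect_equal(aggregate_min_differences(dm, l = 8)$values[1],
               sum(dm$maps[agg$index[1], ]), tolerance = 1e-12)
  # constant image: t_l identically zero
  dmc <- compute_difference_maps(matrix(6, 5, 5))
  expect_true(all(aggregate_min_differences(dmc)$values == 0))
})

test_that("ties in the distance sort break by direction index", {
  # craft a pixel whose 8 differences give tied distances
  d8 <- c(2, -2, 2, -2, 1, 1, 3, 3)
  centers <- rep(0, 8)
  # distances: 2 2 2 2 1 1 3 3 -> l=4 picks dirs 5,6 (dist 1) then 1,2
  expect_equal(oracle_t_l(d8, centers, 4), 1 + 1 + 2 - 2)
})

test_that("kde fit: known density, positivity, normalization", {
  set.seed(8)
  x <- rnorm(1e4) * 10  # scale up so the unit-grid bandwidth floor is inert
  curve <- fit_kde(x)
  expect_s3_class(curve, "kde_curve")
  expect_true(all(curve$density >= 0))
  expect_equal(diff(curve$grid)[1], 1)
  # trapezoid integral
  integral <- sum((head(curve$density, -1) + tail(curve$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 0.01)
  # density near 0 within 10% of N(0, 10) peak
  peak <- curve$density[which.min(abs(curve$grid))]
  expect_equal(peak, 1 / sqrt(2 * pi) / 10, tolerance = 0.1)
  expect_warning(fit_kde(1:5), "fewer than 10")
  # constant sample: bandwidth floor keeps the fit usable and the
  # threshold lands beyond every sample point (nothing flagged)
  cst <- fit_kde(rep(2, 20))
  expect_gt(find_threshold(cst), 2)
})

test_that("threshold detection: clean unimodal curve flags nothing, a far
           bump is cut between the modes", {
  set.seed(12)
  main <- rnorm(2e4) * 2
  curve <- fit_kde(main)
  xt <- find_threshold(curve)
  # derivative vanishes only in the far tail: nothing beyond it
  expect_gt(xt, quantile(main, 0.999))
  bump <- c(main, rnorm(200) * 0.5 + 20)  # tiny mode at +10 sigma
  curve2 <- fit_kde(bump)
  xt2 <- find_threshold(curve2)
  expect_gt(xt2, max(main))
  expect_lt(xt2, 19)
  expect_gt(sum(bump > xt2), 150)  # the bump is flagged
})

test_that("median replacement uses pre-replacement values and edge rules", {
  img <- matrix(1, 3, 3)
  img[2, 2] <- 100
  mask <- img > 50
  expect_equal(median_replace(img, mask)[2, 2], 1)
  expect_equal(median_replace(img, matrix(FALSE, 3, 3)), img)
  set.seed(31)
  big <- matrix(rpois(100, 10), 10, 10)
  m <- matrix(runif(100) < 0.2, 10, 10)
  m[4, 5] <- TRUE; m[5, 5] <- TRUE  # adjacent flagged pair
  expect_equal(median_replace(big, m), oracle_median_replace(big, m))
})

test_that("dimr removes injected single hot pixels and stays idle on
           clean images", {
  expect_equal(dimr(matrix(5, 16, 16))$report$total_flagged, 0)
  trip <- simulate_imc(sim_config(size = 128, lambda_fg = 10,
                                  lambda_bg = 1,
                                  hot_pixel_density = 50 / 128^2),
                       seed = 3)
  res <- dimr(trip$hot)
  det <- res$report$total_mask
  expect_gte(sum(det & trip$hot_mask) / sum(trip$hot_mask), 0.9)
  expect_lte(sum(det & !trip$hot_mask), 5)
  expect_s3_class(res$report, "hot_pixel_report")
  expect_lte(res$report$iterations_run, 3)
})

test_that("dimr never modifies pixels below the background cutoff", {
  trip <- simulate_imc(sim_config(size = 64, lambda_fg = 20, lambda_bg = 1,
                                  hot_pixel_density = 0.01), seed = 6)
  res <- dimr(trip$hot)
  low <- anscombe_forward(trip$hot) < 4
  expect_equal(res$pixels[low], trip$hot[low], tolerance = 1e-9)
})

test_that("dimr is idempotent in tendency: second pass changes almost
           nothing", {
  trip <- simulate_imc(sim_config(size = 128, lambda_fg = 20, lambda_bg = 1,
                                  hot_pixel_density = 0.01), seed = 9)
  r1 <- dimr(trip$hot)
  r2 <- dimr(r1$pixels)
  expect_lte(mean(abs(r2$pixels - r1$pixels) > 1e-6), 0.001)
})

test_that("zero-density control: false flags are rare without injected
           hot pixels", {
  fracs <- sapply(1:10, function(s) {
    trip <- simulate_imc(sim_config(size = 128, lambda_fg = 20,
                                    lambda_bg = 1,
                                    hot_pixel_density = 0), seed = s)
    rep <- dimr(trip$noisy)$report
    n_valid <- sum(anscombe_forward(trip$noisy) >= 4)
    rep$total_flagged / max(n_valid, 1)
  })
  expect_lt(median(fracs), 0.005)
})

test_that("flagged count grows with injected density (monotone burden)", {
  counts <- sapply(c(0.001, 0.005, 0.01), function(dens) {
    median(sapply(1:5, function(s) {
      trip <- simulate_imc(sim_config(size = 96, lambda_fg = 20,
                                      lambda_bg = 1,
                                      hot_pixel_density = dens), seed = s)
      dimr(trip$hot)$report$total_flagged
    }))
  })
  expect_true(all(diff(counts) > 0))
})
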