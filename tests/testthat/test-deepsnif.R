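test_that("patch extraction: tiling arithmetic, filtering, augmentation", {
  img <- matrix(rpois(128 * 128, 5) + 1, 128, 128)  # fully positive
  ps <- suppressWarnings(extract_patches(img, rho = 0.8, seed = 1))
  expect_equal(ps$n_base, 4)           # 128x128 -> 4 base tiles
  expect_equal(dim(ps$patches)[3], 32) # x8 augmentations
  one <- matrix(rpois(64 * 64, 10) + 1, 64, 64)
  ps1 <- suppressWarnings(extract_patches(one, rho = 0.8, seed = 1))
  expect_equal(dim(ps1$patches)[3], 8)
  # the 8 orientations contain the original and its vertical mirror
  sc <- ps1$record$scale_value
  expect_true(any(apply(ps1$patches, 3, function(p)
    isTRUE(all.equal(p * sc, one, tolerance = 1e-9)))))
  expect_error(suppressWarnings(
    extract_patches(matrix(0, 64, 64), rho = 0.8)), "empty training set")
  # split proportions
  expect_equal(sum(ps$split == "train"), round(0.85 * 32))
})

test_that("masking: exact count, stratification, unmasked identity,
           determinism", {
  set.seed(2)
  patch <- matrix(runif(4096), 64, 64)
  mm <- make_mask(patch, rate = 0.002)
  expect_equal(sum(mm$plan$mask), 8)  # round(0.002 * 4096)
  expect_identical(mm$masked[!mm$plan$mask], patch[!mm$plan$mask])
  # every masked value came from a 5x5 neighbor, not the center
  idx <- which(mm$plan$mask)
  for (j in seq_along(idx)) {
    off <- mm$plan$offsets[j, ]
    expect_true(any(off != 0) && all(abs(off) <= 2))
  }
  # one masked pixel per stratum: 2x4 grid of 32x16 strata for k = 8
  rows <- (which(mm$plan$mask) - 1) %% 64 + 1
  expect_equal(sum(rows <= 32), 4)
  set.seed(99); m1 <- make_mask(patch)
  set.seed(99); m2 <- make_mask(patch)
  expect_identical(m1$plan$mask, m2$plan$mask)
  expect_identical(m1$masked, m2$masked)
})

test_that("i-divergence: closed forms, zero convention, masked-only", {
  p <- matrix(2, 4, 4); t0 <- matrix(2, 4, 4)
  M <- matrix(FALSE, 4, 4); M[1, 1] <- TRUE
  expect_equal(i_divergence(p, t0, M), 0)
  t0[1, 1] <- 0
  expect_equal(i_divergence(p, t0, M), 2)  # 0 - 0 + 2
  t0[1, 1] <- 4
  expect_equal(i_divergence(p, t0, M), 4 * log(2) - 4 + 2,
               tolerance = 1e-12)
  # perturbing unmasked targets changes nothing
  t1 <- t0; t1[!M] <- 77
  expect_equal(i_divergence(p, t1, M), i_divergence(p, t0, M))
  expect_error(i_divergence(p * 0, t0, M), "positive")
})

test_that("losses match naive double-loop oracles on random 8x8 inputs", {
  set.seed(13)
  for (rep in 1:10) {
    pred <- matrix(runif(64, 0.1, 3), 8, 8)
    target <- matrix(rpois(64, 2), 8, 8)
    M <- matrix(runif(64) < 0.2, 8, 8)
    M[1] <- TRUE
    expect_equal(i_divergence(pred, target, M),
                 oracle_idiv(pred, target, M), tolerance = 1e-6)
    expect_equal(hessian_norm(pred), oracle_hessian(pred),
                 tolerance = 1e-6)
  }
})

test_that("hessian norm: constant and planar fields vanish, x^2 curves", {
  expect_equal(hessian_norm(matrix(7, 10, 10)), 0)
  ramp <- outer(1:10, 1:10, function(i, j) 3 * i - 2 * j + 1)
  expect_equal(hessian_norm(ramp), 0)
  sq <- outer(1:12, 1:12, function(i, j) i^2)
  expect_equal(hessian_norm(sq), 2)  # f_xx = 2 on the interior
})

test_that("total loss composes the two terms and supports the
           no-regularization variant", {
  pred <- outer(1:12, 1:12, function(i, j) i^2) + 0.5
  target <- pred
  M <- matrix(FALSE, 12, 12); M[5, 5] <- TRUE
  expect_equal(total_loss(pred, target, M, lambda_h = 0),
               i_divergence(pred, target, M))
  expect_equal(total_loss(pred, target, M, lambda_h = 3e-6), 3e-6 * 2,
               tolerance = 1e-12)
  cst <- matrix(1.5, 8, 8)
  expect_equal(total_loss(cst, cst, M[1:8, 1:8], 3e-6), 0)
})

test_that("network convolution kernels match the naive oracle (fwd and
           both gradients)", {
  set.seed(17)
  x <- array(rnorm(6 * 8 * 2 * 3), c(6, 8, 2, 3))
  w <- matrix(rnorm(27 * 4), 27, 4); b <- rnorm(4)
  y <- imcdenoise:::conv_apply(x, w, b, 3L)
  expect_equal(y, oracle_conv(x, w, b, 3L), tolerance = 1e-5)
  dy <- array(rnorm(length(y)), dim(y))
  fw <- imcdenoise:::conv_fwd(x, dim(x), NULL, 0L, w, b, 3L, TRUE, NULL)
  bk <- imcdenoise:::conv_bwd(fw$col, dim(x), 0L, w, dy, 3L, TRUE)
  ref <- oracle_conv_grads(x, w, dy, 3L)
  expect_equal(bk$dx, ref$dx, tolerance = 1e-4)
  expect_equal(bk$dw, ref$dw, tolerance = 1e-4)
  expect_equal(bk$db, ref$db, tolerance = 1e-4)
  # 1x1 path
  w1 <- matrix(rnorm(3 * 5), 3, 5)
  fw1 <- imcdenoise:::conv_fwd(x, dim(x), NULL, 0L, w1, numeric(5), 1L,
                               TRUE, NULL)
  dy1 <- array(rnorm(6 * 8 * 2 * 5), c(6, 8, 2, 5))
  bk1 <- imcdenoise:::conv_bwd(fw1$col, dim(x), 0L, w1, dy1, 1L, TRUE)
  ref1 <- oracle_conv_grads(x, w1, dy1, 1L)
  expect_equal(bk1$dx, ref1$dx, tolerance = 1e-4)
  # stacked two-piece input equals convolution of the concatenation
  xa <- x[, , , 1:2, drop = FALSE]; xb <- x[, , , 3, drop = FALSE]
  fw2 <- imcdenoise:::conv_fwd(xa, dim(xa), xb, 1L, w, b, 3L, FALSE, NULL)
  expect_equal(fw2$y, y, tolerance = 1e-5)
})

test_that("whole-network gradients agree with double-precision finite
           differences", {
  # float kernels limit agreement; compare on a tiny net with loose but
  # meaningful relative tolerance
  set.seed(7)
  net <- imcdenoise:::net_init(base_filters = 2L)
  net$arch$dropout_rate <- 0
  x <- array(abs(rnorm(32 * 32 * 2)), c(32, 32, 2, 1))
  tgt <- array(abs(rnorm(32 * 32 * 2)), c(32, 32, 2, 1))
  M <- array(runif(32 * 32 * 2) < 0.05, c(32, 32, 2, 1))
  fw <- imcdenoise:::net_forward(net, x, train = TRUE)
  lg <- imcdenoise:::.batch_loss_grad(fw$pred, tgt, M, 1e-3)
  bw <- imcdenoise:::net_backward(net, fw, lg$dpred)
  loss_at <- function(net) {
    f <- imcdenoise:::net_forward(net, x, train = TRUE, keep_cache = FALSE)
    imcdenoise:::.batch_loss_grad(f$pred, tgt, M, 1e-3)$loss
  }
  eps <- 1e-3
  for (nm in c("b1.w", "c2.gamma", "d1.w", "b3.beta")) {
    i <- 2L
    np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + eps
    nm2 <- net; nm2$params[[nm]][i] <- nm2$params[[nm]][i] - eps
    num <- (loss_at(np) - loss_at(nm2)) / (2 * eps)
    ana <- bw$grads[[nm]][i]
    expect_equal(ana, num, tolerance = 0.05)
  }
})

test_that("training contract: finite losses, seeded determinism, descent", {
  set.seed(20)
  imgs <- matrix(rpois(128 * 128, 8) + 1, 128, 128)
  ps <- suppressWarnings(extract_patches(imgs, rho = 0.9, seed = 1))
  m1 <- deepsnif_train(ps, base_filters = 2, epochs = 2, batch_size = 8,
                       seed = 5)
  expect_true(all(is.finite(m1$history$train_loss)))
  expect_true(all(is.finite(m1$history$val_loss)))
  m2 <- deepsnif_train(ps, base_filters = 2, epochs = 2, batch_size = 8,
                       seed = 5)
  expect_equal(m1$history$train_loss[1], m2$history$train_loss[1],
               tolerance = 1e-6)
  m3 <- deepsnif_train(ps, base_filters = 4, epochs = 12, batch_size = 8,
                       seed = 5)
  expect_lt(tail(m3$history$train_loss, 1), m3$history$train_loss[1])
})

test_that("prediction pads to multiples of 16, preserves shape, stays
           positive", {
  set.seed(21)
  imgs <- matrix(rpois(128 * 128, 8) + 1, 128, 128)
  ps <- suppressWarnings(extract_patches(imgs, rho = 0.9, seed = 1))
  m <- deepsnif_train(ps, base_filters = 2, epochs = 1, batch_size = 8,
                      seed = 5)
  for (sz in list(c(100, 100), c(64, 64), c(48, 80))) {
    img <- matrix(rpois(prod(sz), 8), sz[1], sz[2])
    out <- deepsnif_predict(m, img)
    expect_equal(dim(out), sz)
    expect_true(all(out > 0))
  }
  expect_error(deepsnif_predict(m, matrix(numeric(0), 0, 0)), "empty")
  # save / load round trip predicts identically
  dir <- withr::local_tempdir()
  p <- file.path(dir, "model.rds")
  deepsnif_save(m, p)
  m2 <- deepsnif_load(p)
  img <- matrix(rpois(64 * 64, 8), 64, 64)
  expect_equal(deepsnif_predict(m2, img), deepsnif_predict(m, img))
})
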