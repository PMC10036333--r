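test_that("identity and hand-computed cases for rmse/psnr/ssim", {
  set.seed(1)
  x <- matrix(runif(256), 16, 16)
  expect_equal(img_rmse(x, x), 0)
  expect_equal(img_ssim(x, x), 1, tolerance = 1e-9)
  expect_equal(img_psnr(x, x), Inf)
  expect_equal(img_rmse(c(0, 0), c(3, 4)), sqrt(25 / 2), tolerance = 1e-12)
  # peak 255, MSE 1 -> 10 log10(255^2)
  a <- matrix(0, 10, 10); b <- matrix(1, 10, 10)
  expect_equal(img_psnr(a, b, peak = 255), 10 * log10(255^2),
               tolerance = 1e-9)
})

test_that("metrics match naive double-loop oracles on random instances", {
  set.seed(11)
  for (rep in 1:5) {
    img <- matrix(rpois(256, 6), 16, 16)
    bg <- matrix(runif(256) < 0.4, 16, 16)
    bg[1] <- TRUE  # never empty
    expect_equal(img_rmse(img, img * 0), oracle_rmse(img, img * 0),
                 tolerance = 1e-9)
    expect_equal(stdb(img, bg), oracle_stdb(img, bg), tolerance = 1e-9)
    y <- rnorm(100); z <- y + rnorm(100)
    expect_equal(pcc(y, z), oracle_pcc(y, z), tolerance = 1e-12)
  }
})

test_that("stdb uses the population convention and rejects empty masks", {
  img <- matrix(c(1, 3, 1, 3), 2, 2)
  expect_equal(stdb(img, matrix(TRUE, 2, 2)), 1)
  expect_equal(stdb(matrix(5, 3, 3), matrix(TRUE, 3, 3)), 0)
  expect_error(stdb(img, matrix(FALSE, 2, 2)), "empty")
})

test_that("cnr matches its definition and is shift-invariant", {
  img <- matrix(0, 4, 4)
  sm <- matrix(FALSE, 4, 4); bm <- matrix(FALSE, 4, 4)
  sm[, 1:2] <- TRUE; bm[, 3:4] <- TRUE
  img[sm] <- 10
  img[bm] <- c(0, 4)  # mean 2, population sd 2
  expect_equal(cnr(img, sm, bm), (10 - 2) / 2, tolerance = 1e-12)
  expect_equal(cnr(img + 7, sm, bm), cnr(img, sm, bm), tolerance = 1e-12)
  img2 <- img; img2[sm] <- img[bm]  # signal = background stats
  expect_equal(cnr(img2, sm, bm), 0, tolerance = 1e-12)
  expect_error(cnr(matrix(1, 4, 4), sm, bm), "undefined")
})

test_that("cnr and stdb depend only on pixels inside the masks", {
  set.seed(14)
  img <- matrix(rpois(256, 10), 16, 16)
  sm <- matrix(FALSE, 16, 16); sm[1:4, ] <- TRUE
  bm <- matrix(FALSE, 16, 16); bm[9:16, ] <- TRUE
  img2 <- img
  img2[!(sm | bm)] <- 999  # perturb only unmasked pixels
  expect_equal(stdb(img2, bm), stdb(img, bm))
  expect_equal(cnr(img2, sm, bm), cnr(img, sm, bm))
})

test_that("pcc basics: self, negation, affine invariance", {
  set.seed(3)
  x <- rnorm(50)
  expect_equal(pcc(x, x), 1, tolerance = 1e-12)
  expect_equal(pcc(x, -x), -1, tolerance = 1e-12)
  expect_equal(pcc(x, 2.5 * x + 3), 1, tolerance = 1e-12)
  expect_error(pcc(x, rep(1, 50)), "variance")
})

test_that("binarize is >=-inclusive", {
  expect_equal(as.numeric(binarize(c(0.5, 1, 2), 1)), c(0, 1, 1))
  img <- matrix(rpois(64, 3), 8, 8)
  expect_true(all(binarize(img, 0)))
  expect_false(any(binarize(img, max(img) + 1)))
})

test_that("overlap scores: arithmetic, identity F1 = 2J/(1+J), edge cases", {
  p <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2, 3)
  t <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE), 2, 3)
  ov <- overlap_scores(p, t)  # TP 2, FP 1, FN 1
  expect_equal(unname(ov$counts[c("TP", "FP", "FN")]), c(2, 1, 1))
  expect_equal(ov$f1, 4 / 6, tolerance = 1e-12)
  expect_equal(ov$jaccard, 0.5, tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:20) {
    pm <- matrix(runif(144) < 0.4, 12, 12)
    tm <- matrix(runif(144) < 0.4, 12, 12)
    ov <- overlap_scores(pm, tm)
    ref <- oracle_f1_jaccard(pm, tm)
    expect_equal(ov$f1, unname(ref["f1"]), tolerance = 1e-12)
    expect_equal(ov$jaccard, unname(ref["jaccard"]), tolerance = 1e-12)
    expect_equal(ov$f1, 2 * ov$jaccard / (1 + ov$jaccard), tolerance = 1e-12)
    expect_gte(ov$f1, ov$jaccard)
  }
  empty <- matrix(FALSE, 3, 3)
  some <- matrix(c(TRUE, rep(FALSE, 8)), 3, 3)
  expect_equal(overlap_scores(empty, empty)$f1, 1)
  expect_equal(overlap_scores(some, empty)$f1, 0)
})
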