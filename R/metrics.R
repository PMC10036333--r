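# Image-quality and overlap metrics used to score restoration results.

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("images must have the same shape", call. = FALSE)
}

#' Root mean squared error
#' @param a,b numeric images of identical shape.
#' @return scalar RMSE.
#' @export
img_rmse <- function(a, b) {
  .check_same_shape(a, b)
  sqrt(mean((as.numeric(a) - as.numeric(b))^2))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB. Identical images return `Inf`.
#'
#' @param a,b numeric images of identical shape.
#' @param peak positive dynamic-range value; defaults to the joint maximum
#'   of the two images.
#' @return scalar in dB (`Inf` for identical inputs).
#' @export
img_psnr <- function(a, b, peak = max(a, b)) {
  .check_same_shape(a, b)
  if (peak <= 0) stop("peak must be positive", call. = FALSE)
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Mean SSIM over the image, computed with an 11x11 Gaussian window
#' (sigma 1.5), constants K1 = 0.01, K2 = 0.03 and dynamic range taken from
#' the joint maximum of the pair unless given.
#'
#' @param a,b numeric matrices of identical shape.
#' @param dynamic_range positive scalar `L` in the SSIM constants.
#' @return scalar in `[-1, 1]`; 1 for identical images.
#' @export
img_ssim <- function(a, b, dynamic_range = max(a, b) - min(a, b)) {
  .check_same_shape(a, b)
  if (!is.matrix(a)) stop("ssim expects 2D images", call. = FALSE)
  if (dynamic_range <= 0) dynamic_range <- 1
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  w <- function(x) gaussian_smooth(x, kernel_size = 11, sigma = 1.5)
  mu_a <- w(a); mu_b <- w(b)
  va <- w(a * a) - mu_a^2
  vb <- w(b * b) - mu_b^2
  vab <- w(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Standard deviation of the annotated background (STDB)
#'
#' Noise-level readout: the standard deviation of image intensities inside
#' the background mask, population convention (divide by N).
#'
#' @param img numeric image.
#' @param bg_mask logical mask of the same shape; must select at least one
#'   pixel.
#' @return scalar standard deviation.
#' @export
stdb <- function(img, bg_mask) {
  .check_same_shape(img, bg_mask)
  v <- as.numeric(img)[as.logical(bg_mask)]
  if (length(v) == 0) stop("background mask is empty", call. = FALSE)
  sqrt(mean((v - mean(v))^2))
}

#' Contrast-to-noise ratio (CNR)
#'
#' `(C_sig - C_bg) / sigma_bg` where `C_sig`, `C_bg` are the mean intensity
#' over the annotated signal and background regions and `sigma_bg` is
#' [stdb()].
#'
#' @param img numeric image.
#' @param signal_mask,bg_mask non-empty logical masks of the same shape.
#' @return scalar CNR.
#' @export
cnr <- function(img, signal_mask, bg_mask) {
  .check_same_shape(img, signal_mask)
  .check_same_shape(img, bg_mask)
  x <- as.numeric(img)
  s <- as.logical(signal_mask); b <- as.logical(bg_mask)
  if (!any(s) || !any(b)) stop("masks must be non-empty", call. = FALSE)
  sig_bg <- stdb(img, bg_mask)
  if (sig_bg == 0) stop("zero background deviation: CNR undefined", call. = FALSE)
  (mean(x[s]) - mean(x[b])) / sig_bg
}

#' Pearson correlation coefficient between two images
#'
#' @param y,y_ref numeric vectors/images of equal length (>= 2) with
#'   non-zero variance.
#' @return scalar in `[-1, 1]`.
#' @export
pcc <- function(y, y_ref) {
  y <- as.numeric(y); y_ref <- as.numeric(y_ref)
  if (length(y) != length(y_ref) || length(y) < 2)
    stop("inputs must have equal length >= 2", call. = FALSE)
  if (sd(y) == 0 || sd(y_ref) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  dy <- y - mean(y); dr <- y_ref - mean(y_ref)
  sum(dy * dr) / sqrt(sum(dy^2) * sum(dr^2))
}

#' Threshold binarization
#'
#' Inclusive at the boundary: pixels `>= threshold` map to `TRUE`. The
#' inclusive convention matters for the single-threshold-1 background
#' removal applied to softplus-positive denoised images.
#'
#' @param img numeric image.
#' @param threshold finite scalar.
#' @return logical mask of the same shape.
#' @export
binarize <- function(img, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  m <- img >= threshold
  storage.mode(m) <- "logical"
  m
}

#' Pixel-overlap scores between a predicted and a reference mask
#'
#' Returns the confusion counts together with the F1 score
#' `2TP / (2TP + FP + FN)` and Jaccard score `TP / (TP + FP + FN)`.
#' Both masks empty counts as perfect agreement (score 1); an empty truth
#' with a non-empty prediction scores 0.
#'
#' @param pred_mask,truth_mask logical masks of identical shape.
#' @return list with `counts` (TP, FP, FN, TN), `f1` and `jaccard`.
#' @export
overlap_scores <- function(pred_mask, truth_mask) {
  .check_same_shape(pred_mask, truth_mask)
  p <- as.logical(pred_mask); t <- as.logical(truth_mask)
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  denom_f1 <- 2 * tp + fp + fn
  denom_j <- tp + fp + fn
  f1 <- if (denom_f1 == 0) 1 else 2 * tp / denom_f1
  j <- if (denom_j == 0) 1 else tp / denom_j
  list(counts = c(TP = tp, FP = fp, FN = fn, TN = tn), f1 = f1, jaccard = j)
}
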