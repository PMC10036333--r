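# Variance stabilization and intensity normalization shared by both
# restoration stages.

.check_image <- function(img, what = "img") {
  if (!is.numeric(img)) stop(what, " must be numeric", call. = FALSE)
  if (anyNA(img) || any(!is.finite(img)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(img)
}

#' Anscombe variance-stabilizing transform
#'
#' Maps Poisson-distributed counts `x` to `2 * sqrt(x + 3/8)`, which has
#' approximately unit variance for moderate-to-large Poisson means. DIMR
#' detects hot pixels in this domain so that neighbor differences are
#' close to homoscedastic Gaussian.
#'
#' @param img numeric vector, matrix or array of non-negative counts.
#' @return Object of the same shape with transformed values (all
#'   `>= 2 * sqrt(3/8)`).
#' @seealso [anscombe_inverse()] for the direct algebraic inverse.
#' @examples
#' anscombe_forward(0)   # 2*sqrt(0.375) ~ 1.2247
#' anscombe_forward(1)   # ~ 2.3452
#' @export
anscombe_forward <- function(img) {
  .check_image(img)
  if (any(img < 0)) stop("counts must be non-negative", call. = FALSE)
  2 * sqrt(img + 0.375)
}

#' Direct algebraic inverse Anscombe transform
#'
#' Inverts [anscombe_forward()] pointwise via `(y/2)^2 - 3/8`. This is the
#' direct algebraic inverse (not the exact-unbiased inverse); composed with
#' the forward transform it is the identity on counts.
#'
#' @param t numeric vector, matrix or array of non-negative
#'   variance-stabilized values.
#' @return Same shape, real-valued (can be slightly negative only for
#'   inputs below `2*sqrt(3/8)`, which do not arise from counts).
#' @export
anscombe_inverse <- function(t) {
  .check_image(t, "t")
  if (any(t < 0)) stop("transformed values must be non-negative", call. = FALSE)
  (t / 2)^2 - 0.375
}

#' Percentile normalization with an invertible record
#'
#' Divides an image by the intensity at a high percentile (99.9--99.999 in
#' practice, default 99.99) of its pixel distribution. Values above 1 are
#' deliberately not clipped: the denoiser's softplus output and the
#' I-divergence loss tolerate them, and clipping would destroy bright
#' staining. The percentile uses linear interpolation between order
#' statistics (`stats::quantile()` type 7).
#'
#' @param img numeric matrix with at least one positive pixel.
#' @param percentile scalar in `[99, 100]`.
#' @param channel_id optional label stored in the record.
#' @return List with `pixels` (normalized image) and `record`, a
#'   `normalization_record` holding `percentile`, `scale_value` and
#'   `channel_id`; pass the record to [denormalize()] to invert exactly.
#' @export
percentile_normalize <- function(img, percentile = 99.99, channel_id = NULL) {
  .check_image(img)
  if (percentile < 99 || percentile > 100)
    stop("percentile must lie in [99, 100]", call. = FALSE)
  scale_value <- as.numeric(quantile(img, percentile / 100, type = 7))
  if (scale_value <= 0)
    stop("degenerate scale: image percentile is not positive", call. = FALSE)
  record <- structure(
    list(percentile = percentile, scale_value = scale_value,
         channel_id = channel_id),
    class = "normalization_record")
  list(pixels = img / scale_value, record = record)
}

#' Undo a percentile normalization
#'
#' @param img normalized image.
#' @param record a `normalization_record` from [percentile_normalize()].
#' @return Image on the original intensity scale.
#' @export
denormalize <- function(img, record) {
  stopifnot(inherits(record, "normalization_record"))
  img * record$scale_value
}

#' @export
print.normalization_record <- function(x, ...) {
  cat(sprintf("normalization_record: p%.5g -> scale %.6g (channel %s)\n",
              x$percentile, x$scale_value,
              if (is.null(x$channel_id)) "<none>" else x$channel_id))
  invisible(x)
}
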