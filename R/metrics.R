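#' Intersection over union of two binary masks
#'
#' IoU(A, B) = |A & B| / |A | B|, the standard overlap score used both for
#' segmentation accuracy and for Annexin-V validity/localization calls.
#'
#' @param mask_a,mask_b logical matrices of identical geometry.
#' @return A number in [0, 1].
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' b <- matrix(FALSE, 4, 4); b[1:4, 1:2] <- TRUE
#' iou(a, b)  # 4/8
#' @export
iou <- function(mask_a, mask_b) {
  check_binary_mask(mask_a)
  check_binary_mask(mask_b, dim_ref = mask_a)
  u <- sum(mask_a | mask_b)
  if (u == 0L) stop("IoU is undefined when both masks are empty")
  sum(mask_a & mask_b) / u
}

#' Pearson correlation of two images
#'
#' Standard Pearson correlation coefficient over flattened pixels; used to
#' quantify Annexin-V colocalization with cell-body and immune-synapse
#' masks (masks are passed as 0/1 images).
#'
#' @param image_x,image_y numeric matrices of identical geometry, each with
#'   nonzero variance.
#' @return A number in [-1, 1].
#' @export
pcc <- function(image_x, image_y) {
  stopifnot(is.matrix(image_x), is.matrix(image_y))
  if (!identical(dim(image_x), dim(image_y)))
    stop("geometry mismatch between the two images")
  x <- as.numeric(image_x); y <- as.numeric(image_y)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("PCC is undefined for a zero-variance image")
  stats::cor(x, y)
}

#' Otsu threshold of an image
#'
#' Returns the gray level maximizing the between-class variance of the
#' two-class split of the intensity histogram. Candidate thresholds are the
#' distinct observed values; the split assigns a pixel to the foreground
#' when its value is strictly greater than the threshold, so the maximum
#' observed value is not a candidate. Among ties the smallest threshold is
#' returned.
#'
#' @param image numeric matrix with at least two distinct values.
#' @return The threshold, on the intensity scale of the input. Binarize as
#'   \code{image > otsu_threshold(image)}.
#' @export
otsu_threshold <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image), all(is.finite(image)))
  v <- sort(as.numeric(image))
  u <- unique(v)
  if (length(u) < 2L) stop("Otsu threshold is undefined for a constant image")
  cnt <- tabulate(findInterval(v, u), nbins = length(u))
  n <- length(v)
  # cumulative pixel count and intensity sum up to and including each level
  cw <- cumsum(cnt)
  cs <- cumsum(cnt * u)
  k <- seq_len(length(u) - 1L)        # thresholds: all levels but the max
  w0 <- cw[k] / n
  w1 <- 1 - w0
  mu0 <- cs[k] / cw[k]
  mu1 <- (cs[length(u)] - cs[k]) / (n - cw[k])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  u[k[which.max(bcv)]]
}

#' Otsu binarization
#'
#' Convenience wrapper: pixels strictly above the Otsu threshold become
#' foreground (ties fall to background).
#'
#' @param image numeric matrix with at least two distinct values.
#' @return Logical matrix.
#' @export
binarize_otsu <- function(image) {
  image > otsu_threshold(image)
}
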