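#' Contrast-to-noise ratio
#'
#' \code{CNR = 20 log10((mean_t - mean_b) / sqrt(sd_t^2 + sd_b^2))} computed on
#' linear envelope intensities of a target and a background region.
#'
#' @param image envelope matrix (or a \code{bf_image}).
#' @param target,background logical masks or index vectors selecting the two
#'   (disjoint) regions.
#' @return list(cnr_db, defined): \code{defined} is FALSE (and \code{cnr_db}
#'   NA) when the target mean does not exceed the background mean or the
#'   denominator vanishes.
#' @examples
#' img <- matrix(0, 10, 10); img[4:6, 4:6] <- 10
#' # cnr(img, target, background)
#' @export
cnr <- function(image, target, background) {
  if (inherits(image, "bf_image")) image <- image$envelope
  it <- image[target]; ib <- image[background]
  if (length(it) < 2 || length(ib) < 2)
    stop("both regions need at least 2 pixels")
  num <- mean(it) - mean(ib)
  den <- sqrt(stats::var(it) * (length(it) - 1) / length(it) +
              stats::var(ib) * (length(ib) - 1) / length(ib))
  if (num <= 0 || den == 0)
    return(list(cnr_db = NA_real_, defined = FALSE))
  list(cnr_db = 20 * log10(num / den), defined = TRUE)
}

#' Field-of-view mask post-processing
#'
#' Blurs a binary field-of-view mask with a Gaussian filter (default standard
#' deviation 3 pixels) and multiplies it pixel-wise with the image, smoothly
#' suppressing everything outside the field of view.
#'
#' @param image numeric matrix.
#' @param mask 0/1 (or logical) matrix of the same shape.
#' @param blur_sd Gaussian standard deviation in pixels; 0 gives a hard mask.
#' @return the masked image.
#' @export
apply_fov_mask <- function(image, mask, blur_sd = 3) {
  if (!all(dim(image) == dim(mask))) stop("mask shape must match the image")
  if (blur_sd < 0) stop("blur_sd must be non-negative")
  mask <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (blur_sd > 0) mask <- as.matrix(EBImage::gblur(mask, sigma = blur_sd))
  image * mask
}

#' Localization error of known targets
#'
#' Distance from each true point to the nearest local envelope maximum above
#' the threshold.
#'
#' @param image a \code{bf_image} or envelope matrix.
#' @param true_points npts x 2 matrix of true positions (mm).
#' @param threshold_db acceptance threshold relative to the envelope max (dB).
#' @param grid required when \code{image} is a matrix.
#' @return list(errors (mm; Inf when no qualifying maximum), flagged).
#' @export
localization_error <- function(image, true_points, threshold_db = -20,
                               grid = NULL) {
  if (inherits(image, "bf_image")) { env <- image$envelope; grid <- image$grid }
  else env <- image
  stopifnot(inherits(grid, "imaging_grid"))
  true_points <- rbind(true_points)
  mx <- max(env)
  if (mx <= 0)
    return(list(errors = rep(Inf, nrow(true_points)), flagged = TRUE))
  thr <- mx * 10^(threshold_db / 20)
  m <- nrow(env); n <- ncol(env)
  ep <- env[c(1, 1:m, m), c(1, 1:n, n)]
  is_max <- env >= thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & env >= ep[di + 1 + 1:m, dj + 1 + 1:n]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(errors = rep(Inf, nrow(true_points)), flagged = TRUE))
  peaks <- grid_index_to_point(grid, idx[, 1], idx[, 2])
  errs <- apply(true_points, 1, function(p)
    min(sqrt((peaks[, 1] - p[1])^2 + (peaks[, 2] - p[2])^2)))
  list(errors = errs, flagged = any(!is.finite(errs)))
}
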