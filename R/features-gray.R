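#' Quantize a masked lesion to a fixed number of gray levels
#'
#' Converts an RGB image to ITU-R 601 luma and linearly rebins the in-mask
#' intensity range to `Ng` levels (`0 .. Ng-1`); the min--max is taken over
#' in-mask pixels only, and out-of-mask pixels are flagged ignored. All
#' histogram- and matrix-based texture families operate on this
#' representation.
#'
#' @param image H x W x 3 array in `[0, 1]`, or an H x W grayscale matrix.
#' @param mask Binary matrix of the same spatial size, non-empty.
#' @param Ng Number of gray levels (default 32).
#' @return A `dermaug_gray_lesion` list: `gray` (integer matrix, `NA` outside
#'   the mask), `mask`, `Ng`.
#' @export
quantize_and_mask <- function(image, mask, Ng = 32L) {
  gray <- if (is.matrix(image)) image else {
    check_rgb_image(image)
    rgb_to_gray(image)
  }
  mask <- mask > 0
  if (!any(mask)) stop_invalid("mask", "must contain at least one pixel")
  if (!all(dim(gray) == dim(mask))) stop_invalid("mask", "shape must match image")
  check_number(Ng, "Ng", min = 2, integerish = TRUE)
  v <- gray[mask]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(gray), ncol(gray))
  if (diff(rng) < .Machine$double.eps) {
    q[mask] <- 0L   # degenerate range maps to level 0
  } else {
    lev <- floor((gray[mask] - rng[1]) / (rng[2] - rng[1]) * Ng)
    q[mask] <- as.integer(pmin(lev, Ng - 1L))
  }
  structure(list(gray = q, mask = mask, Ng = as.integer(Ng)),
            class = "dermaug_gray_lesion")
}

# Lesion bounding box, out-of-mask pixels filled with the in-mask mean, on the
# raw (unquantized) luma scale. Shared by the wavelet / LBP / HOS / FDTA
# families which need a dense rectangular support.
lesion_bbox_filled <- function(image, mask) {
  gray <- if (is.matrix(image)) image else rgb_to_gray(image)
  mask <- mask > 0
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  sub <- gray[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  msk <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  sub[!msk] <- mean(sub[msk])
  list(gray = sub, mask = msk)
}
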