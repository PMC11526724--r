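# Geometric ABCD-rule features: asymmetry, border irregularity, colour count
# and diameter, computed from the binary lesion mask (and the image for C).

#' ABCD-rule geometric features of a lesion
#'
#' * `geo_assymetry` -- mean non-overlap fraction of the mask against its
#'   reflections across the two principal axes (PCA axes of the pixel cloud),
#'   in `[0, 1]`; 0 for a mirror-symmetric lesion.
#' * `geo_border` -- compactness \eqn{P^2 / (4 \pi A)} with the perimeter
#'   measured along the traced 8-connected boundary chain; 1 for a disk up to
#'   discretization.
#' * `geo_color` -- number of reference dermoscopy colours (white, red, light
#'   brown, dark brown, blue-gray, black) occupying more than 1% of lesion
#'   pixels, each pixel assigned to its nearest reference colour in RGB.
#' * `geo_diameter` -- maximum Feret diameter in pixels.
#'
#' @param mask Binary lesion mask (non-empty).
#' @param image H x W x 3 array in `[0, 1]`.
#' @return Named numeric vector of the 4 features.
#' @export
abcd_features <- function(mask, image) {
  mask <- mask > 0
  if (!any(mask)) stop_invalid("mask", "must be non-empty")
  check_rgb_image(image)

  pts <- which(mask, arr.ind = TRUE)  # (row, col)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  pc <- eigen(stats::cov(cen), symmetric = TRUE)$vectors

  # Asymmetry: reflect pixel centres across each principal axis and measure
  # the fraction that land outside the mask.
  asym <- vapply(1:2, function(ax) {
    u <- pc[, ax]  # axis direction; reflect across the axis => flip the
    # component along the orthogonal direction
    v <- pc[, 3 - ax]
    proj <- cen %*% v
    refl <- cen - 2 * drop(proj) %o% drop(v)
    rr <- round(refl[, 1] + ctr[1]); cc <- round(refl[, 2] + ctr[2])
    inside <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    hit <- logical(nrow(pts))
    hit[inside] <- mask[cbind(rr[inside], cc[inside])]
    1 - mean(hit)
  }, numeric(1))

  per <- chain_perimeter(mask)
  area <- sum(mask)
  border <- per^2 / (4 * pi * area)

  diameter <- feret_diameter(pts)

  refs <- rbind(white = c(1, 1, 1), red = c(0.8, 0.2, 0.2),
                light_brown = c(0.82, 0.6, 0.4), dark_brown = c(0.35, 0.2, 0.1),
                blue_gray = c(0.45, 0.5, 0.6), black = c(0.05, 0.05, 0.05))
  rgbm <- cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  d2 <- sapply(seq_len(nrow(refs)), function(k) {
    colSums((t(rgbm) - refs[k, ])^2)
  })
  assign_ <- max.col(-d2)
  occ <- tabulate(assign_, nbins = nrow(refs)) / nrow(rgbm)
  n_colors <- sum(occ > 0.01)

  c(geo_assymetry = mean(asym), geo_border = border,
    geo_color = n_colors, geo_diameter = diameter)
}

# Perimeter of the largest boundary chain: Moore-neighbour tracing with
# steps of 1 (4-neighbour) or sqrt(2) (diagonal).
chain_perimeter <- function(mask) {
  ct <- EBImage::ocontour(as_ebi(mask * 1))
  if (!length(ct)) return(0)
  ct <- ct[[which.max(vapply(ct, nrow, integer(1)))]]
  if (nrow(ct) < 2) return(4)  # single pixel
  d <- sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), ])^2))
  sum(d)
}

# Maximum Feret diameter from the convex hull of mask pixel centres.
feret_diameter <- function(pts) {
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[hull, , drop = FALSE]
  if (nrow(hp) == 1) return(1)
  max(stats::dist(hp)) + 1  # +1: pixel extent, so a single row of n pixels has diameter n
}

#' Colour-distribution statistics of a masked lesion
#'
#' Mean, standard deviation, skewness and kurtosis of the in-mask pixel
#' values in the requested colour space. For `CIELab`, `CIELuv` and `YCrCb`
#' the four statistics are computed per channel (12 features each); for `RGB`
#' and `HSV` they are pooled over all in-mask channel values (4 features
#' each), giving the catalogue total of 44 colour features.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param mask Binary mask, non-empty.
#' @param space One of `"RGB"`, `"HSV"`, `"CIELab"`, `"CIELuv"`, `"YCrCb"`.
#' @return Named numeric vector.
#' @export
color_stats <- function(image, mask, space) {
  check_rgb_image(image)
  mask <- mask > 0
  if (!any(mask)) stop_invalid("mask", "must be non-empty")
  if (!space %in% c("RGB", "HSV", "CIELab", "CIELuv", "YCrCb")) {
    stop_invalid("space", sprintf("unknown colour space '%s'", space))
  }
  rgbm <- rbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  four <- function(x) c(mean = mean(x),
                        std = if (length(x) > 1) sd(x) else 0,
                        skewness = moment_skewness(x),
                        kurtosis = moment_kurtosis(x))
  if (space == "RGB") {
    v <- four(as.vector(rgbm))
    names(v) <- paste0("rgb_", names(v))
    return(v)
  }
  if (space == "HSV") {
    hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
    v <- four(as.vector(hsv))
    names(v) <- paste0("hsv_", names(v))
    return(v)
  }
  channels <- switch(space,
    CIELab = t(grDevices::convertColor(t(rgbm), from = "sRGB", to = "Lab")),
    CIELuv = t(grDevices::convertColor(t(rgbm), from = "sRGB", to = "Luv")),
    YCrCb = {
      # ITU-R 601 full-range YCrCb
      y <- 0.299 * rgbm[1, ] + 0.587 * rgbm[2, ] + 0.114 * rgbm[3, ]
      cr <- 0.5 + 0.713 * (rgbm[1, ] - y)
      cb <- 0.5 + 0.564 * (rgbm[3, ] - y)
      rbind(y, cr, cb)
    })
  ch_names <- switch(space, CIELab = c("L", "a", "b"),
                     CIELuv = c("L", "u", "v"), YCrCb = c("Y", "Cr", "Cb"))
  prefix <- switch(space, CIELab = "lab", CIELuv = "luv", YCrCb = "ycrcb")
  out <- c()
  for (k in 1:3) {
    v <- four(channels[k, ])
    names(v) <- sprintf("%s_%s_%s", prefix, ch_names[k], names(v))
    out <- c(out, v)
  }
  out
}
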