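#' Preprocessing configuration
#'
#' Parameters for lesion preprocessing: the common resize target and the
#' oriented black-hat hair detector. Defaults follow thin (1--3 px) hair
#' strokes at the 224 x 224 working resolution: linear structuring elements at
#' six orientations and two lengths, thresholded at 10 gray levels (0--255
#' scale), with fast-marching-style inpainting of radius 3 px.
#'
#' @param target_size Output side length in pixels (default 224).
#' @param blackhat_kernel_lengths Lengths (px, >= 3) of the linear structuring
#'   elements.
#' @param blackhat_orientations Orientations in degrees, in `[0, 180)`.
#' @param hair_threshold Black-hat response threshold in gray levels (0--255).
#' @param inpaint_radius Neighbourhood radius (px) used when filling masked
#'   pixels.
#' @return An object of class `dermaug_preprocess_config`.
#' @export
preprocess_config <- function(target_size = 224L,
                              blackhat_kernel_lengths = c(9L, 15L),
                              blackhat_orientations = seq(0, 150, by = 30),
                              hair_threshold = 10,
                              inpaint_radius = 3L) {
  check_number(target_size, "target_size", min = 1, integerish = TRUE)
  if (any(blackhat_kernel_lengths < 3)) {
    stop_invalid("blackhat_kernel_lengths", "all lengths must be >= 3 px")
  }
  if (any(blackhat_orientations < 0 | blackhat_orientations >= 180)) {
    stop_invalid("blackhat_orientations", "must be in [0, 180)")
  }
  check_number(hair_threshold, "hair_threshold", min = 0)
  check_number(inpaint_radius, "inpaint_radius", min = 1, integerish = TRUE)
  structure(
    list(target_size = as.integer(target_size),
         blackhat_kernel_lengths = as.integer(blackhat_kernel_lengths),
         blackhat_orientations = blackhat_orientations,
         hair_threshold = hair_threshold,
         inpaint_radius = as.integer(inpaint_radius)),
    class = "dermaug_preprocess_config"
  )
}

#' Resize an RGB image (and optionally a mask) to the working resolution
#'
#' Direct bilinear resampling to `target_size` x `target_size`; the aspect
#' ratio is not preserved and no padding is added.
#'
#' @param image H x W x 3 numeric array in `[0, 1]`.
#' @param config A [preprocess_config()].
#' @return Resized H' x W' x 3 array.
#' @export
resize_image <- function(image, config = preprocess_config()) {
  check_rgb_image(image)
  s <- config$target_size
  out <- array(0, dim = c(s, s, 3))
  for (ch in 1:3) {
    out[, , ch] <- from_ebi(EBImage::resize(as_ebi(image[, , ch]), w = s, h = s))
  }
  clamp01(out)
}

# Resize a binary mask with nearest-equivalent thresholding.
resize_mask <- function(mask, target_size) {
  m <- from_ebi(EBImage::resize(as_ebi(mask * 1), w = target_size, h = target_size))
  (m >= 0.5) * 1L
}

#' Remove hair strokes by oriented black-hat morphology and inpainting
#'
#' Dark curvilinear artifacts are detected as the union, over orientations and
#' kernel lengths, of thresholded morphological black-hat responses of the
#' grayscale (ITU-R 601 luma) image with linear structuring elements; detected
#' pixels are replaced by a fast-marching-style inpainting that fills the mask
#' from its boundary inward, each unknown pixel as an inverse-distance-weighted
#' average of already-known neighbours. Pixels outside the hair mask are
#' returned unchanged.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param config A [preprocess_config()].
#' @return List with `clean_image` and binary `hair_mask`.
#' @export
remove_hair <- function(image, config = preprocess_config()) {
  check_rgb_image(image)
  gray255 <- rgb_to_gray(image) * 255
  # Responses are thresholded on both the raw luma and a lightly smoothed
  # copy: single-pixel noise only fires on the raw image, smoothed object
  # boundaries only on the smoothed one; true hair strokes fire on both.
  smooth <- from_ebi(EBImage::gblur(as_ebi(gray255), sigma = 1))
  hair <- matrix(FALSE, nrow(gray255), ncol(gray255))
  for (len in config$blackhat_kernel_lengths) {
    for (ang in config$blackhat_orientations) {
      brush <- line_brush(len, ang)
      bh_raw <- gray_morph(gray_morph(gray255, brush, max), brush, min) - gray255
      bh_smooth <- gray_morph(gray_morph(smooth, brush, max), brush, min) - smooth
      hair <- hair | (bh_raw > config$hair_threshold &
                        bh_smooth > config$hair_threshold)
    }
  }
  clean <- image
  if (any(hair)) {
    for (ch in 1:3) {
      clean[, , ch] <- inpaint_march(image[, , ch], hair, config$inpaint_radius)
    }
  }
  list(clean_image = clamp01(clean), hair_mask = hair * 1L)
}

# Grayscale flat-structuring-element morphology: `op = max` gives dilation,
# `op = min` erosion; out-of-frame support is ignored (identity padding).
gray_morph <- function(m, brush, op) {
  h <- nrow(m); w <- ncol(m)
  ctr <- (dim(brush) + 1) %/% 2
  offs <- which(brush > 0, arr.ind = TRUE)
  elt <- if (identical(op, max)) pmax else pmin
  out <- matrix(if (identical(op, max)) -Inf else Inf, h, w)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1] - ctr[1]; dc <- offs[k, 2] - ctr[2]
    rr <- max(1, 1 - dr):min(h, h - dr)
    cc <- max(1, 1 - dc):min(w, w - dc)
    out[rr, cc] <- elt(out[rr, cc], m[rr + dr, cc + dc])
  }
  out[!is.finite(out)] <- m[!is.finite(out)]
  out
}

# Linear structuring element of `len` px at `angle` degrees, rasterized by
# stepping along the line through the centre of an odd-sized square.
line_brush <- function(len, angle) {
  half <- (len - 1) / 2
  th <- angle * pi / 180
  t_ <- seq(-half, half, by = 0.5)
  xs <- round(t_ * cos(th)); ys <- round(-t_ * sin(th))
  ext <- max(abs(c(xs, ys)))
  b <- matrix(0L, 2 * ext + 1, 2 * ext + 1)
  b[cbind(ys + ext + 1, xs + ext + 1)] <- 1L
  # trim to the tight odd-sized bounding box (degenerate kernels upset the
  # morphology backend otherwise)
  rows <- range(which(rowSums(b) > 0)); cols <- range(which(colSums(b) > 0))
  b[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
}

# Distance-ordered inpainting: unknown pixels are processed in increasing
# distance from the known region and filled with 1/(d + 1) weighted averages
# of known pixels in a (2r+1)^2 window.
inpaint_march <- function(channel, mask, radius) {
  if (!any(mask)) return(channel)
  h <- nrow(channel); w <- ncol(channel)
  dm <- from_ebi(EBImage::distmap(as_ebi(mask * 1)))
  idx <- which(mask)
  ord <- idx[order(dm[idx], (seq_along(dm))[idx])]
  known <- !mask
  out <- channel
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr != 0 | offs$dc != 0, ]
  wgt <- 1 / (sqrt(offs$dr^2 + offs$dc^2) + 1)
  for (p in ord) {
    r <- ((p - 1L) %% h) + 1L
    cl <- ((p - 1L) %/% h) + 1L
    acc <- 0; wsum <- 0
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dr[k]; cc <- cl + offs$dc[k]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && known[rr, cc]) {
        acc <- acc + wgt[k] * out[rr, cc]
        wsum <- wsum + wgt[k]
      }
    }
    out[r, cl] <- if (wsum > 0) acc / wsum else mean(channel[known])
    known[r, cl] <- TRUE
  }
  out
}

#' Fallback lesion segmentation
#'
#' Otsu threshold on the grayscale image (lesion assumed darker than the
#' surrounding skin), keep the largest connected component, and fill holes.
#' This is a deliberately simple segmenter for synthetic fixtures; real
#' pipelines are expected to supply externally produced masks.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @return Binary mask matrix (1 = lesion).
#' @export
segment_fallback <- function(image) {
  check_rgb_image(image)
  gray <- rgb_to_gray(image)
  if (max(gray) - min(gray) < 1e-8) {
    abort("segmentation-empty: image has no contrast", class = "dermaug_segmentation_error")
  }
  thr <- EBImage::otsu(as_ebi(gray), range = c(0, 1))
  fg <- gray < thr
  if (!any(fg)) {
    abort("segmentation-empty: no foreground component", class = "dermaug_segmentation_error")
  }
  lab <- from_ebi(EBImage::bwlabel(as_ebi(fg * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  comp <- (lab == keep)
  filled <- from_ebi(EBImage::fillHull(as_ebi(comp * 1)))
  (filled > 0.5) * 1L
}
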