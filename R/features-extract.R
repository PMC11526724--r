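texture_families <- function() {
  c("FOS", "GLCM", "GLDS", "GLRLM", "GLSZM", "LBP", "SFM",
    "NGTDM_KING", "HOS", "FDTA", "DWT", "WP")
}

#' Extract one texture-feature family from a quantized lesion
#'
#' Dispatches to the named family implementation. Histogram/matrix families
#' (FOS, GLCM, GLDS, GLRLM, GLSZM, NGTDM_KING) run on the quantized in-mask
#' gray levels; signal families (LBP, SFM, HOS, FDTA, DWT, WP) run on the
#' mean-filled lesion bounding box on the raw luma scale. Lesions smaller
#' than a family's minimum support raise an insufficient-support error naming
#' the family.
#'
#' @param gl A `dermaug_gray_lesion` from [quantize_and_mask()]. Families
#'   that need the raw-scale bounding box reconstruct it from the `raw`
#'   attribute set by [extract_all()]; when called directly, pass `raw_gray`.
#' @param family One of `r paste(texture_families(), collapse = ", ")`.
#' @param raw_gray Optional raw grayscale matrix (same shape as the mask) for
#'   the signal families; defaults to the quantized levels rescaled to
#'   `[0, 1]`.
#' @return Named numeric vector (one slice of the feature catalogue).
#' @export
extract_texture_family <- function(gl, family, raw_gray = NULL) {
  stopifnot(inherits(gl, "dermaug_gray_lesion"))
  family <- match.arg(family, texture_families())
  if (family %in% c("FOS", "GLCM", "GLDS", "GLRLM", "GLSZM", "NGTDM_KING")) {
    return(switch(family,
      FOS = fos_features(gl),
      GLCM = glcm_features(gl),
      GLDS = glds_features(gl),
      GLRLM = glrlm_features(gl),
      GLSZM = glszm_features(gl),
      NGTDM_KING = king_features(gl)))
  }
  raw <- raw_gray
  if (is.null(raw)) {
    raw <- matrix(0, nrow(gl$gray), ncol(gl$gray))
    raw[gl$mask] <- gl$gray[gl$mask] / max(1L, gl$Ng - 1L)
  }
  box <- lesion_bbox_filled(raw, gl$mask)
  switch(family,
    LBP = lbp_features(box),
    SFM = sfm_features(box),
    HOS = hos_features(box),
    FDTA = fdta_features(box),
    DWT = dwt_features(box),
    WP = wp_features(box))
}

#' Extract the full handcrafted feature catalogue from a masked lesion
#'
#' Concatenates the ABCD geometric features, the five colour-space statistic
#' blocks and the twelve texture families, in that fixed order, with
#' canonical feature names. Errors from a family are propagated with the
#' family name attached.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param mask Binary lesion mask.
#' @param Ng Gray levels for the quantized families (default 32).
#' @param families Texture families to include (default all 12).
#' @return A one-row tibble of named features.
#' @examples
#' les <- generate_lesion_image(lesion_spec(image_size = 96, seed = 3))
#' fv <- extract_all(les$image, les$mask)
#' ncol(fv)
#' @export
extract_all <- function(image, mask, Ng = 32L, families = texture_families()) {
  check_rgb_image(image)
  gl <- quantize_and_mask(image, mask, Ng)
  raw <- rgb_to_gray(image)
  out <- abcd_features(mask, image)
  for (space in c("RGB", "HSV", "CIELab", "CIELuv", "YCrCb")) {
    out <- c(out, color_stats(image, mask, space))
  }
  for (fam in families) {
    vals <- tryCatch(extract_texture_family(gl, fam, raw_gray = raw),
                     error = function(e) {
                       abort(sprintf("family %s: %s", fam, conditionMessage(e)),
                             class = class(e)[1], parent = e)
                     })
    out <- c(out, vals)
  }
  stopifnot(!anyDuplicated(names(out)))
  as_tibble(as.list(out))
}
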