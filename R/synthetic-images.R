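#' Specification for a synthetic dermoscopy-style lesion image
#'
#' Describes a single simulated skin lesion: an ellipse with a sinusoidal
#' radial perturbation (border waviness) and a one-sided radial scaling
#' (asymmetry), rendered on a noisy skin-toned background, optionally crossed
#' by dark hair strokes. The knobs map one-to-one onto the A (asymmetry) and
#' B (border) components of the ABCD screening rule, so downstream feature
#' extractors can be exercised against known ground truth.
#'
#' @param image_size Side length in pixels of the square image (>= 64).
#' @param eccentricity Axis ratio of the base ellipse (>= 1; 1 = circle).
#' @param asymmetry_coeff One-sided radial scaling in `[0, 1]`; 0 gives a
#'   mirror-symmetric lesion.
#' @param border_waviness Numeric length-2 vector `(amplitude_px, frequency)`;
#'   a sinusoidal perturbation of the lesion radius with that amplitude (in
#'   pixels) and integer number of cycles around the boundary.
#' @param lesion_palette List of RGB triplets in `[0, 1]`; the first entry is
#'   the base lesion colour, the rest are used for variegation spots.
#' @param variegation_spots Number of differently coloured spots (>= 0).
#' @param texture_noise_sigma Gaussian pixel noise inside the lesion, in
#'   gray-level units on the 0--255 scale.
#' @param n_hairs Number of dark hair strokes drawn over the image (>= 0).
#' @param class_label 0 (not-melanoma) or 1 (melanoma).
#' @param seed Integer seed; the generator is a pure function of the spec.
#'
#' @return An object of class `dermaug_lesion_spec`.
#' @seealso [generate_lesion_image()]
#' @export
lesion_spec <- function(image_size = 224L,
                        eccentricity = 1,
                        asymmetry_coeff = 0,
                        border_waviness = c(0, 0),
                        lesion_palette = list(c(0.35, 0.22, 0.15)),
                        variegation_spots = 0L,
                        texture_noise_sigma = 4,
                        n_hairs = 0L,
                        class_label = 0L,
                        seed = 1L) {
  check_number(image_size, "image_size", min = 64, integerish = TRUE)
  check_number(eccentricity, "eccentricity", min = 1)
  check_number(asymmetry_coeff, "asymmetry_coeff", min = 0, max = 1)
  if (!is.numeric(border_waviness) || length(border_waviness) != 2L ||
      any(border_waviness < 0)) {
    stop_invalid("border_waviness", "must be c(amplitude_px, frequency), both >= 0")
  }
  if (!is.list(lesion_palette) || !length(lesion_palette) ||
      !all(vapply(lesion_palette, function(p) is.numeric(p) && length(p) == 3L &&
                    all(p >= 0 & p <= 1), logical(1)))) {
    stop_invalid("lesion_palette", "must be a non-empty list of RGB triplets in [0, 1]")
  }
  check_number(variegation_spots, "variegation_spots", min = 0, integerish = TRUE)
  check_number(texture_noise_sigma, "texture_noise_sigma", min = 0)
  check_number(n_hairs, "n_hairs", min = 0, integerish = TRUE)
  if (!class_label %in% c(0L, 1L)) stop_invalid("class_label", "must be 0 or 1")
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(image_size = as.integer(image_size), eccentricity = eccentricity,
         asymmetry_coeff = asymmetry_coeff, border_waviness = border_waviness,
         lesion_palette = lesion_palette,
         variegation_spots = as.integer(variegation_spots),
         texture_noise_sigma = texture_noise_sigma, n_hairs = as.integer(n_hairs),
         class_label = as.integer(class_label), seed = as.integer(seed)),
    class = "dermaug_lesion_spec"
  )
}

#' Generate a synthetic lesion image with its ground-truth mask
#'
#' Renders the lesion described by a [lesion_spec()]: a constant beige skin
#' background with Gaussian noise, an elliptical lesion whose polar radius is
#' modulated by the waviness and asymmetry knobs, optional variegation spots
#' drawn from the palette, in-lesion texture noise, and optional anti-aliased
#' quadratic Bezier hair strokes 1--3 px wide. Hair strokes are drawn last
#' from an independent RNG stream, so the image with `n_hairs = 0` and the
#' image with hairs differ only on stroke pixels.
#'
#' @param spec A `dermaug_lesion_spec`.
#' @return A `dermaug_lesion` list: `image` (H x W x 3 array in `[0, 1]`),
#'   `mask` (binary matrix, the exact ground-truth lesion region),
#'   `hair_mask` (binary matrix of stroke pixels), `label`, and `spec`.
#' @examples
#' les <- generate_lesion_image(lesion_spec(image_size = 96, seed = 7))
#' mean(les$mask)  # lesion area fraction
#' @export
generate_lesion_image <- function(spec) {
  if (!inherits(spec, "dermaug_lesion_spec")) {
    stop_invalid("spec", "must be created by lesion_spec()")
  }
  s <- spec$image_size
  base <- with_seed(spec$seed, {
    cx <- s / 2 + runif(1, -s * 0.02, s * 0.02)
    cy <- s / 2 + runif(1, -s * 0.02, s * 0.02)
    theta0 <- runif(1, 0, 2 * pi)   # ellipse orientation
    phi <- runif(1, 0, 2 * pi)      # waviness phase
    asym_dir <- runif(1, 0, 2 * pi) # direction of the one-sided bulge

    yy <- matrix(seq_len(s), s, s)          # row index
    xx <- matrix(seq_len(s), s, s, byrow = TRUE)
    dx <- xx - cx
    dy <- yy - cy
    ang <- atan2(dy, dx)
    r <- sqrt(dx^2 + dy^2)

    # Ellipse boundary radius: semi-axes a = r0*sqrt(e), b = r0/sqrt(e).
    r0 <- s * 0.28
    a <- r0 * sqrt(spec$eccentricity)
    b <- r0 / sqrt(spec$eccentricity)
    ca <- cos(ang - theta0)
    sa <- sin(ang - theta0)
    r_ell <- (a * b) / sqrt((b * ca)^2 + (a * sa)^2)

    wav <- 1 + if (spec$border_waviness[1] > 0 && spec$border_waviness[2] > 0) {
      spec$border_waviness[1] / r0 *
        sin(spec$border_waviness[2] * ang + phi)
    } else 0
    asym <- 1 + spec$asymmetry_coeff * 0.6 * pmax(0, cos(ang - asym_dir))
    mask <- r <= r_ell * wav * asym

    skin <- c(0.87, 0.70, 0.59)
    img <- array(0, dim = c(s, s, 3))
    for (ch in 1:3) {
      img[, , ch] <- skin[ch] + matrix(rnorm(s * s, 0, 0.015), s, s)
    }
    base_col <- spec$lesion_palette[[1]]
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[mask] <- base_col[ch]
      img[, , ch] <- layer
    }

    if (spec$variegation_spots > 0) {
      inside <- which(mask, arr.ind = TRUE)
      pal <- spec$lesion_palette
      for (i in seq_len(spec$variegation_spots)) {
        ctr <- inside[sample.int(nrow(inside), 1L), ]
        rad <- runif(1, 0.04, 0.10) * r0
        col <- pal[[if (length(pal) > 1) 2L + (i - 1L) %% (length(pal) - 1L) else 1L]]
        spot <- (yy - ctr[1])^2 + (xx - ctr[2])^2 <= rad^2 & mask
        for (ch in 1:3) {
          layer <- img[, , ch]
          layer[spot] <- col[ch]
          img[, , ch] <- layer
        }
      }
    }

    if (spec$texture_noise_sigma > 0) {
      n_in <- sum(mask)
      for (ch in 1:3) {
        layer <- img[, , ch]
        layer[mask] <- layer[mask] + rnorm(n_in, 0, spec$texture_noise_sigma / 255)
        img[, , ch] <- layer
      }
    }
    list(img = clamp01(img), mask = mask)
  })

  hair_mask <- matrix(FALSE, s, s)
  img <- base$img
  if (spec$n_hairs > 0) {
    drawn <- with_seed(spec$seed + 10007L,
                       draw_hairs(img, spec$n_hairs))
    img <- drawn$img
    hair_mask <- drawn$hair_mask
  }

  structure(
    list(image = img, mask = base$mask * 1L, hair_mask = hair_mask * 1L,
         label = spec$class_label, spec = spec),
    class = "dermaug_lesion"
  )
}

# Dark anti-aliased quadratic Bezier strokes, 1-3 px wide, spanning the frame.
draw_hairs <- function(img, n_hairs) {
  s <- dim(img)[1]
  hair_mask <- matrix(FALSE, s, s)
  alpha_acc <- matrix(0, s, s)
  for (h in seq_len(n_hairs)) {
    p0 <- runif(2, 1, s)
    p2 <- runif(2, 1, s)
    p1 <- (p0 + p2) / 2 + runif(2, -s * 0.25, s * 0.25)
    w <- runif(1, 1, 3)
    tt <- seq(0, 1, length.out = 4L * s)
    bx <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
    by <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
    reach <- ceiling(w / 2 + 1)
    for (i in seq_along(tt)) {
      r0 <- round(by[i]); c0 <- round(bx[i])
      if (r0 < 1 - reach || r0 > s + reach || c0 < 1 - reach || c0 > s + reach) next
      rr <- seq(max(1, r0 - reach), min(s, r0 + reach))
      cc <- seq(max(1, c0 - reach), min(s, c0 + reach))
      for (r in rr) for (cl in cc) {
        d <- sqrt((r - by[i])^2 + (cl - bx[i])^2)
        a <- clamp01(w / 2 + 0.5 - d)
        if (a > alpha_acc[r, cl]) alpha_acc[r, cl] <- a
      }
    }
  }
  hair_col <- c(0.12, 0.08, 0.05)
  hair_mask <- alpha_acc > 0
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - alpha_acc) + hair_col[ch] * alpha_acc
  }
  list(img = clamp01(img), hair_mask = hair_mask)
}

#' Fixed 4 x 4 gray-level fixture for texture-operator oracles
#'
#' A constant, documented 4 x 4 integer matrix with gray levels `{0, 1, 2, 3}`
#' used by the brute-force texture oracles in the test suite. The pattern is
#' the classic co-occurrence textbook example.
#'
#' @return Integer matrix, 4 x 4, values in 0..3.
#' @export
toy_gray_matrix <- function() {
  matrix(c(0L, 0L, 1L, 1L,
           0L, 0L, 1L, 1L,
           0L, 2L, 2L, 2L,
           2L, 2L, 3L, 3L),
         nrow = 4, byrow = TRUE)
}
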