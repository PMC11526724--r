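# Shared fixtures, built in code. Lesions are cached per test run because
# several files reuse the same spec.

.fixture_env <- new.env(parent = emptyenv())

fixture_lesion <- function(key = "disk224", ...) {
  if (is.null(.fixture_env[[key]])) {
    spec <- switch(key,
      disk224 = lesion_spec(image_size = 224, seed = 11),
      hairy224 = lesion_spec(image_size = 224, seed = 11, n_hairs = 10),
      disk96 = lesion_spec(image_size = 96, seed = 7),
      textured224 = lesion_spec(
        image_size = 224, seed = 3, variegation_spots = 3,
        texture_noise_sigma = 8,
        lesion_palette = list(c(0.35, 0.22, 0.15), c(0.2, 0.12, 0.08),
                              c(0.55, 0.35, 0.2))),
      stop("unknown fixture key"))
    .fixture_env[[key]] <- generate_lesion_image(spec)
  }
  .fixture_env[[key]]
}

# Quantized gray lesion over the full 4x4 toy matrix (Ng = 4, identity
# rebinning since values already span 0..3).
toy_gl <- function() {
  quantize_and_mask(toy_gray_matrix() / 3, matrix(1, 4, 4), Ng = 4)
}

# Reference half-disk mask (left half of a disk), for asymmetry checks.
half_disk_mask <- function(n = 101, r = 40) {
  ctr <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  ((yy - ctr)^2 + (xx - ctr)^2 <= r^2) & (xx <= ctr)
}

disk_mask <- function(n = 101, r = 40) {
  ctr <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  (yy - ctr)^2 + (xx - ctr)^2 <= r^2
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Flat RGB image of the given gray value.
flat_image <- function(n, value = 0.5) array(value, dim = c(n, n, 3))
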