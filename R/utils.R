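# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's RNG
# state is restored afterwards so generators are pure functions of their spec.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_invalid <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "dermaug_validation_error")
}

stop_capability <- function(what, msg) {
  abort(sprintf("capability `%s` unavailable: %s", what, msg),
        class = "dermaug_capability_error")
}

check_number <- function(x, field, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(field, "must be a single finite number")
  }
  if (x < min || x > max) {
    stop_invalid(field, sprintf("must be in [%s, %s]", format(min), format(max)))
  }
  if (integerish && x != round(x)) stop_invalid(field, "must be an integer")
  x
}

# ITU-R 601 luma in [0, 1] from an H x W x 3 array in [0, 1].
rgb_to_gray <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

check_rgb_image <- function(image, field = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L ||
      any(dim(image)[1:2] < 1L)) {
    stop_invalid(field, "must be a non-empty H x W x 3 numeric array")
  }
  invisible(image)
}

# Skewness/kurtosis with the zero-variance convention: both map to 0 when the
# standard deviation is 0, so degenerate lesions never emit NaN.
moment_skewness <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean(((x - mean(x)) / s)^3)
}

moment_kurtosis <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean(((x - mean(x)) / s)^4)
}

# Shannon entropy (nats) of a probability vector; 0 log 0 := 0.
entropy_nat <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log(p))
}

# EBImage stores images as (x, y); native matrices here are (row = y, col = x).
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

clamp01 <- function(x) pmin(pmax(x, 0), 1)
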