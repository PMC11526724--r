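# Untrained 50-layer residual backbone for image embeddings.
#
# A full ResNet-50 forward pass (7x7 stem, 3-4-6-3 bottleneck stages,
# expansion 4, global average pooling) implemented with im2col convolutions
# on BLAS matrix products. Weights are He-initialised from a fixed seed and
# no training is performed: the adapter exists to provide the 2048-dim
# embedding contract without any deep-learning runtime or weight download.
# Batch-normalization layers are identity at initialisation (unit scale,
# zero shift, unit running variance), so they are folded away.

conv2d <- function(x, W, stride = 1L, pad = 0L) {
  # x: H x W x C, W: kh x kw x C x F
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  h <- dim(x)[1]; w <- dim(x)[2]
  if (pad > 0) {
    xp <- array(0, dim = c(h + 2 * pad, w + 2 * pad, Cin))
    xp[pad + seq_len(h), pad + seq_len(w), ] <- x
    x <- xp
    h <- h + 2 * pad; w <- w + 2 * pad
  }
  oh <- (h - kh) %/% stride + 1L
  ow <- (w - kw) %/% stride + 1L
  # im2col: rows = output positions, cols = kh*kw*Cin patch entries
  ri <- (seq_len(oh) - 1L) * stride
  ci <- (seq_len(ow) - 1L) * stride
  col <- matrix(0, oh * ow, kh * kw * Cin)
  k <- 1L
  for (c_ in seq_len(Cin)) {
    ch <- x[, , c_]
    for (j in seq_len(kw)) for (i in seq_len(kh)) {
      col[, k] <- ch[outer(ri + i, (ci + j - 1L) * h, "+")]
      k <- k + 1L
    }
  }
  Wm <- matrix(W, kh * kw * Cin, Cout)  # filled in (kh, kw, Cin) order
  # reorder rows of Wm to match col's (kh within kw within Cin) order
  perm <- as.vector(outer(seq_len(kh), (seq_len(kw) - 1L) * kh, "+"))
  perm <- as.vector(outer(perm, (seq_len(Cin) - 1L) * kh * kw, "+"))
  out <- col %*% Wm[perm, , drop = FALSE]
  array(out, dim = c(oh, ow, Cout))
}

maxpool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  h <- dim(x)[1]; w <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(-Inf, dim = c(h + 2 * pad, w + 2 * pad, C))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  oh <- (h + 2 * pad - k) %/% stride + 1L
  ow <- (w + 2 * pad - k) %/% stride + 1L
  out <- array(-Inf, dim = c(oh, ow, C))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sl <- xp[seq(i, by = stride, length.out = oh),
             seq(j, by = stride, length.out = ow), , drop = FALSE]
    out <- pmax(out, sl)
  }
  out
}

relu <- function(x) { x[x < 0] <- 0; x }

he_weights <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

bottleneck <- function(x, cin, cmid, stride) {
  cout <- 4L * cmid
  w1 <- he_weights(1L, 1L, cin, cmid)
  w2 <- he_weights(3L, 3L, cmid, cmid)
  w3 <- he_weights(1L, 1L, cmid, cout)
  shortcut <- if (cin != cout || stride != 1L) {
    conv2d(x, he_weights(1L, 1L, cin, cout), stride = stride)
  } else x
  y <- relu(conv2d(x, w1))
  y <- relu(conv2d(y, w2, stride = stride, pad = 1L))
  y <- conv2d(y, w3)
  relu(y + shortcut)
}

resnet50_forward <- function(image) {
  x <- relu(conv2d(image, he_weights(7L, 7L, 3L, 64L), stride = 2L, pad = 3L))
  x <- maxpool2d(x)
  stages <- list(c(3L, 64L), c(4L, 128L), c(6L, 256L), c(3L, 512L))
  cin <- 64L
  for (s in seq_along(stages)) {
    n_blocks <- stages[[s]][1]; cmid <- stages[[s]][2]
    for (b in seq_len(n_blocks)) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      x <- bottleneck(x, cin, cmid, stride)
      cin <- 4L * cmid
    }
  }
  apply(x, 3, mean)  # global average pooling -> 2048
}

#' Image embeddings from an untrained 50-layer residual backbone
#'
#' Runs each 224 x 224 x 3 image through a randomly initialised (seeded,
#' untrained) ResNet-50 and returns the activations of the final global
#' average pooling layer, a 2048-dimensional vector per image. The weight
#' source is configurable through `weights_seed`; identical seeds give
#' identical embeddings.
#'
#' @param images A list of H x W x 3 arrays (H = W = 224), or a single array.
#' @param backbone_id Currently only `"resnet50_random"`.
#' @param weights_seed Seed for the He-initialised weights.
#' @return Numeric matrix, one 2048-long row per image.
#' @export
extract_embeddings_adapter <- function(images, backbone_id = "resnet50_random",
                                       weights_seed = 42L) {
  if (!identical(backbone_id, "resnet50_random")) {
    stop_capability("backbone", sprintf("backbone '%s' is not available", backbone_id))
  }
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  for (im in images) {
    check_rgb_image(im)
    if (!all(dim(im)[1:2] == 224L)) {
      stop_invalid("images", "each image must be 224 x 224 x 3")
    }
  }
  out <- matrix(0, length(images), 2048L)
  for (i in seq_along(images)) {
    out[i, ] <- with_seed(weights_seed, resnet50_forward(images[[i]]))
  }
  out
}
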