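# Periodized filter-bank wavelet decompositions. Two filter banks are
# shipped: the biorthogonal 3.3 pair for the three-level discrete wavelet
# transform and coiflet-1 for the depth-3 wavelet packet tree. The
# decimated periodic convolution uses the convention
#   y[k] = sum_m f[m] x[(2k + 1 - m + L/2 - 1) mod n],  k = 0..n/2-1,
# which matches the standard periodization mode of common wavelet toolboxes,
# so subband values can be cross-checked against independent references.

wavelet_filters <- function(name) {
  switch(name,
    "bior3.3" = list(
      lo = c(0.06629126073623882, -0.1988737822087165, -0.15467960838455727,
             0.9943689110435826, 0.9943689110435826, -0.15467960838455727,
             -0.1988737822087165, 0.06629126073623882),
      hi = c(0, 0, -0.1767766952966369, 0.5303300858899106,
             -0.5303300858899106, 0.1767766952966369, 0, 0)),
    "coif1" = list(
      lo = c(-0.01565572813579199, -0.07273261951252645, 0.3848648468648578,
             0.8525720202116003, 0.3378976624574818, -0.07273261951252645),
      hi = c(0.07273261951252645, 0.3378976624574818, -0.8525720202116003,
             0.3848648468648578, 0.07273261951252645, -0.01565572813579199)),
    stop_invalid("wavelet", sprintf("unknown filter bank '%s'", name))
  )
}

# One decimated periodic convolution of each row of `m` with filter `f`.
dwt_rows <- function(m, f) {
  n <- ncol(m)
  L <- length(f)
  half <- n %/% 2
  out <- matrix(0, nrow(m), half)
  for (k in seq_len(half)) {
    idx <- ((2 * k - seq_len(L) + L / 2 - 1) %% n) + 1
    out[, k] <- m[, idx, drop = FALSE] %*% f
  }
  out
}

# Single-level 2-D DWT: returns LL, LH (detail along columns), HL, HH.
dwt2 <- function(m, filters) {
  lo_r <- dwt_rows(m, filters$lo)
  hi_r <- dwt_rows(m, filters$hi)
  list(ll = t(dwt_rows(t(lo_r), filters$lo)),
       lh = t(dwt_rows(t(lo_r), filters$hi)),
       hl = t(dwt_rows(t(hi_r), filters$lo)),
       hh = t(dwt_rows(t(hi_r), filters$hi)))
}

# Pad to the next multiple of 2^levels by symmetric reflection.
pad_dyadic <- function(m, levels) {
  mult <- 2^levels
  target_h <- ceiling(nrow(m) / mult) * mult
  target_w <- ceiling(ncol(m) / mult) * mult
  reflect_to <- function(v, target) {
    while (length(v) < target) v <- c(v, rev(v))[seq_len(min(target, 2 * length(v)))]
    v[seq_len(target)]
  }
  m <- m[reflect_to(seq_len(nrow(m)), target_h), , drop = FALSE]
  m[, reflect_to(seq_len(ncol(m)), target_w), drop = FALSE]
}

# Mean and std of absolute coefficients in each detail subband of a 3-level
# DWT. Subband letters: a = approximation, d = detail; e.g. `ad` is low-pass
# rows / high-pass columns.
dwt_features <- function(box, wavelet = "bior3.3", levels = 3L) {
  f <- wavelet_filters(wavelet)
  m <- pad_dyadic(box$gray, levels)
  if (min(dim(m)) < 2^levels) {
    abort("insufficient-support: DWT needs a larger lesion", class = "dermaug_support_error")
  }
  out <- c()
  cur <- m
  for (lev in seq_len(levels)) {
    d <- dwt2(cur, f)
    for (band in c("ad", "da", "dd")) {
      coefs <- switch(band, ad = d$lh, da = d$hl, dd = d$hh)
      v <- c(mean(abs(coefs)), sd(abs(coefs)))
      if (is.na(v[2])) v[2] <- 0
      names(v) <- sprintf("DWT_%s_level%d_%s_%s", wavelet, lev, band, c("mean", "std"))
      out <- c(out, v)
    }
    cur <- d$ll
  }
  v <- c(mean(abs(cur)), sd(abs(cur)))
  if (is.na(v[2])) v[2] <- 0
  names(v) <- sprintf("DWT_%s_level%d_aa_%s", wavelet, levels, c("mean", "std"))
  c(out, v)
}

# Full wavelet packet tree to `depth`; node paths use the a/h/v/d letter
# convention (approximation, horizontal, vertical, diagonal) per level.
wp_features <- function(box, wavelet = "coif1", depth = 3L) {
  f <- wavelet_filters(wavelet)
  m <- pad_dyadic(box$gray, depth)
  if (min(dim(m)) < 2^depth) {
    abort("insufficient-support: WP needs a larger lesion", class = "dermaug_support_error")
  }
  nodes <- list(m)
  paths <- ""
  for (lev in seq_len(depth)) {
    nxt <- list()
    nxt_paths <- character(0)
    for (q in seq_along(nodes)) {
      d <- dwt2(nodes[[q]], f)
      nxt <- c(nxt, list(d$ll, d$lh, d$hl, d$hh))
      nxt_paths <- c(nxt_paths, paste0(paths[q], c("a", "h", "v", "d")))
    }
    nodes <- nxt
    paths <- nxt_paths
  }
  names(nodes) <- paths
  out <- c()
  for (path in names(nodes)) {
    coefs <- nodes[[path]]
    v <- c(mean(abs(coefs)), sd(abs(coefs)))
    if (is.na(v[2])) v[2] <- 0
    names(v) <- sprintf("WP_%s_%s_%s", wavelet, path, c("mean", "std"))
    out <- c(out, v)
  }
  out
}
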