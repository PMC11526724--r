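# Signal-processing texture families: uniform local binary patterns, the
# statistical feature matrix, bispectral phase entropy on Radon projections,
# and multiresolution Hurst (fractal) coefficients. These operate on the
# mean-filled lesion bounding box on the raw luma scale.

# Uniform LBP histogram at radius R with P circularly interpolated neighbours;
# P + 2 bins (P + 1 uniform codes plus one catch-all). Centers restricted to
# in-mask pixels whose sampling circle stays inside the box.
lbp_histogram <- function(box, R, P) {
  g <- box$gray
  h <- nrow(g); w <- ncol(g)
  if (h < 2 * R + 1 || w < 2 * R + 1) {
    abort(sprintf("insufficient-support: LBP R=%d needs a larger lesion", R),
          class = "dermaug_support_error")
  }
  rows <- (R + 1):(h - R)
  cols <- (R + 1):(w - R)
  centers <- as.matrix(expand.grid(r = rows, c = cols))
  inm <- box$mask[centers]
  centers <- centers[inm, , drop = FALSE]
  if (!nrow(centers)) abort("insufficient-support: LBP has no valid centers",
                            class = "dermaug_support_error")
  gc <- g[centers]
  code_trans <- integer(nrow(centers))  # number of 0/1 transitions
  code_ones <- integer(nrow(centers))
  prev_bit <- NULL; first_bit <- NULL
  for (p in 0:(P - 1)) {
    angp <- 2 * pi * p / P
    dy <- -R * sin(angp); dx <- R * cos(angp)
    rr <- centers[, 1] + dy; cc <- centers[, 2] + dx
    r0 <- pmin(floor(rr), h - 1L); c0 <- pmin(floor(cc), w - 1L)
    fr <- rr - r0; fc <- cc - c0
    gi <- (1 - fr) * (1 - fc) * g[cbind(r0, c0)] +
      (1 - fr) * fc * g[cbind(r0, c0 + 1)] +
      fr * (1 - fc) * g[cbind(r0 + 1, c0)] +
      fr * fc * g[cbind(r0 + 1, c0 + 1)]
    bit <- as.integer(gi >= gc)
    code_ones <- code_ones + bit
    if (is.null(first_bit)) first_bit <- bit else {
      code_trans <- code_trans + as.integer(bit != prev_bit)
    }
    prev_bit <- bit
  }
  code_trans <- code_trans + as.integer(prev_bit != first_bit)
  uniform <- code_trans <= 2
  # uniform codes binned by number of ones (0..P); non-uniform -> bin P+2
  bins <- ifelse(uniform, code_ones + 1L, P + 2L)
  tabulate(bins, nbins = P + 2L) / length(bins)
}

lbp_features <- function(box) {
  cfg <- list(c(1L, 8L), c(2L, 16L), c(3L, 24L))
  out <- numeric(0)
  for (rp in cfg) {
    p <- lbp_histogram(box, rp[1], rp[2])
    v <- c(sum(p^2), entropy_nat(p))
    names(v) <- sprintf("LBP_R_%d_P_%d_%s", rp[1], rp[2], c("energy", "entropy"))
    out <- c(out, v)
  }
  out
}

# Statistical feature matrix: dissimilarity and contrast as functions of the
# displacement (dy, dx) within |dy|, dx <= L. Coarseness is the reciprocal of
# the mean dissimilarity, periodicity the relative depth of its valley along
# each axis, and roughness a fractal-style log-log slope of dissimilarity
# versus displacement length.
sfm_features <- function(box, Lr = 4L) {
  g <- box$gray * 255
  h <- nrow(g); w <- ncol(g)
  Lr <- min(Lr, h - 1L, w - 1L)
  if (Lr < 1) abort("insufficient-support: SFM needs a larger lesion",
                    class = "dermaug_support_error")
  dss <- c(); con <- c(); dlen <- c()
  for (dy in 0:Lr) for (dx in (-Lr):Lr) {
    if (dy == 0 && dx <= 0) next
    rr <- 1:(h - dy)
    cc <- max(1, 1 - dx):min(w, w - dx)
    a <- g[rr, cc, drop = FALSE]
    b <- g[rr + dy, cc + dx, drop = FALSE]
    dss <- c(dss, mean(abs(a - b)))
    con <- c(con, mean((a - b)^2))
    dlen <- c(dlen, sqrt(dy^2 + dx^2))
  }
  coarse <- 100 / (1e-12 + mean(dss))
  contrast <- sqrt(mean(con))
  # periodicity: valley depth of dissimilarity over displacement lengths
  agg <- tapply(dss, round(dlen, 6), mean)
  periodicity <- if (length(agg) > 1) (mean(agg) - min(agg)) / (1e-12 + mean(agg)) else 0
  ok <- dss > 0
  rough <- if (sum(ok) > 1) {
    slope <- stats::coef(stats::lm(log(dss[ok]) ~ log(dlen[ok])))[2]
    (6 - slope) / 2   # fractal-dimension-style rescaling of the scaling exponent
  } else 3
  c(SFM_Coarseness = unname(coarse), SFM_Contrast = unname(contrast),
    SFM_Periodicity = unname(periodicity), SFM_Roughness = unname(rough))
}

# Radon-style projection of the box onto the axis at `angle_deg`, by binning
# pixel coordinates on u = x cos(t) + y sin(t).
radon_projection <- function(g, angle_deg) {
  h <- nrow(g); w <- ncol(g)
  th <- angle_deg * pi / 180
  yy <- matrix(seq_len(h) - (h + 1) / 2, h, w)
  xx <- matrix(seq_len(w) - (w + 1) / 2, h, w, byrow = TRUE)
  u <- xx * cos(th) + yy * sin(th)
  nb <- max(8L, ceiling(sqrt(h^2 + w^2)))
  brk <- seq(min(u) - 1e-9, max(u) + 1e-9, length.out = nb + 1L)
  idx <- findInterval(u, brk, rightmost.closed = TRUE)
  as.numeric(tapply(as.vector(g), factor(idx, levels = seq_len(nb)), sum, default = 0))
}

# Normalized bispectral phase entropy of a 1-D signal: accumulate the
# third-order spectrum B(f1, f2) = X(f1) X(f2) X*(f1 + f2) over the principal
# region and take the entropy of the phase histogram, normalized to [0, 1].
bispectral_phase_entropy <- function(x, n_phase_bins = 32L) {
  x <- x - mean(x)
  n <- length(x)
  if (n < 8 || all(x == 0)) return(0)
  X <- fft(x)
  half <- floor(n / 2)
  phases <- c()
  for (f1 in 1:half) {
    f2max <- min(f1, half - f1)
    if (f2max < 1) next
    f2 <- 1:f2max
    B <- X[f1 + 1] * X[f2 + 1] * Conj(X[f1 + f2 + 1])
    phases <- c(phases, Arg(B[Mod(B) > 1e-12]))
  }
  if (!length(phases)) return(0)
  brk <- seq(-pi, pi, length.out = n_phase_bins + 1L)
  p <- tabulate(findInterval(phases, brk, rightmost.closed = TRUE),
                nbins = n_phase_bins) / length(phases)
  entropy_nat(p) / log(n_phase_bins)
}

hos_features <- function(box, angles = c(135, 140)) {
  vals <- vapply(angles, function(a) {
    bispectral_phase_entropy(radon_projection(box$gray, a))
  }, numeric(1))
  names(vals) <- sprintf("HOS_%g_degrees", angles)
  vals
}

# Four Hurst coefficients, one per dyadic resolution: at each scale the image
# is block-averaged by 2^s and H is the log-log slope of the mean absolute
# intensity increment over lags 1..4 (horizontal and vertical pooled).
fdta_features <- function(box, n_res = 4L) {
  g <- box$gray * 255
  out <- numeric(n_res)
  for (s in seq_len(n_res)) {
    if (s > 1) {
      h2 <- floor(nrow(g) / 2); w2 <- floor(ncol(g) / 2)
      if (h2 < 5 || w2 < 5) { out[s:n_res] <- 0; break }
      g <- (g[2 * (1:h2) - 1, 2 * (1:w2) - 1] + g[2 * (1:h2), 2 * (1:w2) - 1] +
              g[2 * (1:h2) - 1, 2 * (1:w2)] + g[2 * (1:h2), 2 * (1:w2)]) / 4
    }
    lags <- 1:min(4L, nrow(g) - 1L, ncol(g) - 1L)
    if (length(lags) < 2) { out[s] <- 0; next }
    inc <- vapply(lags, function(k) {
      mean(c(abs(g[-(1:k), ] - g[1:(nrow(g) - k), ]),
             abs(g[, -(1:k)] - g[, 1:(ncol(g) - k)])))
    }, numeric(1))
    out[s] <- if (all(inc > 0)) {
      unname(stats::coef(stats::lm(log(inc) ~ log(lags)))[2])
    } else 0  # constant image convention
  }
  names(out) <- sprintf("FDTA_HurstCoeff_%d", seq_len(n_res))
  out
}
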