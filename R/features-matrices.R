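# Matrix-based statistical texture families: GLCM (Haralick), GLDS, GLRLM,
# GLSZM and the neighbourhood gray-tone difference (King) features. All
# operate on a quantized `dermaug_gray_lesion`; only pixel pairs / runs /
# zones fully inside the mask contribute.

glcm_offsets <- function() list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

#' Normalized gray-level co-occurrence matrix
#'
#' Counts pairs of in-mask pixels separated by `offset = (dy, dx)`; each pair
#' is counted in both directions, so the matrix is symmetric, and it is
#' normalized to sum to 1.
#'
#' @param gl A [quantize_and_mask()] result.
#' @param offset Integer `(dy, dx)`, not `(0, 0)`.
#' @return `Ng` x `Ng` matrix summing to 1.
#' @export
cooccurrence_matrix <- function(gl, offset = c(0L, 1L)) {
  stopifnot(inherits(gl, "dermaug_gray_lesion"))
  dy <- offset[1]; dx <- offset[2]
  if (dy == 0 && dx == 0) stop_invalid("offset", "must not be (0, 0)")
  g <- gl$gray
  h <- nrow(g); w <- ncol(g)
  r1 <- max(1, 1 - dy):min(h, h - dy)
  c1 <- max(1, 1 - dx):min(w, w - dx)
  if (!length(r1) || !length(c1)) abort("no-pairs: offset exceeds image", class = "dermaug_nopairs_error")
  a <- g[r1, c1, drop = FALSE]
  b <- g[r1 + dy, c1 + dx, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) abort("no-pairs: no in-mask pixel pairs for this offset",
                      class = "dermaug_nopairs_error")
  Ng <- gl$Ng
  tab <- table(factor(a[ok], levels = 0:(Ng - 1)),
               factor(b[ok], levels = 0:(Ng - 1)))
  P <- unclass(tab) + t(unclass(tab))   # symmetric: count both directions
  P / sum(P)
}

# The 14 Haralick statistics of one normalized symmetric co-occurrence matrix.
# Natural logs; zero-variance conventions give 0 for correlation-type terms.
haralick_stats <- function(P) {
  Ng <- nrow(P)
  i <- matrix(0:(Ng - 1), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum((0:(Ng - 1)) * px)
  sig2 <- sum(((0:(Ng - 1)) - mu)^2 * px)
  sig <- sqrt(sig2)

  # p_{x+y}(k), k = 0..2Ng-2 and p_{x-y}(k), k = 0..Ng-1
  pxy_sum <- vapply(0:(2 * Ng - 2), function(k) sum(P[i + j == k]), numeric(1))
  pxy_dif <- vapply(0:(Ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  corr <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 0
  sos <- sum((i - mu)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sa <- sum((0:(2 * Ng - 2)) * pxy_sum)
  se <- entropy_nat(pxy_sum)
  sv <- sum(((0:(2 * Ng - 2)) - sa)^2 * pxy_sum)
  ent <- entropy_nat(as.vector(P))
  dmean <- sum((0:(Ng - 1)) * pxy_dif)
  dv <- sum(((0:(Ng - 1)) - dmean)^2 * pxy_dif)
  de <- entropy_nat(pxy_dif)

  # Information measures of correlation and the maximal correlation coefficient.
  hx <- entropy_nat(px)
  pipj <- outer(px, px)
  pos <- P > 0 & pipj > 0
  hxy1 <- -sum(P[pos] * log(pipj[pos]))
  hxy2 <- -sum(pipj[pipj > 0] * log(pipj[pipj > 0]))
  ic1 <- if (hx > 0) (ent - hxy1) / hx else 0
  ic2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - ent))))
  Q <- matrix(0, Ng, Ng)
  nz <- px > 0
  if (sum(nz) >= 2) {
    Pn <- P[nz, nz, drop = FALSE]
    pxn <- px[nz]
    # Q[i,j] = sum_k P(i,k) P(j,k) / (px(i) px(k))
    Q <- sweep(Pn, 1, pxn, "/") %*% t(sweep(Pn, 2, pxn, "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- if (length(ev) >= 2) sqrt(pmax(0, ev[2])) else 0
  } else mcc <- 0

  c(glcm_asm = asm, glcm_contrast = contrast, glcm_corr = corr, glcm_sos = sos,
    glcm_idm = idm, glcm_sa = sa, glcm_sv = sv, glcm_se = se,
    glcm_entropy = ent, glcm_dv = dv, glcm_de = de,
    glcm_ic1 = ic1, glcm_ic2 = ic2, glcm_mcc = mcc)
}

glcm_features <- function(gl) {
  vals <- lapply(glcm_offsets(), function(o) haralick_stats(cooccurrence_matrix(gl, o)))
  Reduce(`+`, vals) / length(vals)
}

# Gray-level difference statistics: histogram of |g(x) - g(x + d)| over the 4
# canonical displacements, averaged.
glds_histogram <- function(gl, offset) {
  g <- gl$gray
  h <- nrow(g); w <- ncol(g)
  dy <- offset[1]; dx <- offset[2]
  r1 <- max(1, 1 - dy):min(h, h - dy)
  c1 <- max(1, 1 - dx):min(w, w - dx)
  a <- g[r1, c1, drop = FALSE]
  b <- g[r1 + dy, c1 + dx, drop = FALSE]
  d <- abs(a - b)
  d <- d[!is.na(d)]
  if (!length(d)) abort("insufficient-support: GLDS has no in-mask pairs",
                        class = "dermaug_support_error")
  tabulate(d + 1L, nbins = gl$Ng) / length(d)
}

glds_features <- function(gl) {
  hs <- lapply(glcm_offsets(), function(o) glds_histogram(gl, o))
  p <- Reduce(`+`, hs) / length(hs)
  k <- 0:(gl$Ng - 1)
  c(glds_H = sum(p / (1 + k^2)),
    glds_C = sum(k^2 * p),
    glds_energy = sum(p^2),
    glds_entropy = entropy_nat(p),
    glds_M = sum(k * p))
}

# Run-length matrix for one direction; runs break at mask boundaries.
run_length_matrix <- function(gl, direction = c(0L, 1L)) {
  g <- gl$gray
  Ng <- gl$Ng
  h <- nrow(g); w <- ncol(g)
  dy <- direction[1]; dx <- direction[2]
  # enumerate maximal lines along (dy, dx) and run-length encode each
  starts <- list()
  if (dy == 0 && dx == 1) {
    lines <- lapply(seq_len(h), function(r) g[r, ])
  } else if (dy == 1 && dx == 0) {
    lines <- lapply(seq_len(w), function(cl) g[, cl])
  } else if (dy == 1 && dx == 1) {
    lines <- lapply(seq(-(h - 1), w - 1), function(k) {
      rr <- seq_len(h); cc <- rr + k
      ok <- cc >= 1 & cc <= w
      g[cbind(rr[ok], cc[ok])]
    })
  } else if (dy == 1 && dx == -1) {
    lines <- lapply(seq(2, h + w), function(k) {
      rr <- seq_len(h); cc <- k - rr
      ok <- cc >= 1 & cc <= w
      g[cbind(rr[ok], cc[ok])]
    })
  } else stop_invalid("direction", "must be one of the 4 canonical directions")
  maxlen <- max(h, w)
  R <- matrix(0, Ng, maxlen)
  for (ln in lines) {
    if (!length(ln)) next
    rl <- rle(ifelse(is.na(ln), -1L, ln))
    keep <- rl$values >= 0
    if (any(keep)) {
      for (q in which(keep)) {
        R[rl$values[q] + 1L, rl$lengths[q]] <- R[rl$values[q] + 1L, rl$lengths[q]] + 1
      }
    }
  }
  R[, seq_len(max(1, max(which(colSums(R) > 0), 1))), drop = FALSE]
}

# 16 run-length statistics: the 11 classic Galloway/Chu/Dasarathy features
# plus normalized non-uniformities, gray-level/run-length variances and run
# entropy.
glrlm_stats <- function(R, n_mask) {
  Nr <- sum(R)
  if (Nr == 0) abort("insufficient-support: GLRLM has no runs", class = "dermaug_support_error")
  Ng <- nrow(R); L <- ncol(R)
  i <- matrix(seq_len(Ng), Ng, L)        # gray level index (1-based)
  j <- matrix(seq_len(L), Ng, L, byrow = TRUE)  # run length
  p <- R / Nr
  ri <- rowSums(R); rj <- colSums(R)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(glrlm_sre = sum(R / j^2) / Nr,
    glrlm_lre = sum(R * j^2) / Nr,
    glrlm_gln = sum(ri^2) / Nr,
    glrlm_rln = sum(rj^2) / Nr,
    glrlm_rp = Nr / n_mask,
    glrlm_lglre = sum(R / i^2) / Nr,
    glrlm_hglre = sum(R * i^2) / Nr,
    glrlm_srlgle = sum(R / (i^2 * j^2)) / Nr,
    glrlm_srhgle = sum(R * i^2 / j^2) / Nr,
    glrlm_lrlgle = sum(R * j^2 / i^2) / Nr,
    glrlm_lrhgle = sum(R * i^2 * j^2) / Nr,
    glrlm_glnn = sum(ri^2) / Nr^2,
    glrlm_rlnn = sum(rj^2) / Nr^2,
    glrlm_glv = sum(p * (i - mu_i)^2),
    glrlm_rlv = sum(p * (j - mu_j)^2),
    glrlm_re = entropy_nat(as.vector(p)))
}

glrlm_features <- function(gl) {
  n_mask <- sum(gl$mask)
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  vals <- lapply(dirs, function(d) glrlm_stats(run_length_matrix(gl, d), n_mask))
  Reduce(`+`, vals) / length(vals)
}

# Size-zone matrix: zones are 8-connected components of constant gray level.
size_zone_matrix <- function(gl) {
  g <- gl$gray
  Ng <- gl$Ng
  zones <- list()
  sizes <- integer(0)
  levels_ <- integer(0)
  for (lev in 0:(Ng - 1)) {
    binary <- !is.na(g) & g == lev
    if (!any(binary)) next
    lab <- from_ebi(EBImage::bwlabel(as_ebi(binary * 1)))
    tab <- tabulate(lab[lab > 0])
    tab <- tab[tab > 0]
    sizes <- c(sizes, tab)
    levels_ <- c(levels_, rep(lev, length(tab)))
  }
  if (!length(sizes)) abort("insufficient-support: GLSZM has no zones",
                            class = "dermaug_support_error")
  S <- matrix(0, Ng, max(sizes))
  for (q in seq_along(sizes)) {
    S[levels_[q] + 1L, sizes[q]] <- S[levels_[q] + 1L, sizes[q]] + 1
  }
  S
}

# The 14 zone statistics of the size-zone matrix.
glszm_features <- function(gl) {
  S <- size_zone_matrix(gl)
  Nz <- sum(S)
  n_mask <- sum(gl$mask)
  Ng <- nrow(S); L <- ncol(S)
  i <- matrix(seq_len(Ng), Ng, L)
  j <- matrix(seq_len(L), Ng, L, byrow = TRUE)
  p <- S / Nz
  si <- rowSums(S); sj <- colSums(S)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(glszm_sze = sum(S / j^2) / Nz,
    glszm_lze = sum(S * j^2) / Nz,
    glszm_glnu = sum(si^2) / Nz,
    glszm_zsnu = sum(sj^2) / Nz,
    glszm_lglze = sum(S / i^2) / Nz,
    glszm_hglze = sum(S * i^2) / Nz,
    glszm_zp = Nz / n_mask,
    glszm_szlgle = sum(S / (i^2 * j^2)) / Nz,
    glszm_szhgle = sum(S * i^2 / j^2) / Nz,
    glszm_lzlgle = sum(S * j^2 / i^2) / Nz,
    glszm_lzhgle = sum(S * i^2 * j^2) / Nz,
    glszm_glvar = sum(p * (i - mu_i)^2),
    glszm_zsvar = sum(p * (j - mu_j)^2),
    glszm_zsentr = entropy_nat(as.vector(p)))
}

# Neighbourhood gray-tone difference matrix (Amadasun & King): s(i) is the
# summed absolute difference between level-i pixels and the mean of their
# in-mask 3x3 neighbours.
ngtdm <- function(gl) {
  g <- gl$gray
  Ng <- gl$Ng
  h <- nrow(g); w <- ncol(g)
  val <- matrix(0, h, w); cnt <- matrix(0, h, w)
  gz <- ifelse(is.na(g), 0, g)
  inm <- !is.na(g)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    rr <- max(1, 1 - dy):min(h, h - dy)
    cc <- max(1, 1 - dx):min(w, w - dx)
    val[rr, cc] <- val[rr, cc] + gz[rr + dy, cc + dx]
    cnt[rr, cc] <- cnt[rr, cc] + inm[rr + dy, cc + dx]
  }
  ok <- inm & cnt > 0
  if (!any(ok)) abort("insufficient-support: NGTDM has no valid pixels",
                      class = "dermaug_support_error")
  abar <- val[ok] / cnt[ok]
  lev <- g[ok]
  s_i <- vapply(0:(Ng - 1), function(l) sum(abs(lev[lev == l] - abar[lev == l])), numeric(1))
  n_i <- tabulate(lev + 1L, nbins = Ng)
  list(s = s_i, n = n_i, N = sum(n_i))
}

# King's five neighbourhood gray-tone difference features.
king_features <- function(gl) {
  m <- ngtdm(gl)
  p <- m$n / m$N
  act <- which(m$n > 0)
  Ngr <- length(act)
  eps <- 1e-12
  coarseness <- 1 / (eps + sum(p * m$s))
  contrast <- if (Ngr > 1) {
    (1 / (Ngr * (Ngr - 1))) *
      sum(outer(p[act], p[act]) * outer(act - 1, act - 1, function(a, b) (a - b)^2)) *
      sum(m$s) / m$N
  } else 0
  busy_den <- sum(abs(outer((act - 1) * p[act], (act - 1) * p[act], "-")))
  busyness <- if (busy_den > 0) sum(p * m$s) / busy_den else 0
  cmplx <- if (m$N > 0 && Ngr > 1) {
    tot <- 0
    for (a in act) for (b in act) {
      if (a == b) next
      tot <- tot + abs(a - b) / (m$N * (p[a] + p[b])) *
        (p[a] * m$s[a] + p[b] * m$s[b])
    }
    tot
  } else 0
  strength <- if (sum(m$s) > 0) {
    tot <- 0
    for (a in act) for (b in act) {
      if (a == b) next
      tot <- tot + (p[a] + p[b]) * (a - b)^2
    }
    tot / (eps + sum(m$s))
  } else 0
  c(king_coarseness = coarseness, king_contrast = contrast,
    king_busyness = busyness, king_complexity = cmplx, king_strength = strength)
}

# 15 first-order statistics of the in-mask quantized gray histogram.
fos_features <- function(gl) {
  v <- gl$gray[gl$mask]
  p <- tabulate(v + 1L, nbins = gl$Ng) / length(v)
  m <- mean(v); s <- sd(v); if (is.na(s)) s <- 0
  qs <- quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  c(fos_energy = sum(p^2),
    fos_mean = m,
    fos_std = s,
    fos_median = median(v),
    fos_variance = s^2,
    fos_mode = which.max(p) - 1,
    fos_skew = moment_skewness(v),
    fos_entropy = entropy_nat(p),
    fos_mngl = min(v),
    fos_mxgl = max(v),
    fos_cov = if (m != 0) s / m else 0,
    fos_10 = qs[1], fos_25 = qs[2], fos_75 = qs[3], fos_90 = qs[4])
}
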