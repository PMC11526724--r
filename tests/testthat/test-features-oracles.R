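# Brute-force oracles for the texture operators on the 4x4 fixture. Every
# oracle below is a literal, naive evaluation (double loops, hand counts)
# independent of the vectorized implementations.

test_that("quantization maps ranges as specified", {
  gl <- quantize_and_mask(matrix(0.5, 8, 8), matrix(1, 8, 8), Ng = 32)
  expect_true(all(gl$gray[gl$mask] == 0))       # degenerate range
  two <- matrix(c(10, 200) / 255, 8, 8)
  gl2 <- quantize_and_mask(two, matrix(1, 8, 8), Ng = 32)
  expect_setequal(unique(gl2$gray[gl2$mask]), c(0L, 31L))
  expect_identical(toy_gl()$gray, toy_gray_matrix())  # identity rebinning
  expect_error(quantize_and_mask(two, matrix(0, 8, 8)), "mask",
               class = "dermaug_validation_error")
})

test_that("co-occurrence matrix equals a literal hand count of pairs", {
  gl <- toy_gl()
  P <- cooccurrence_matrix(gl, c(0, 1))
  # brute force: enumerate all horizontal neighbour pairs in both directions
  m <- toy_gray_matrix()
  C <- matrix(0, 4, 4)
  for (r in 1:4) for (cl in 1:3) {
    C[m[r, cl] + 1, m[r, cl + 1] + 1] <- C[m[r, cl] + 1, m[r, cl + 1] + 1] + 1
    C[m[r, cl + 1] + 1, m[r, cl] + 1] <- C[m[r, cl + 1] + 1, m[r, cl] + 1] + 1
  }
  expect_equal(unname(unclass(P)), C / sum(C), tolerance = 1e-12)
  expect_equal(sum(P), 1)
  expect_identical(unname(unclass(P)), unname(t(unclass(P))))  # symmetric
  # constant image: single diagonal entry
  cg <- quantize_and_mask(matrix(0.4, 4, 4), matrix(1, 4, 4), Ng = 4)
  Pc <- cooccurrence_matrix(cg, c(0, 1))
  expect_equal(Pc[1, 1], 1)
  expect_equal(sum(Pc), 1)
  expect_error(cooccurrence_matrix(gl, c(0, 0)), "offset")
})

test_that("all 14 Haralick statistics match naive textbook evaluation", {
  P <- unclass(cooccurrence_matrix(toy_gl(), c(0, 1)))
  got <- dermaug:::haralick_stats(P)
  Ng <- 4
  px <- unname(rowSums(P)); py <- unname(colSums(P))
  mu <- sum((0:3) * px)
  # naive double loops
  asm <- 0; con <- 0; sos <- 0; idm <- 0; ent <- 0; corr_num <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    asm <- asm + p^2
    con <- con + (i - j)^2 * p
    sos <- sos + (i - 1 - mu)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log(p)
    corr_num <- corr_num + (i - 1 - mu) * (j - 1 - mu) * p
  }
  sig2 <- sum(((0:3) - mu)^2 * px)
  psum <- sapply(0:6, function(k) {
    s <- 0
    for (i in 1:Ng) for (j in 1:Ng) if ((i - 1) + (j - 1) == k) s <- s + P[i, j]
    s
  })
  pdif <- sapply(0:3, function(k) {
    s <- 0
    for (i in 1:Ng) for (j in 1:Ng) if (abs(i - j) == k) s <- s + P[i, j]
    s
  })
  sa <- sum((0:6) * psum)
  se <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  sv <- sum(((0:6) - sa)^2 * psum)
  dmean <- sum((0:3) * pdif)
  dv <- sum(((0:3) - dmean)^2 * pdif)
  de <- -sum(pdif[pdif > 0] * log(pdif[pdif > 0]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    if (P[i, j] > 0 && px[i] * py[j] > 0) hxy1 <- hxy1 - P[i, j] * log(px[i] * py[j])
    if (px[i] * py[j] > 0) hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
  }
  Q <- matrix(0, Ng, Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    for (k in 1:Ng) if (px[i] * py[k] > 0) {
      Q[i, j] <- Q[i, j] + P[i, k] * P[j, k] / (px[i] * py[k])
    }
  }
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  want <- c(glcm_asm = asm, glcm_contrast = con,
            glcm_corr = corr_num / sig2, glcm_sos = sos, glcm_idm = idm,
            glcm_sa = sa, glcm_sv = sv, glcm_se = se, glcm_entropy = ent,
            glcm_dv = dv, glcm_de = de,
            glcm_ic1 = (ent - hxy1) / hx,
            glcm_ic2 = sqrt(1 - exp(-2 * (hxy2 - ent))),
            glcm_mcc = sqrt(ev[2]))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("gray-level difference statistics match a naive histogram count", {
  gl <- toy_gl()
  m <- toy_gray_matrix()
  # naive: pool the |difference| histograms of the 4 displacements
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  hs <- lapply(offs, function(o) {
    d <- c()
    for (r in 1:4) for (cl in 1:4) {
      r2 <- r + o[1]; c2 <- cl + o[2]
      if (r2 >= 1 && r2 <= 4 && c2 >= 1 && c2 <= 4) {
        d <- c(d, abs(m[r, cl] - m[r2, c2]))
      }
    }
    tabulate(d + 1, nbins = 4) / length(d)
  })
  p <- Reduce(`+`, hs) / 4
  k <- 0:3
  want <- c(glds_H = sum(p / (1 + k^2)), glds_C = sum(k^2 * p),
            glds_energy = sum(p^2),
            glds_entropy = -sum(p[p > 0] * log(p[p > 0])),
            glds_M = sum(k * p))
  expect_equal(extract_texture_family(gl, "GLDS"), want, tolerance = 1e-12)
})

test_that("run-length matrix matches hand-enumerated runs", {
  # constant 4x4 image: every row is a single run of length 4
  cg <- quantize_and_mask(matrix(0.7, 4, 4), matrix(1, 4, 4), Ng = 4)
  R <- dermaug:::run_length_matrix(cg, c(0, 1))
  expect_equal(R[1, 4], 4)
  expect_equal(sum(R), 4)
  # toy matrix horizontal runs: hand enumeration per row
  # rows: (0,0),(1,1) | (0,0),(1,1) | (0),(2,2,2) | (2,2),(3,3)
  R2 <- dermaug:::run_length_matrix(toy_gl(), c(0, 1))
  want <- matrix(0, 4, 4)
  want[1, 2] <- 2  # two runs of 0s, length 2
  want[2, 2] <- 2  # two runs of 1s, length 2
  want[1, 1] <- 1  # single 0
  want[3, 3] <- 1  # run of three 2s
  want[3, 2] <- 1  # run of two 2s
  want[4, 2] <- 1  # run of two 3s
  expect_equal(unname(R2), want[, seq_len(ncol(R2))])
})

test_that("run-length statistics match their naive formulas", {
  got <- extract_texture_family(toy_gl(), "GLRLM")
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  vals <- sapply(dirs, function(d) {
    R <- dermaug:::run_length_matrix(toy_gl(), d)
    Nr <- sum(R)
    sre <- 0; lre <- 0; lglre <- 0; hglre <- 0
    for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
      sre <- sre + R[i, j] / j^2
      lre <- lre + R[i, j] * j^2
      lglre <- lglre + R[i, j] / i^2
      hglre <- hglre + R[i, j] * i^2
    }
    c(sre, lre, lglre, hglre) / Nr
  })
  avg <- rowMeans(vals)
  expect_equal(unname(got[c("glrlm_sre", "glrlm_lre", "glrlm_lglre",
                            "glrlm_hglre")]), avg, tolerance = 1e-12)
})

test_that("size-zone matrix matches hand-identified zones of the fixture", {
  # hand analysis of the 4x4 fixture (8-connected equal-level zones):
  # level 0 -> one zone of 5; level 1 -> one zone of 4;
  # level 2 -> one zone of 5; level 3 -> one zone of 2
  S <- dermaug:::size_zone_matrix(toy_gl())
  want <- matrix(0, 4, 5)
  want[1, 5] <- 1; want[2, 4] <- 1; want[3, 5] <- 1; want[4, 2] <- 1
  expect_equal(unname(S), want)
  got <- extract_texture_family(toy_gl(), "GLSZM")
  Nz <- 4
  expect_equal(unname(got[["glszm_sze"]]),
               (1 / 25 + 1 / 16 + 1 / 25 + 1 / 4) / Nz, tolerance = 1e-12)
  expect_equal(unname(got[["glszm_zp"]]), 4 / 16)
  expect_equal(unname(got[["glszm_hglze"]]), (1 + 4 + 9 + 16) / Nz,
               tolerance = 1e-12)
})

test_that("neighbourhood gray-tone difference features match naive loops", {
  m <- toy_gray_matrix()
  got <- extract_texture_family(toy_gl(), "NGTDM_KING")
  # naive s(i): per pixel, mean of its in-frame 3x3 neighbours
  s_i <- numeric(4); n_i <- numeric(4)
  for (r in 1:4) for (cl in 1:4) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- cl + dc
      if (rr >= 1 && rr <= 4 && cc >= 1 && cc <= 4) nb <- c(nb, m[rr, cc])
    }
    lev <- m[r, cl] + 1
    s_i[lev] <- s_i[lev] + abs(m[r, cl] - mean(nb))
    n_i[lev] <- n_i[lev] + 1
  }
  p <- n_i / 16
  expect_equal(unname(got[["king_coarseness"]]),
               1 / (1e-12 + sum(p * s_i)), tolerance = 1e-9)
})

test_that("first-order statistics have the printed catalogue size and values", {
  got <- extract_texture_family(toy_gl(), "FOS")
  expect_length(got, 15)
  v <- as.vector(toy_gray_matrix())
  expect_equal(unname(got[["fos_mean"]]), mean(v))
  expect_equal(unname(got[["fos_energy"]]), sum((table(v) / 16)^2),
               ignore_attr = TRUE)
  expect_equal(unname(got[["fos_mxgl"]]), 3)
})

test_that("constant lesions hit the zero-variation conventions", {
  cg <- quantize_and_mask(matrix(0.6, 8, 8), matrix(1, 8, 8), Ng = 32)
  fos <- extract_texture_family(cg, "FOS")
  glcm <- extract_texture_family(cg, "GLCM")
  glds <- extract_texture_family(cg, "GLDS")
  expect_equal(unname(fos[["fos_std"]]), 0)
  expect_equal(unname(glcm[["glcm_contrast"]]), 0)
  expect_equal(unname(glcm[["glcm_entropy"]]), 0)
  expect_equal(unname(glds[["glds_C"]]), 0)
  fdta <- extract_texture_family(cg, "FDTA", raw_gray = matrix(0.6, 8, 8))
  expect_true(all(fdta == 0))
})

test_that("isotropic families are invariant under 90-degree rotation", {
  les <- fixture_lesion("textured224")
  rot <- function(m) t(m[nrow(m):1, ])
  gl1 <- quantize_and_mask(dermaug:::rgb_to_gray(les$image), les$mask, 32)
  gl2 <- quantize_and_mask(rot(dermaug:::rgb_to_gray(les$image)), rot(les$mask), 32)
  for (fam in c("GLCM", "GLDS", "GLRLM")) {
    expect_equal(extract_texture_family(gl1, fam),
                 extract_texture_family(gl2, fam), tolerance = 1e-9)
  }
  expect_equal(extract_texture_family(gl1, "GLSZM"),
               extract_texture_family(gl2, "GLSZM"), tolerance = 1e-9)
})

test_that("wavelet subbands match the independently computed reference", {
  # 16x16 deterministic fixture; per-subband mean and population std frozen
  # from an independent wavelet toolbox (periodization mode)
  M <- outer(0:15, 0:15, function(i, j) (7 * i + 13 * j) %% 31) * 1.0
  for (w in c("bior3.3", "coif1")) {
    d <- dermaug:::dwt2(M, dermaug:::wavelet_filters(w))
    got <- c(mean(d$ll), pop_sd(d$ll), mean(d$lh), pop_sd(d$lh),
             mean(d$hl), pop_sd(d$hl), mean(d$hh), pop_sd(d$hh))
    want <- if (w == "bior3.3") {
      c(29.71875, 11.147799728265, 0.21875, 10.262596996002,
        0.40625, 18.558247525457, 0.0, 5.168873633459)
    } else {
      c(29.71875, 4.7786005133, -0.21875, 7.794115029137,
        -0.40625, 11.350183090934, 0.0, 10.313127540259)
    }
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("half-disk asymmetry matches the naive reflection computation", {
  mask <- half_disk_mask()
  img <- flat_image(101, 0.3)
  a <- abcd_features(mask, img)
  # naive oracle: for a half-disk the principal axes are the image axes, so
  # reflect pixel centres across the vertical / horizontal lines through the
  # centroid with explicit arithmetic and average the non-overlap fractions
  pts <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(pts)
  nonov <- sapply(1:2, function(dim_) {
    refl <- pts
    refl[, dim_] <- round(2 * ctr[dim_] - pts[, dim_])
    ok <- refl[, dim_] >= 1 & refl[, dim_] <= 101
    hit <- logical(nrow(pts))
    hit[ok] <- mask[refl[ok, , drop = FALSE]]
    1 - mean(hit)
  })
  expect_equal(unname(a[["geo_assymetry"]]), mean(nonov), tolerance = 1e-6)
  # reflection across the axis parallel to the flat edge is the asymmetric one
  expect_gt(max(nonov), 0.15)
  d <- abcd_features(disk_mask(), img)
  expect_lt(d[["geo_assymetry"]], a[["geo_assymetry"]])
})

test_that("single-colour lesion occupies exactly one reference colour", {
  mask <- disk_mask(64, 20)
  img <- flat_image(64, 0)
  img[, , 1] <- 0.34; img[, , 2] <- 0.21; img[, , 3] <- 0.12  # dark brown
  a <- abcd_features(mask, img)
  expect_equal(unname(a[["geo_color"]]), 1)
})

test_that("pooled colour statistics follow the closed-form mean", {
  # 50/50 two-tone lesion with channel values 0 and 200/255
  img <- flat_image(10, 0)
  img[1:5, , ] <- 200 / 255
  mask <- matrix(1, 10, 10)
  v <- color_stats(img, mask, "RGB")
  expect_equal(unname(v[["rgb_mean"]]), 100 / 255)
  cs <- color_stats(flat_image(10, 0.4), mask, "CIELab")
  expect_length(cs, 12)
  expect_true(all(cs[grep("std|skew|kurt", names(cs))] == 0))
  expect_error(color_stats(img, mask, "XYZ"), "space",
               class = "dermaug_validation_error")
})
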