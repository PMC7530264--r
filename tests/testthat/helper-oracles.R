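# Independent brute-force oracles, written directly from the textbook
# definitions with plain loops. They deliberately share no code with the
# package implementations they check.

# All 14 Haralick statistics of a normalized co-occurrence matrix,
# gray levels indexed 0-based, entropies in bits.
brute_haralick <- function(p) {
  ng <- nrow(p)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  lev <- 0:(ng - 1)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px))
  sdy <- sqrt(sum((lev - muy)^2 * py))
  psum <- numeric(2 * ng - 1)   # index k+1 holds P(i+j == k), k = 0..2ng-2
  pdif <- numeric(ng)           # index k+1 holds P(|i-j| == k)
  for (i in 1:ng) for (j in 1:ng) {
    k <- (i - 1) + (j - 1)
    psum[k + 1] <- psum[k + 1] + p[i, j]
    d <- abs(i - j)
    pdif[d + 1] <- pdif[d + 1] + p[i, j]
  }
  H <- function(q) { s <- 0; for (v in q) if (v > 0) s <- s - v * log2(v); s }

  f1 <- sum(p * p)
  f2 <- 0
  for (k in 0:(ng - 1)) f2 <- f2 + k^2 * pdif[k + 1]
  f3 <- 0
  if (sdx > 0 && sdy > 0) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng)
      s <- s + (i - 1) * (j - 1) * p[i, j]
    f3 <- (s - mux * muy) / (sdx * sdy)
  }
  f4 <- 0
  for (i in 1:ng) for (j in 1:ng) f4 <- f4 + ((i - 1) - mux)^2 * p[i, j]
  f5 <- 0
  for (i in 1:ng) for (j in 1:ng) f5 <- f5 + p[i, j] / (1 + (i - j)^2)
  f6 <- 0
  for (k in 0:(2 * ng - 2)) f6 <- f6 + k * psum[k + 1]
  f7 <- 0
  for (k in 0:(2 * ng - 2)) f7 <- f7 + (k - f6)^2 * psum[k + 1]
  f8 <- H(psum)
  f9 <- H(p)
  mud <- 0
  for (k in 0:(ng - 1)) mud <- mud + k * pdif[k + 1]
  f10 <- 0
  for (k in 0:(ng - 1)) f10 <- f10 + (k - mud)^2 * pdif[k + 1]
  f11 <- H(pdif)
  hx <- H(px); hy <- H(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - f9))))
  keep <- which(px > 0)
  f14 <- 0
  if (length(keep) >= 2) {
    q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      s <- 0
      for (k in 1:ng)
        if (py[k] > 0)
          s <- s + p[keep[a], k] * p[keep[b], k] / (px[keep[a]] * py[k])
      q[a, b] <- s
    }
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    f14 <- sqrt(max(0, ev[2]))
  }
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14)
}

# LBP code by direct per-neighbor enumeration with its own bilinear
# interpolation (r, c 1-based; same geometric convention as the package:
# neighbor p at (r - R sin a, c + R cos a), a = 2 pi p / P, near-integer
# displacements snapped, neighbor >= center sets bit p).
brute_lbp_code <- function(img, r, c, P, R) {
  gc <- img[r, c]
  code <- 0
  for (p in 0:(P - 1)) {
    a <- 2 * pi * p / P
    rr <- r - R * sin(a)
    cc <- c + R * cos(a)
    if (abs(rr - round(rr)) < 1e-6) rr <- round(rr)
    if (abs(cc - round(cc)) < 1e-6) cc <- round(cc)
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    gp <- if (fr == 0 && fc == 0) img[r0, c0]
    else (1 - fr) * (1 - fc) * img[r0, c0] +
      (1 - fr) * fc * img[r0, c0 + 1] +
      fr * (1 - fc) * img[r0 + 1, c0] +
      fr * fc * img[r0 + 1, c0 + 1]
    if (gp - gc >= -1e-7) code <- code + 2^p
  }
  code
}

# Raw image moment m_pq by direct summation (x along columns, y along
# rows, both 1-based -- matches the package's axis convention).
brute_moment <- function(img, p, q, xc = 0, yc = 0) {
  s <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    s <- s + (j - xc)^p * (i - yc)^q * img[i, j]
  s
}
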