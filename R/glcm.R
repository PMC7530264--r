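#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of gray levels at the given pixel offsets and
#' normalizes the pooled counts to a joint distribution `p(i, j)`.
#'
#' Binning: when every pixel is an integer already inside
#' `0 .. levels - 1` the values are used directly as gray levels
#' (the usual case for quantized images); otherwise values are assumed to
#' span the 8-bit range and are binned uniformly, level
#' `floor(v * levels / 256)` clamped to `levels - 1`.
#'
#' The default accumulates the four distance-1 directions (0, 45, 90 and
#' 135 degrees) and symmetrizes, so `p` is a symmetric distribution over
#' unordered neighbor pairs.
#'
#' @param image An `eeg_heatmap` or numeric matrix with values in 0..255.
#' @param offsets List of integer `c(drow, dcol)` offsets. Default
#'   `list(c(0,1), c(-1,1), c(-1,0), c(-1,-1))`.
#' @param levels Number of gray levels (<= 256, default 256).
#' @param symmetric Add the transpose so `p == t(p)` (default TRUE).
#' @param normalize Normalize counts to sum 1 (default TRUE).
#'
#' @return An object of class `cooccurrence_matrix`: list with `p`
#'   (levels x levels matrix), `offsets`, `levels`, `symmetric`,
#'   `normalized`.
#' @export
#' @examples
#' g <- compute_glcm(matrix(c(0, 1, 0, 1), 2, 2), levels = 2)
#' sum(g$p)
compute_glcm <- function(image,
                         offsets = list(c(0L, 1L), c(-1L, 1L),
                                        c(-1L, 0L), c(-1L, -1L)),
                         levels = 256, symmetric = TRUE, normalize = TRUE) {
  px <- as_pixel_matrix(image)
  if (!length(px)) stop("empty image")
  if (levels < 2 || levels > 256) stop("levels must be in 2..256")
  if (min(px) < 0 || max(px) > 255) stop("image values must lie in 0..255")
  direct <- all(px == floor(px)) && max(px) <= levels - 1
  bins <- if (direct) px else pmin(floor(px * levels / 256), levels - 1)
  storage.mode(bins) <- "integer"
  h <- nrow(bins); w <- ncol(bins)
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    if (abs(dr) >= h || abs(dc) >= w)
      stop(sprintf("offset (%d, %d) exceeds image extent %d x %d",
                   dr, dc, h, w))
    rows <- seq(max(1, 1 - dr), min(h, h - dr))
    cols <- seq(max(1, 1 - dc), min(w, w - dc))
    i <- bins[rows, cols, drop = FALSE]
    j <- bins[rows + dr, cols + dc, drop = FALSE]
    tab <- tabulate(as.vector(i) * levels + as.vector(j) + 1L,
                    nbins = levels * levels)
    counts <- counts + matrix(tab, levels, levels, byrow = TRUE)
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  if (total == 0) stop("no valid pixel pairs for the given offsets")
  p <- if (normalize) counts / total else counts
  structure(list(p = p, offsets = offsets, levels = levels,
                 symmetric = symmetric, normalized = normalize),
            class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf("<cooccurrence_matrix> %d levels, %d offset(s)%s%s\n",
              x$levels, length(x$offsets),
              if (x$symmetric) ", symmetric" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

glcm_p <- function(p) {
  if (inherits(p, "cooccurrence_matrix")) p <- p$p
  if (!is.matrix(p) || nrow(p) != ncol(p) || any(p < 0))
    stop("expected a square nonnegative co-occurrence matrix")
  if (abs(sum(p) - 1) > 1e-9)
    stop("co-occurrence matrix must be normalized (sum 1)")
  p
}

#' Angular second moment (textural uniformity)
#'
#' The sum of squared entries of the normalized co-occurrence matrix,
#' `sum_ij p(i,j)^2`. Equals 1 exactly for a constant image and decreases
#' toward `1/levels^2` as the texture becomes more disordered.
#'
#' @param p A `cooccurrence_matrix` (normalized) or its matrix.
#' @return A number in (0, 1].
#' @export
asm <- function(p) {
  p <- glcm_p(p)
  sum(p^2)
}

#' Co-occurrence entropy (bits)
#'
#' `-sum_ij p(i,j) log2 p(i,j)` over the nonzero entries, with
#' `0 log 0 = 0`. Zero for a constant image; `2 log2(levels)` at most.
#'
#' @inheritParams asm
#' @return Nonnegative entropy in bits.
#' @export
glcm_entropy <- function(p) {
  p <- glcm_p(p)
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' The 14 Haralick texture features
#'
#' Computes Haralick's fourteen statistics of a normalized co-occurrence
#' distribution, in the fixed order: asm, contrast, correlation,
#' variance (sum of squares), idm (inverse difference moment),
#' sum_average, sum_variance, sum_entropy, entropy, difference_variance,
#' difference_entropy, imc1, imc2 (information measures of correlation)
#' and mcc (maximal correlation coefficient). Gray levels are indexed
#' 0-based; all entropies are in bits. Degenerate denominators
#' (zero marginal variance for correlation, zero marginal entropy for
#' imc1, fewer than two populated levels for mcc) yield 0.
#'
#' Sum variance is centered on the sum average (the widely used reading
#' of the original definition).
#'
#' @inheritParams asm
#' @return A [feature_vector()] of length 14.
#' @export
#' @examples
#' g <- compute_glcm(matrix(rep(0:3, 8), 4, 8), levels = 4)
#' haralick_features(g)
haralick_features <- function(p) {
  p <- glcm_p(p)
  ng <- nrow(p)
  lev <- 0:(ng - 1)
  px <- rowSums(p)
  py <- colSums(p)
  ii <- matrix(lev, ng, ng)              # row level index
  jj <- t(ii)                            # col level index
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))

  # distributions of i+j (0 .. 2(ng-1)) and |i-j| (0 .. ng-1)
  p_sum <- vapply(0:(2 * ng - 2), function(k) sum(p[ii + jj == k]), 0)
  p_diff <- vapply(0:(ng - 1), function(k) sum(p[abs(ii - jj) == k]), 0)
  ks <- 0:(2 * ng - 2)
  kd <- 0:(ng - 1)

  ent_bits <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }

  f1 <- sum(p^2)
  f2 <- sum(kd^2 * p_diff)
  f3 <- if (sd_x > 0 && sd_y > 0)
    (sum(ii * jj * p) - mu_x * mu_y) / (sd_x * sd_y) else 0
  f4 <- sum((ii - mu_x)^2 * p)
  f5 <- sum(p / (1 + (ii - jj)^2))
  f6 <- sum(ks * p_sum)
  f7 <- sum((ks - f6)^2 * p_sum)
  f8 <- ent_bits(p_sum)
  f9 <- ent_bits(p)
  mu_d <- sum(kd * p_diff)
  f10 <- sum((kd - mu_d)^2 * p_diff)
  f11 <- ent_bits(p_diff)

  hx <- ent_bits(px)
  hy <- ent_bits(py)
  pxy <- outer(px, py)
  pos <- p > 0 & pxy > 0
  hxy1 <- -sum(p[pos] * log2(pxy[pos]))
  hxy2 <- ent_bits(pxy)
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - f9))))
  f14 <- mcc_feature(p, px, py)

  feature_vector(
    c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14),
    c("asm", "contrast", "correlation", "variance", "idm",
      "sum_average", "sum_variance", "sum_entropy", "entropy",
      "difference_variance", "difference_entropy", "imc1", "imc2", "mcc"),
    extractor_id = "glcm")
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue
# of Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), restricted to levels
# with positive marginals; 0 when fewer than two such levels exist.
mcc_feature <- function(p, px, py) {
  keep_i <- px > 0
  keep_k <- py > 0
  if (sum(keep_i) < 2) return(0)
  sub <- p[keep_i, keep_k, drop = FALSE]
  a <- sub / px[keep_i]
  b <- sweep(sub, 2, py[keep_k], "/")
  q <- a %*% t(b)
  ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, ev[2]))
}
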