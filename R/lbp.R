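#' Local binary pattern configuration
#'
#' The default — 8 neighbors at radii 1, 2 and 3 pixels, each code
#' histogram folded into 16 equal-width bins — yields a 48-dimensional
#' descriptor (3 neighborhoods x 16 bins).
#'
#' @param neighborhoods List of `c(P, R)` pairs: P circular neighbors at
#'   radius R pixels. Default `list(c(8,1), c(8,2), c(8,3))`.
#' @param bins_per_neighborhood Number of equal-width histogram bins over
#'   the code range `[0, 2^P)` (default 16).
#' @param normalize Normalize each per-neighborhood histogram to sum 1
#'   (default TRUE).
#' @return An object of class `lbp_config`.
#' @export
lbp_config <- function(neighborhoods = list(c(8, 1), c(8, 2), c(8, 3)),
                       bins_per_neighborhood = 16, normalize = TRUE) {
  for (nb in neighborhoods) {
    if (length(nb) != 2 || nb[1] < 4 || nb[2] < 1)
      stop("each neighborhood must be c(P >= 4, R >= 1)")
  }
  if (bins_per_neighborhood < 1) stop("need >= 1 bin")
  structure(list(neighborhoods = neighborhoods,
                 bins_per_neighborhood = bins_per_neighborhood,
                 normalize = normalize),
            class = "lbp_config")
}

# Neighbor displacements for P points on the radius-R circle, angle
# 2*pi*p/P, p = 0..P-1: column p+1 holds c(drow, dcol). Row axis points
# down, so the p-th neighbor sits at (r - R sin a, c + R cos a).
# Near-integer displacements are snapped to avoid spurious interpolation.
lbp_offsets <- function(P, R) {
  a <- 2 * pi * (0:(P - 1)) / P
  dr <- -R * sin(a)
  dc <- R * cos(a)
  snap <- function(x) ifelse(abs(x - round(x)) < 1e-6, round(x), x)
  rbind(dr = snap(dr), dc = snap(dc))
}

# Bilinearly interpolated neighbor plane for one displacement, evaluated
# at every center in rows x cols (index vectors into `img`).
lbp_neighbor_plane <- function(img, rows, cols, dr, dc) {
  r0 <- floor(dr); fr <- dr - r0
  c0 <- floor(dc); fc <- dc - c0
  g <- function(ro, co) img[rows + ro, cols + co, drop = FALSE]
  if (fr == 0 && fc == 0) return(g(r0, c0))
  (1 - fr) * (1 - fc) * g(r0, c0) +
    (1 - fr) * fc * g(r0, c0 + 1) +
    fr * (1 - fc) * g(r0 + 1, c0) +
    fr * fc * g(r0 + 1, c0 + 1)
}

# Comparison tolerance: a neighbor counts as >= the center whenever
# g_p - g_c >= -LBP_EPS, so exactly-equal neighbors set their bit even
# under bilinear floating-point rounding.
LBP_EPS <- 1e-7

lbp_code_matrix <- function(px, P, R) {
  margin <- ceiling(R)
  h <- nrow(px); w <- ncol(px)
  if (h < 2 * margin + 1 || w < 2 * margin + 1)
    stop(sprintf("image %d x %d too small for radius %g", h, w, R))
  rows <- (margin + 1):(h - margin)
  cols <- (margin + 1):(w - margin)
  centers <- px[rows, cols, drop = FALSE]
  off <- lbp_offsets(P, R)
  codes <- matrix(0, nrow(centers), ncol(centers))
  for (p in 0:(P - 1)) {
    nb <- lbp_neighbor_plane(px, rows, cols, off["dr", p + 1],
                             off["dc", p + 1])
    codes <- codes + (nb - centers >= -LBP_EPS) * 2^p
  }
  codes
}

#' Local binary pattern code of one pixel
#'
#' Thresholds the P circular neighbors at radius R against the center
#' (bilinear interpolation off the pixel grid) and packs the results as
#' bits: `sum_p 1[g_p - g_c >= 0] * 2^p`. A neighbor exactly equal to the
#' center sets its bit.
#'
#' @param image An `eeg_heatmap` or numeric matrix.
#' @param center `c(row, col)` of the center pixel (1-based); must be at
#'   least `ceiling(R)` away from every border.
#' @param P Number of neighbors (>= 4).
#' @param R Circle radius in pixels (>= 1).
#' @return Integer code in `0 .. 2^P - 1`.
#' @export
#' @examples
#' m <- matrix(0, 3, 3); m[2, 2] <- 5
#' lbp_code(m, c(2, 2), P = 8, R = 1)  # all neighbors below center -> 0
lbp_code <- function(image, center, P = 8, R = 1) {
  px <- as_pixel_matrix(image)
  margin <- ceiling(R)
  r <- center[1]; c <- center[2]
  if (r <= margin || r > nrow(px) - margin ||
      c <= margin || c > ncol(px) - margin)
    stop(sprintf("center (%d, %d) is within radius %g of the border",
                 r, c, R))
  off <- lbp_offsets(P, R)
  gc <- px[r, c]
  code <- 0
  for (p in 0:(P - 1)) {
    nb <- lbp_neighbor_plane(px, r, c, off["dr", p + 1], off["dc", p + 1])
    code <- code + (nb - gc >= -LBP_EPS) * 2^p
  }
  as.integer(code)
}

#' Multi-scale local binary pattern histogram features
#'
#' For every `(P, R)` neighborhood, computes the LBP code of each valid
#' pixel, folds the code histogram into `bins_per_neighborhood`
#' equal-width bins over `[0, 2^P)`, normalizes it to sum 1, and
#' concatenates the histograms. The default configuration yields 48
#' features. Codes depend only on gray-level differences, so the
#' descriptor is invariant to a global additive offset (absent
#' saturation).
#'
#' @param image An `eeg_heatmap` or numeric matrix.
#' @param config An [lbp_config()].
#' @return A [feature_vector()] of length
#'   `length(neighborhoods) * bins_per_neighborhood`.
#' @export
#' @examples
#' length(lbp_features(matrix(runif(400, 0, 255), 20, 20)))
lbp_features <- function(image, config = lbp_config()) {
  px <- as_pixel_matrix(image)
  stopifnot(inherits(config, "lbp_config"))
  out <- lapply(config$neighborhoods, function(nb) {
    P <- nb[1]; R <- nb[2]
    codes <- lbp_code_matrix(px, P, R)
    nb_bins <- config$bins_per_neighborhood
    width <- 2^P / nb_bins
    h <- tabulate(pmin(floor(codes / width), nb_bins - 1) + 1L,
                  nbins = nb_bins)
    if (config$normalize) h <- h / sum(h)
    stats::setNames(h, sprintf("lbp_P%d_R%g_b%02d", P, R, seq_len(nb_bins)))
  })
  feature_vector(unlist(out), names(unlist(out)), extractor_id = "lbp")
}
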