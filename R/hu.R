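#' Hu's seven invariant moments
#'
#' Treats the gray image as a 2D mass density, computes central moments
#' `mu_pq` about the intensity centroid (translation invariance),
#' normalizes them as `eta_pq = mu_pq / mu_00^alpha` (scale invariance)
#' and combines them into the seven classical rotation-invariant values
#' `phi_1 .. phi_7`.
#'
#' The default exponent is the standard `alpha = (p + q)/2 + 1`, the
#' value for which `eta_pq` is actually invariant under uniform
#' rescaling. `exponent = "printed"` switches to `alpha = (p + q)/2`, a
#' variant sometimes printed in the literature that is not
#' scale-invariant; it is provided for comparability only.
#'
#' @param image An `eeg_heatmap` or numeric nonnegative matrix with at
#'   least one positive pixel.
#' @param exponent `"standard"` or `"printed"` (see above).
#' @return A [feature_vector()] of length 7 named `phi1` .. `phi7`.
#' @export
#' @examples
#' sq <- matrix(0, 16, 16); sq[5:12, 5:12] <- 1
#' hu_moments(sq)
hu_moments <- function(image, exponent = c("standard", "printed")) {
  exponent <- match.arg(exponent)
  px <- as_pixel_matrix(image)
  if (any(px < 0)) stop("image intensities must be nonnegative")
  m00 <- sum(px)
  if (m00 <= 0) stop("all-zero image: moments undefined")
  rows <- seq_len(nrow(px))
  cols <- seq_len(ncol(px))
  # x along columns, y along rows (any consistent convention works for
  # the invariants)
  xbar <- sum(t(px) * cols) / m00
  ybar <- sum(px * rows) / m00
  dy <- rows - ybar
  dx <- cols - xbar
  mu <- function(p, q) sum(outer(dy^q, dx^p) * px)
  eta <- function(p, q) {
    a <- if (exponent == "standard") (p + q) / 2 + 1 else (p + q) / 2
    mu(p, q) / m00^a
  }
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  phi1 <- n20 + n02
  phi2 <- (n20 - n02)^2 + 4 * n11^2
  phi3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  phi4 <- (n30 + n12)^2 + (n21 + n03)^2
  phi5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  phi6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  phi7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  feature_vector(c(phi1, phi2, phi3, phi4, phi5, phi6, phi7),
                 paste0("phi", 1:7), extractor_id = "hu")
}
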