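#' Construct a named feature vector
#'
#' Light container tying an ordered numeric vector to the extractor that
#' produced it.
#'
#' @param values Finite numeric vector.
#' @param names Character vector of feature names, same length.
#' @param extractor_id Identifier of the extractor (e.g. `"glcm"`,
#'   `"lbp"`, `"hu"`, `"mobilenet"`).
#' @return A named numeric vector of class `feature_vector` with
#'   attribute `extractor_id`.
#' @export
feature_vector <- function(values, names, extractor_id) {
  if (length(values) != length(names))
    stop("values and names must have equal length")
  if (!all(is.finite(values)))
    stop(sprintf("non-finite feature value from extractor '%s'",
                 extractor_id))
  structure(stats::setNames(as.numeric(values), names),
            extractor_id = extractor_id,
            class = c("feature_vector", "numeric"))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s (%d features)\n",
              attr(x, "extractor_id"), length(x)))
  print(utils::head(unclass(x), 10), ...)
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Extract the traditional texture descriptors from an image
#'
#' Runs the co-occurrence (14 Haralick statistics), local binary pattern
#' (48 histogram bins by default) and Hu invariant-moment (7) extractors
#' and concatenates them in that fixed order, for a total of 69 features
#' when `which = "all"`.
#'
#' @param image An `eeg_heatmap` or a numeric matrix of gray values in
#'   0..255.
#' @param which `"glcm"`, `"lbp"`, `"hu"` or `"all"`.
#' @param glcm_args List of arguments forwarded to [compute_glcm()]
#'   (offsets, levels, symmetric).
#' @param lbp An [lbp_config()].
#' @param hu_exponent Normalization exponent convention for
#'   [hu_moments()].
#' @return A [feature_vector()].
#' @export
#' @examples
#' img <- matrix(rep(0:255, length.out = 32 * 32), 32, 32)
#' length(extract_traditional(img, "all"))
extract_traditional <- function(image, which = c("all", "glcm", "lbp", "hu"),
                                glcm_args = list(), lbp = lbp_config(),
                                hu_exponent = "standard") {
  which <- match.arg(which)
  px <- as_pixel_matrix(image)
  parts <- list()
  if (which %in% c("glcm", "all")) {
    p <- do.call(compute_glcm, c(list(px), glcm_args))
    parts$glcm <- haralick_features(p)
  }
  if (which %in% c("lbp", "all"))
    parts$lbp <- lbp_features(px, lbp)
  if (which %in% c("hu", "all"))
    parts$hu <- hu_moments(px, exponent = hu_exponent)
  feature_vector(unlist(lapply(parts, as.numeric)),
                 unlist(lapply(parts, names)),
                 extractor_id = which)
}
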