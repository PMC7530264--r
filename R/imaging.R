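#' Compose the heat-map image from a quantized recording
#'
#' Each selected channel becomes a vertical block of `block_width`
#' identical pixel columns; time runs down the rows. With the defaults
#' (11 channels, 1024 samples, 32-pixel blocks) the result is the
#' 1024 x 352 8-bit image: smooth blocks for low-frequency channels,
#' rough texture for high-frequency ones. Column replication (rather
#' than interpolation) keeps the map invertible: averaging the columns
#' of a block recovers the quantized series exactly.
#'
#' @param q A `quantized_recording` (see [normalize_quantize()]).
#' @param config A [pipeline_config()]; `time_length`, `block_width` and
#'   `pad_mode` are used. Recordings longer than `time_length` are
#'   truncated; shorter ones are an error unless `pad_mode = "edge"`.
#'
#' @return An object of class `eeg_heatmap`: list with `pixels`
#'   (`time_length` x `n_channels * block_width` integer matrix in
#'   0..255), `layout` (data.frame: channel, first/last column) and
#'   provenance fields `label`, `subject_id`.
#' @export
#' @examples
#' cfg <- pipeline_config(time_length = 4, block_width = 3)
#' q <- structure(list(channel_names = c("A", "B"),
#'                     values = matrix(0:7, 2, 4, byrow = TRUE),
#'                     quant_levels = 256, label = "unknown",
#'                     subject_id = ""), class = "quantized_recording")
#' dim(compose_heatmap(q, cfg)$pixels)
compose_heatmap <- function(q, config = pipeline_config()) {
  stopifnot(inherits(q, "quantized_recording"),
            inherits(config, "pipeline_config"))
  n_ch <- nrow(q$values)
  n_s <- ncol(q$values)
  if (n_ch < 1 || n_s < 1) stop("quantized recording is empty")
  tl <- config$time_length
  v <- q$values
  if (n_s > tl) v <- v[, seq_len(tl), drop = FALSE]
  if (n_s < tl) {
    if (config$pad_mode != "edge")
      stop(sprintf(
        "recording has %d samples but time_length is %d (enable pad_mode)",
        n_s, tl))
    v <- cbind(v, v[, rep(n_s, tl - n_s), drop = FALSE])
  }
  bw <- config$block_width
  # samples down the rows, channel blocks across the columns
  pixels <- t(v)[, rep(seq_len(n_ch), each = bw), drop = FALSE]
  dimnames(pixels) <- NULL
  layout <- data.frame(channel = q$channel_names,
                       col_start = (seq_len(n_ch) - 1L) * bw + 1L,
                       col_end = seq_len(n_ch) * bw,
                       stringsAsFactors = FALSE)
  structure(list(pixels = pixels, layout = layout,
                 label = q$label, subject_id = q$subject_id),
            class = "eeg_heatmap")
}

#' @export
print.eeg_heatmap <- function(x, ...) {
  cat(sprintf("<eeg_heatmap> %d x %d pixels, %d channel blocks (%s)\n",
              nrow(x$pixels), ncol(x$pixels), nrow(x$layout), x$label))
  invisible(x)
}

#' @export
#' @importFrom graphics image
plot.eeg_heatmap <- function(x, ...) {
  # orient so time runs top-to-bottom as in the composed image
  m <- t(x$pixels)[, rev(seq_len(nrow(x$pixels))), drop = FALSE]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  xlab = "channel blocks", ylab = "time (samples)", ...)
  invisible(x)
}

#' Write / read a heat-map image as 8-bit grayscale PNG
#'
#' `write_png()` stores the pixel grid losslessly as a single-channel
#' 8-bit PNG; `read_png()` restores it and refuses files that are not
#' 8-bit grayscale.
#'
#' @param image An `eeg_heatmap`.
#' @param path PNG file path.
#' @return `read_png()` returns an `eeg_heatmap` (layout metadata is not
#'   stored in the PNG; the restored object carries a single full-width
#'   block and unknown provenance). `write_png()` returns `path`
#'   invisibly.
#' @export
write_png <- function(image, path) {
  stopifnot(inherits(image, "eeg_heatmap"))
  px <- image$pixels
  if (any(px < 0 | px > 255)) stop("pixels must lie in 0..255")
  png::writePNG(px / 255, path)
  invisible(path)
}

#' @rdname write_png
#' @export
read_png <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  if (length(dim(arr)) != 2)
    stop(sprintf("%s is not a single-channel grayscale PNG", path))
  if (!is.null(info$bit.depth) && info$bit.depth != 8)
    stop(sprintf("%s is not 8-bit (bit depth %s)", path, info$bit.depth))
  px <- round(arr * 255)
  storage.mode(px) <- "integer"
  attributes(px) <- list(dim = dim(px))
  structure(list(pixels = px,
                 layout = data.frame(channel = NA_character_,
                                     col_start = 1L,
                                     col_end = ncol(px),
                                     stringsAsFactors = FALSE),
                 label = "unknown", subject_id = ""),
            class = "eeg_heatmap")
}

# Accept either an eeg_heatmap or a plain numeric matrix of gray values.
as_pixel_matrix <- function(image) {
  if (inherits(image, "eeg_heatmap")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  stop("expected an eeg_heatmap or a numeric matrix")
}
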