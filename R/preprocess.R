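#' Pipeline configuration
#'
#' Settings for the signal-conditioning stage: which channels to keep,
#' the outlier threshold, the quantization depth and the image geometry.
#'
#' @param channel_mode `"fixed-list"` (keep the electrodes in
#'   `fixed_channels`, in that order) or `"top-k"` (keep the `top_k`
#'   channels with the highest mean variance).
#' @param fixed_channels Electrode labels for fixed-list mode; default the
#'   11 channels of [default_channels()].
#' @param top_k Number of channels kept in top-k mode (default 11).
#' @param clip_threshold Outlier threshold in uV (default 73.3); samples
#'   beyond +/- this value are treated as artifacts.
#' @param outlier_mode `"clip"` (saturate at the threshold) or `"drop"`
#'   (replace by linear interpolation of the neighboring in-range samples).
#' @param normalization `"global"` (min-max over all selected channels
#'   jointly, the default) or `"per-channel"`.
#' @param time_length Number of time samples per image (default 1024).
#' @param block_width Pixel width of each channel block (default 32).
#' @param quant_levels Number of gray levels (default 256, i.e. 8-bit).
#' @param pad_mode `"off"` (recordings shorter than `time_length` are an
#'   error) or `"edge"` (repeat the final sample).
#'
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' pipeline_config(top_k = 5, channel_mode = "top-k")
pipeline_config <- function(channel_mode = c("fixed-list", "top-k"),
                            fixed_channels = default_channels(),
                            top_k = 11,
                            clip_threshold = 73.3,
                            outlier_mode = c("clip", "drop"),
                            normalization = c("global", "per-channel"),
                            time_length = 1024,
                            block_width = 32,
                            quant_levels = 256,
                            pad_mode = c("off", "edge")) {
  channel_mode <- match.arg(channel_mode)
  outlier_mode <- match.arg(outlier_mode)
  normalization <- match.arg(normalization)
  pad_mode <- match.arg(pad_mode)
  if (clip_threshold <= 0) stop("clip_threshold must be > 0")
  if (top_k < 1) stop("top_k must be >= 1")
  if (quant_levels < 2) stop("quant_levels must be >= 2")
  if (anyDuplicated(fixed_channels)) stop("fixed_channels must be unique")
  if (time_length < 1 || block_width < 1)
    stop("time_length and block_width must be positive")
  structure(list(channel_mode = channel_mode,
                 fixed_channels = as.character(fixed_channels),
                 top_k = as.integer(top_k),
                 clip_threshold = clip_threshold,
                 outlier_mode = outlier_mode,
                 normalization = normalization,
                 time_length = as.integer(time_length),
                 block_width = as.integer(block_width),
                 quant_levels = as.integer(quant_levels),
                 pad_mode = pad_mode),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  sel <- if (x$channel_mode == "fixed-list")
    sprintf("%d fixed channels", length(x$fixed_channels))
  else sprintf("top %d by mean variance", x$top_k)
  cat(sprintf(paste0(
    "<pipeline_config> %s; clip +/-%g uV (%s); %s min-max; ",
    "%d levels; image %d x (k*%d)\n"),
    sel, x$clip_threshold, x$outlier_mode, x$normalization,
    x$quant_levels, x$time_length, x$block_width))
  invisible(x)
}

#' Rank channels by mean variance across recordings
#'
#' Computes the sample variance of every channel in every recording,
#' averages per channel across recordings, and sorts in decreasing order.
#' Ties are broken alphabetically by channel name. This reproduces the
#' selection rule that picked the 11 high-activity electrodes: channels
#' with intense activity (high-frequency, high-amplitude signal) rank
#' first.
#'
#' @param recordings A list of [eeg_recording()] objects sharing one
#'   channel set (order may differ).
#' @return A data.frame with columns `channel` and `mean_variance`,
#'   ordered by decreasing mean variance.
#' @export
channel_variance_ranking <- function(recordings) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  if (!length(recordings)) stop("no recordings given")
  ref <- sort(recordings[[1]]$channel_names)
  per_rec <- lapply(recordings, function(r) {
    if (!identical(sort(r$channel_names), ref)) {
      extra <- setdiff(r$channel_names, ref)
      missing <- setdiff(ref, r$channel_names)
      stop(sprintf(
        "inconsistent channel sets (extra: %s; missing: %s)",
        paste(extra, collapse = ","), paste(missing, collapse = ",")))
    }
    v <- apply(r$data, 1, stats::var)
    v[ref]
  })
  mv <- Reduce(`+`, per_rec) / length(per_rec)
  ord <- order(-mv, ref)
  data.frame(channel = ref[ord], mean_variance = unname(mv[ord]),
             stringsAsFactors = FALSE)
}

#' Restrict a recording to the analysis channels
#'
#' In fixed-list mode the rows are restricted to and ordered by
#' `config$fixed_channels`; in top-k mode they follow the mean-variance
#' ranking of this recording (or of `ranking` when the ranking was
#' computed over a whole dataset).
#'
#' @param recording An [eeg_recording()].
#' @param config A [pipeline_config()].
#' @param ranking Optional precomputed [channel_variance_ranking()] table
#'   used in top-k mode.
#' @return An [eeg_recording()] with the selected rows.
#' @export
select_channels <- function(recording, config = pipeline_config(),
                            ranking = NULL) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(config, "pipeline_config"))
  keep <- if (config$channel_mode == "fixed-list") {
    missing <- setdiff(config$fixed_channels, recording$channel_names)
    if (length(missing))
      stop(sprintf("channel(s) not present in recording: %s",
                   paste(missing, collapse = ", ")))
    config$fixed_channels
  } else {
    if (is.null(ranking)) ranking <- channel_variance_ranking(recording)
    utils::head(ranking$channel, config$top_k)
  }
  eeg_recording(recording$data[keep, , drop = FALSE], keep,
                recording$sampling_rate, label = recording$label,
                subject_id = recording$subject_id)
}

#' Remove amplitude outliers from a signal
#'
#' Samples beyond +/-`threshold` microvolts (head and eye movement
#' artifacts) are either saturated at the threshold (`"clip"`, length
#' preserving and idempotent) or replaced by linear interpolation between
#' the nearest in-range neighbors (`"drop"`; out-of-range runs at either
#' end take the nearest valid value).
#'
#' @param signal Numeric vector in uV.
#' @param threshold Positive threshold in uV (default 73.3).
#' @param mode `"clip"` or `"drop"`.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' remove_outliers(c(80, -80, 10))
remove_outliers <- function(signal, threshold = 73.3,
                            mode = c("clip", "drop")) {
  mode <- match.arg(mode)
  if (threshold <= 0) stop("threshold must be > 0")
  if (mode == "clip") return(pmin(pmax(signal, -threshold), threshold))
  ok <- abs(signal) <= threshold
  if (!any(ok)) stop("all samples out of range; cannot interpolate")
  if (all(ok)) return(signal)
  idx <- seq_along(signal)
  stats::approx(idx[ok], signal[ok], xout = idx, rule = 2)$y
}

#' Normalize and quantize a recording to integer gray levels
#'
#' Min-max normalizes the selected channels to [0, 1] — jointly over the
#' whole recording by default, so relative channel amplitudes survive —
#' then rescales to `0 .. quant_levels - 1` with round-half-up:
#' `q(x) = floor(x * (quant_levels - 1) + 0.5)`. A constant recording
#' (zero range) maps to all zeros.
#'
#' @param recording An [eeg_recording()] (already channel-selected and
#'   outlier-treated).
#' @param config A [pipeline_config()].
#' @return An object of class `quantized_recording`: list with
#'   `channel_names`, `values` (integer matrix, channels x samples, in
#'   `[0, quant_levels - 1]`) and `quant_levels`; `label` and
#'   `subject_id` are carried through.
#' @export
normalize_quantize <- function(recording, config = pipeline_config()) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(config, "pipeline_config"))
  x <- recording$data
  if (!length(x)) stop("empty recording")
  if (!all(is.finite(x))) stop("recording contains non-finite values")
  L <- config$quant_levels
  rescale <- function(m) {
    rng <- range(m)
    if (rng[1] == rng[2]) return(array(0, dim = dim(m)))
    (m - rng[1]) / (rng[2] - rng[1])
  }
  norm <- if (config$normalization == "global") rescale(x)
  else t(apply(x, 1, function(row) {
    r <- range(row)
    if (r[1] == r[2]) rep(0, length(row)) else (row - r[1]) / (r[2] - r[1])
  }))
  q <- floor(norm * (L - 1) + 0.5)
  storage.mode(q) <- "integer"
  dimnames(q) <- list(recording$channel_names, NULL)
  structure(list(channel_names = recording$channel_names,
                 values = q,
                 quant_levels = L,
                 label = recording$label,
                 subject_id = recording$subject_id),
            class = "quantized_recording")
}

#' @export
print.quantized_recording <- function(x, ...) {
  cat(sprintf("<quantized_recording> %d ch x %d samples, levels 0..%d\n",
              nrow(x$values), ncol(x$values), x$quant_levels - 1L))
  invisible(x)
}

#' Run the full signal-conditioning stage on one recording
#'
#' Convenience chain: [select_channels()] then [remove_outliers()] on each
#' channel, then [normalize_quantize()].
#'
#' @inheritParams select_channels
#' @return A `quantized_recording`.
#' @export
preprocess_recording <- function(recording, config = pipeline_config(),
                                 ranking = NULL) {
  sel <- select_channels(recording, config, ranking)
  sel$data <- t(apply(sel$data, 1, remove_outliers,
                      threshold = config$clip_threshold,
                      mode = config$outlier_mode))
  rownames(sel$data) <- sel$channel_names
  normalize_quantize(sel, config)
}
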