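#' Standard 64-electrode montage labels
#'
#' A fixed set of 64 unique 10-20 / 10-10 system electrode labels used as the
#' default montage for synthetic recordings. It contains the 11 default
#' analysis channels (see [default_channels()]).
#'
#' @return Character vector of 64 unique electrode labels.
#' @export
#' @examples
#' length(montage_64())
montage_64 <- function() {
  c("FP1", "FP2", "FPZ", "AF3", "AF4", "AF7", "AF8", "AFZ",
    "F1", "F2", "F3", "F4", "F5", "F6", "F7", "F8", "FZ",
    "FC1", "FC2", "FC3", "FC4", "FC5", "FC6", "FCZ", "FT7", "FT8",
    "C1", "C2", "C3", "C4", "C5", "C6", "CZ", "T7", "T8",
    "CP1", "CP2", "CP3", "CP4", "CP5", "CP6", "CPZ", "TP7", "TP8",
    "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8", "PZ",
    "PO1", "PO2", "PO3", "PO4", "PO7", "PO8", "POZ",
    "O1", "O2", "OZ", "IZ")
}

#' Default analysis channels
#'
#' The 11 fronto-central/temporal electrodes selected by mean variance in the
#' screening pipeline: FP1, FP2, F7, F8, T7, T8, CZ, C3, C4, CP5, CP6.
#'
#' @return Character vector of 11 electrode labels.
#' @export
default_channels <- function() {
  c("FP1", "FP2", "F7", "F8", "T7", "T8", "CZ", "C3", "C4", "CP5", "CP6")
}

#' Construct a multichannel EEG recording
#'
#' Container for a channels-by-samples matrix of scalp potentials in
#' microvolts, with channel labels, sampling rate and a class label.
#'
#' @param data Numeric matrix, channels in rows, samples in columns. All
#'   values must be finite.
#' @param channel_names Character vector of unique channel labels, one per
#'   row of `data`.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param label Class label: `"control"`, `"alcoholic"` or `"unknown"`.
#' @param subject_id Free-form subject identifier.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `data`, `channel_names`, `sampling_rate`, `label`, `subject_id`.
#' @export
#' @examples
#' r <- eeg_recording(matrix(rnorm(8), 2, 4), c("CZ", "FP1"), 256)
#' r
eeg_recording <- function(data, channel_names, sampling_rate = 256,
                          label = c("unknown", "control", "alcoholic"),
                          subject_id = "") {
  label <- match.arg(label)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) != length(channel_names))
    stop(sprintf("data has %d rows but %d channel names given",
                 nrow(data), length(channel_names)))
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!all(is.finite(data)))
    stop("recording contains non-finite values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  rownames(data) <- channel_names
  structure(list(data = data,
                 channel_names = as.character(channel_names),
                 sampling_rate = sampling_rate,
                 label = label,
                 subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$sampling_rate))
  cat(sprintf("  label: %s%s\n", x$label,
              if (nzchar(x$subject_id))
                paste0("  subject: ", x$subject_id) else ""))
  shown <- utils::head(x$channel_names, 8)
  cat("  channels: ", paste(shown, collapse = ", "),
      if (length(x$channel_names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

class_labels <- function() c("control", "alcoholic")
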