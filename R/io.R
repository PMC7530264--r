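#' Read an EEG recording from a CSV matrix file
#'
#' One row per channel: the first field is the channel name, the remaining
#' fields are the samples in microvolts. All rows must have the same number
#' of samples.
#'
#' @param path Path to the CSV file.
#' @param sampling_rate Sampling rate in Hz to attach (default 256).
#' @param label Class label to attach (default `"unknown"`).
#' @param subject_id Subject identifier to attach (default the file name
#'   without extension).
#'
#' @return An [eeg_recording()].
#' @export
read_csv_recording <- function(path, sampling_rate = 256,
                               label = c("unknown", "control", "alcoholic"),
                               subject_id = NULL) {
  label <- match.arg(label)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty recording file: %s", path))
  fields <- strsplit(lines, ",", fixed = TRUE)
  lens <- lengths(fields)
  if (any(lens != lens[1])) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf(
      "ragged CSV: line %d has %d fields but line 1 has %d (%s)",
      bad, lens[bad], lens[1], path))
  }
  if (lens[1] < 2) stop("each row needs a channel name plus >= 1 sample")
  names <- trimws(vapply(fields, `[[`, "", 1))
  vals <- lapply(seq_along(fields), function(i) {
    v <- suppressWarnings(as.numeric(fields[[i]][-1]))
    if (anyNA(v))
      stop(sprintf("non-numeric sample value on line %d of %s", i, path))
    v
  })
  eeg_recording(do.call(rbind, vals), names, sampling_rate,
                label = label, subject_id = subject_id)
}

#' Write an EEG recording as a CSV matrix file
#'
#' Inverse of [read_csv_recording()]: one line per channel, name first,
#' samples after, full double precision.
#'
#' @param recording An [eeg_recording()] with at least one sample.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_csv_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (ncol(recording$data) == 0) stop("cannot write a 0-sample recording")
  rows <- vapply(seq_len(nrow(recording$data)), function(i) {
    paste(c(recording$channel_names[i],
            format(recording$data[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)),
          collapse = ",")
  }, "")
  tryCatch(writeLines(rows, path),
           error = function(e) stop(sprintf("cannot write %s: %s",
                                            path, conditionMessage(e))))
  invisible(path)
}

#' Read a recording in the UCI-style trial/channel/sample text dialect
#'
#' Lines are either comments starting with `#` or whitespace-delimited
#' records `trial channel sample value` (trial and sample are 0-based
#' integers). Channels are assembled in sample-index order and trials are
#' concatenated along time in ascending trial order, so a file with T
#' trials of S samples yields channels x (T*S) matrices. Parsing is
#' insensitive to the order of record lines; channels are ordered
#' alphabetically in the result.
#'
#' If a comment of the form `# co2a...` / `# co2c...` is present the
#' subject id is taken from it and the fourth character (`a`/`c`) sets the
#' label, matching the public EEG database naming scheme; otherwise the
#' `label` argument applies.
#'
#' @param path Path to the text file.
#' @param sampling_rate Sampling rate in Hz (default 256).
#' @param label Fallback class label.
#' @return An [eeg_recording()].
#' @export
read_uci_text <- function(path, sampling_rate = 256,
                          label = c("unknown", "control", "alcoholic")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- startsWith(trimws(lines), "#")
  subject_id <- sub("\\.[^.]*$", "", basename(path))
  id_line <- grep("^#\\s*co[0-9][ac]", trimws(lines), value = TRUE)
  if (length(id_line)) {
    tok <- strsplit(trimws(sub("^#\\s*", "", id_line[1])), "\\s+")[[1]][1]
    subject_id <- sub("\\.[^.]*$", "", tok)
    label <- if (substr(tok, 4, 4) == "a") "alcoholic" else "control"
  }
  rec_lines <- lines[!is_comment]
  if (!length(rec_lines))
    stop(sprintf("no data records in %s (comments only)", path))
  toks <- strsplit(trimws(rec_lines), "\\s+")
  if (any(lengths(toks) != 4)) {
    bad <- which(lengths(toks) != 4)[1]
    stop(sprintf("malformed record (need 4 fields) in %s: '%s'",
                 path, rec_lines[bad]))
  }
  trial <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 1)))
  chan <- vapply(toks, `[[`, "", 2)
  sample <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 3)))
  value <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 4)))
  if (anyNA(trial) || anyNA(sample) || anyNA(value))
    stop(sprintf("non-numeric trial/sample/value field in %s", path))
  key <- paste(trial, chan, sample)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (trial, channel, sample) record in %s: %s",
                 path, key[anyDuplicated(key)]))
  trials <- sort(unique(trial))
  chans <- sort(unique(chan))
  n_per_trial <- max(sample) + 1L
  # every (trial, channel) must cover samples 0 .. n_per_trial-1
  expected <- length(trials) * length(chans) * n_per_trial
  if (length(value) != expected) {
    have <- split(sample, paste(trial, chan))
    gaps <- names(have)[vapply(have, length, 0L) != n_per_trial]
    stop(sprintf("missing sample indices in %s for (trial channel): %s",
                 path, paste(utils::head(gaps, 5), collapse = "; ")))
  }
  data <- matrix(NA_real_, nrow = length(chans),
                 ncol = length(trials) * n_per_trial,
                 dimnames = list(chans, NULL))
  col <- match(trial, trials) * n_per_trial - n_per_trial + sample + 1L
  data[cbind(match(chan, chans), col)] <- value
  if (anyNA(data))
    stop(sprintf("missing sample indices in %s", path))
  eeg_recording(data, chans, sampling_rate, label = label,
                subject_id = subject_id)
}

#' Read or write a recording manifest
#'
#' A manifest is a CSV table with header `subject_id,label,path`, one row
#' per recording file. Paths must be unique and labels must be one of
#' control, alcoholic, unknown.
#'
#' @param path Manifest file path.
#' @return `read_manifest()` returns a data.frame with columns
#'   `subject_id`, `label`, `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(df)))
    stop("manifest needs columns subject_id, label, path")
  if (anyDuplicated(df$path)) stop("manifest paths must be unique")
  bad <- setdiff(unique(df$label), c(class_labels(), "unknown"))
  if (length(bad))
    stop(sprintf("unknown manifest label(s): %s", paste(bad, collapse = ", ")))
  df[need]
}

#' @rdname read_manifest
#' @param manifest Data.frame with columns `subject_id`, `label`, `path`.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns subject_id, label, path")
  utils::write.csv(manifest[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
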