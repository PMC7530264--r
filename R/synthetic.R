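#' Configuration for the synthetic EEG generator
#'
#' Describes the two-class recordings the generator emits: a 64-channel
#' montage at 256 Hz in which a small set of "active" channels carries a
#' band-limited multi-sinusoid whose frequency band depends on the class
#' (low-frequency for controls, high-frequency for alcoholic subjects),
#' all channels carry Gaussian noise, and rare artifact samples are
#' replaced by large-amplitude spikes exceeding the +/-73.3 uV clipping
#' threshold used downstream.
#'
#' @param n_channels Number of channels (default 64).
#' @param channel_names Channel labels; must have `n_channels` unique
#'   entries. Default [montage_64()].
#' @param sampling_rate Sampling rate in Hz (default 256).
#' @param n_samples Samples per recording (default 1024, one full image
#'   height without padding).
#' @param active_channels Labels receiving the class-dependent signal
#'   (default the 11 channels of [default_channels()]).
#' @param control_band Frequency interval in Hz for the control class
#'   (default `c(1, 7)`).
#' @param alcoholic_band Frequency interval in Hz for the alcoholic class
#'   (default `c(20, 50)`).
#' @param band_amplitude Total signal amplitude in uV; each of the
#'   `n_components` sinusoids gets `band_amplitude / n_components` so the
#'   class signal never exceeds `band_amplitude` in absolute value. May be
#'   a single number or a named vector `c(control = , alcoholic = )`.
#' @param n_components Number of equal-amplitude sinusoids summed to form
#'   the class signal (default 3).
#' @param noise_sd Gaussian noise standard deviation in uV (default 5).
#' @param artifact_rate Per-(channel, sample) probability of an artifact
#'   spike (default 0.001).
#' @param artifact_amplitude Spike magnitude in uV; must exceed 73.3 so
#'   every artifact trips the outlier rule (default 90).
#' @param seed Default seed used when the generation functions are called
#'   without one (optional).
#'
#' @return An object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_samples = 512)
#' cfg$alcoholic_band
synthetic_config <- function(n_channels = 64,
                             channel_names = montage_64(),
                             sampling_rate = 256,
                             n_samples = 1024,
                             active_channels = default_channels(),
                             control_band = c(1, 7),
                             alcoholic_band = c(20, 50),
                             band_amplitude = 20,
                             n_components = 3,
                             noise_sd = 5,
                             artifact_rate = 0.001,
                             artifact_amplitude = 90,
                             seed = NULL) {
  if (n_samples <= 0) stop("n_samples must be > 0")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (length(channel_names) != n_channels || anyDuplicated(channel_names))
    stop(sprintf("channel_names must hold %d unique labels", n_channels))
  nyquist <- sampling_rate / 2
  for (band in list(control = control_band, alcoholic = alcoholic_band)) {
    if (length(band) != 2 || band[1] > band[2] || band[1] <= 0 ||
        band[2] >= nyquist)
      stop(sprintf(
        "frequency bands must lie within (0, %g) Hz (Nyquist)", nyquist))
  }
  if (!all(active_channels %in% channel_names))
    stop("active_channels must be a subset of channel_names")
  if (artifact_amplitude <= 73.3)
    stop("artifact_amplitude must exceed 73.3 uV so spikes are outliers")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must be a probability")
  amp <- band_amplitude
  if (length(amp) == 1) amp <- c(control = unname(amp), alcoholic = unname(amp))
  if (!all(c("control", "alcoholic") %in% names(amp)))
    stop("band_amplitude must be a scalar or named c(control=, alcoholic=)")
  if (any(amp < 0) || noise_sd < 0) stop("amplitudes must be nonnegative")
  if (n_components < 1) stop("n_components must be >= 1")
  structure(list(n_channels = n_channels,
                 channel_names = as.character(channel_names),
                 sampling_rate = sampling_rate,
                 n_samples = n_samples,
                 active_channels = as.character(active_channels),
                 control_band = control_band,
                 alcoholic_band = alcoholic_band,
                 band_amplitude = amp,
                 n_components = n_components,
                 noise_sd = noise_sd,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 seed = seed),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_config> %d ch x %d samples @ %g Hz\n",
    "  active: %d channels; control %g-%g Hz, alcoholic %g-%g Hz\n",
    "  amplitude (uV): control %g, alcoholic %g; noise sd %g\n",
    "  artifacts: rate %g, amplitude %g uV\n"),
    x$n_channels, x$n_samples, x$sampling_rate,
    length(x$active_channels),
    x$control_band[1], x$control_band[2],
    x$alcoholic_band[1], x$alcoholic_band[2],
    x$band_amplitude["control"], x$band_amplitude["alcoholic"],
    x$noise_sd, x$artifact_rate, x$artifact_amplitude))
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

#' Generate one labeled synthetic EEG recording
#'
#' Active channels receive a sum of `n_components` equal-amplitude
#' sinusoids with frequencies drawn uniformly from the class band and
#' uniform random phases; every channel receives i.i.d. Gaussian noise;
#' finally each (channel, sample) cell is independently replaced by a
#' +/-`artifact_amplitude` spike with probability `artifact_rate`.
#' Generation is bit-reproducible for a fixed `(config, label, seed)`.
#'
#' @param config A [synthetic_config()].
#' @param label `"control"` or `"alcoholic"`.
#' @param seed Integer seed; falls back to `config$seed`.
#' @param subject_id Optional subject identifier.
#'
#' @return An [eeg_recording()].
#' @export
#' @examples
#' r <- generate_recording(synthetic_config(), "alcoholic", seed = 1)
#' dim(r)
generate_recording <- function(config, label = c("control", "alcoholic"),
                               seed = NULL, subject_id = "") {
  stopifnot(inherits(config, "synthetic_config"))
  label <- match.arg(label)
  if (is.null(seed)) seed <- config$seed
  band <- if (label == "control") config$control_band else config$alcoholic_band
  amp <- config$band_amplitude[[label]] / config$n_components
  with_seed(seed, {
    n <- config$n_samples
    t_sec <- (seq_len(n) - 1) / config$sampling_rate
    data <- matrix(0, nrow = config$n_channels, ncol = n)
    active <- config$channel_names %in% config$active_channels
    # Draw component frequencies from the DFT grid of the recording when
    # the band contains grid frequencies: the emitted spectrum then sits
    # exactly inside the configured band (no leakage), which keeps the
    # band power a clean class signature. Degenerate bands without a
    # grid frequency fall back to uniform draws.
    grid <- seq_len(max(1, floor(n / 2) - 1)) * config$sampling_rate / n
    grid <- grid[grid >= band[1] & grid <= band[2]]
    for (ch in which(active)) {
      freqs <- if (length(grid))
        grid[sample.int(length(grid), config$n_components, replace = TRUE)]
      else stats::runif(config$n_components, band[1], band[2])
      phases <- stats::runif(config$n_components, 0, 2 * pi)
      sig <- rep(0, n)
      for (k in seq_len(config$n_components))
        sig <- sig + amp * sin(2 * pi * freqs[k] * t_sec + phases[k])
      data[ch, ] <- sig
    }
    if (config$noise_sd > 0)
      data <- data + matrix(stats::rnorm(length(data), 0, config$noise_sd),
                            nrow = nrow(data))
    if (config$artifact_rate > 0) {
      hit <- stats::runif(length(data)) < config$artifact_rate
      if (any(hit)) {
        sign <- sample(c(-1, 1), sum(hit), replace = TRUE)
        data[hit] <- sign * config$artifact_amplitude
      }
    }
    eeg_recording(data, config$channel_names, config$sampling_rate,
                  label = label, subject_id = subject_id)
  })
}

#' Generate a balanced two-class synthetic dataset
#'
#' Produces `n_per_class` control and `n_per_class` alcoholic recordings.
#' Each recording gets its own seed derived deterministically from `seed`
#' and its index, so any subset can be regenerated independently.
#'
#' @param config A [synthetic_config()].
#' @param n_per_class Recordings per class (>= 1).
#' @param seed Integer base seed.
#'
#' @return List of [eeg_recording()] objects, controls first.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_samples = 256), 2, seed = 7)
#' vapply(ds, function(r) r$label, "")
generate_dataset <- function(config, n_per_class, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (is.null(seed)) seed <- if (is.null(config$seed)) 0 else config$seed
  labels <- rep(c("control", "alcoholic"), each = n_per_class)
  ids <- sprintf("%s_%03d", labels, rep(seq_len(n_per_class), 2))
  lapply(seq_along(labels), function(i) {
    generate_recording(config, labels[i],
                       seed = (seed + 7919 * i) %% .Machine$integer.max,
                       subject_id = ids[i])
  })
}
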