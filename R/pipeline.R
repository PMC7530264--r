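#' Run the full screening pipeline from a manifest
#'
#' Reads every recording listed in the manifest, applies the
#' signal-conditioning stage (channel selection, outlier treatment,
#' quantization), composes the heat-map image, extracts the requested
#' features, and evaluates a classifier family over repeated stratified
#' splits. Errors are re-raised with the pipeline stage that produced
#' them.
#'
#' @param manifest Path to a manifest CSV or a data.frame with columns
#'   `subject_id`, `label`, `path` (see [read_manifest()]). Paths may be
#'   relative to the manifest location.
#' @param config A [pipeline_config()].
#' @param extractor `"glcm"`, `"lbp"`, `"hu"`, `"all"`, or a registered
#'   backbone name (in which case `backbone` must be supplied).
#' @param family Classifier family (see [hyperparam_space()]).
#' @param seed Integer seed for the evaluation stage.
#' @param backbone Optional backbone callable for deep extraction (see
#'   [extract_deep()]).
#' @param sampling_rate Sampling rate attached to the recordings read
#'   from CSV (default 256 Hz).
#' @param ... Passed to [evaluate()] (`n_splits`, `n_iter`, ...).
#' @return An object of class `eeg_pipeline_result`: list with `eval`
#'   (the [evaluate()] result), `features`, `labels`, `extractor`,
#'   `config`, `seed`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         extractor = "lbp", family = "rf", seed = NULL,
                         backbone = NULL, sampling_rate = 256, ...) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- stage("eeg_io", read_manifest(manifest))
  }
  recs <- stage("eeg_io", lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, manifest$path[i])
    if (!file.exists(p))
      stop(sprintf("file not found: %s", manifest$path[i]))
    lab <- manifest$label[i]
    read_csv_recording(p, sampling_rate = sampling_rate, label = lab,
                       subject_id = manifest$subject_id[i])
  }))
  quantized <- stage("preprocess",
                     lapply(recs, preprocess_recording, config = config))
  images <- stage("imaging",
                  lapply(quantized, compose_heatmap, config = config))
  deep <- !(extractor %in% c("glcm", "lbp", "hu", "all"))
  feats <- stage(if (deep) "deep_features" else "texture_features", {
    if (deep) {
      spec <- backbone_spec(extractor)
      if (is.null(backbone))
        stop(sprintf("extractor '%s' needs a backbone callable",
                     extractor))
      lapply(images, extract_deep, spec = spec, backbone = backbone)
    } else {
      lapply(images, extract_traditional, which = extractor)
    }
  })
  x <- do.call(rbind, lapply(feats, as.numeric))
  colnames(x) <- names(feats[[1]])
  labels <- vapply(recs, function(r) r$label, "")
  ev <- stage("classify_eval",
              evaluate(x, labels, family, seed = seed, ...))
  structure(list(eval = ev, features = x, labels = labels,
                 extractor = extractor, family = family,
                 config = config, seed = seed),
            class = "eeg_pipeline_result")
}

#' @export
print.eeg_pipeline_result <- function(x, ...) {
  cat(sprintf("<eeg_pipeline_result> %d recordings, extractor %s\n",
              length(x$labels), x$extractor))
  print(x$eval)
  invisible(x)
}

#' Machine-readable report of a pipeline run
#'
#' Serializes the configuration, seeds, chosen hyperparameters and
#' per-split metrics of a pipeline result as JSON.
#'
#' @param result An `eeg_pipeline_result` or `eeg_eval`.
#' @param path Optional output path; when omitted the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
pipeline_report <- function(result, path = NULL) {
  ev <- if (inherits(result, "eeg_pipeline_result")) result$eval else result
  stopifnot(inherits(ev, "eeg_eval"))
  payload <- list(
    family = ev$family,
    n_splits = ev$n_splits,
    test_fraction = ev$test_fraction,
    seed = ev$seed,
    metrics_mean = as.list(ev$mean),
    metrics_sd = as.list(ev$sd),
    per_split = ev$per_split,
    chosen_params = ev$chosen_params)
  if (inherits(result, "eeg_pipeline_result")) {
    payload$extractor <- result$extractor
    payload$config <- unclass(result$config)
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
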