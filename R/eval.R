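#' One-vs-rest confusion counts
#'
#' For each class, counts true/false positives and negatives of the
#' one-vs-rest view of the predictions.
#'
#' @param labels True class labels.
#' @param predictions Predicted labels (same length); every prediction
#'   must be one of `classes`.
#' @param classes Class universe (default: sorted union of the labels).
#' @return An object of class `confusion_counts`: named list per class
#'   with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion(c("a", "a", "b"), c("a", "b", "b"))
confusion <- function(labels, predictions, classes = NULL) {
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (!length(labels)) stop("empty test set")
  if (is.null(classes)) classes <- sort(unique(c(labels)))
  if (!all(labels %in% classes))
    stop("labels outside the declared class set")
  bad <- setdiff(unique(predictions), classes)
  if (length(bad))
    stop(sprintf("unknown prediction label(s): %s",
                 paste(bad, collapse = ", ")))
  out <- lapply(classes, function(cl) {
    pos <- labels == cl
    ppos <- predictions == cl
    list(tp = sum(pos & ppos), fp = sum(!pos & ppos),
         tn = sum(!pos & !ppos), fn = sum(pos & !ppos))
  })
  structure(stats::setNames(out, classes), class = "confusion_counts")
}

#' Macro-averaged classification metrics (percent)
#'
#' Accuracy is the fraction of correct predictions,
#' `(TP + TN) / (TP + TN + FP + FN)` in the one-vs-rest view (identical
#' for every class of a two-class problem). Precision `TP / (TP + FP)`,
#' recall `TP / (TP + FN)` and F1
#' `2 * precision * recall / (precision + recall)` are computed per
#' class — a class with a zero denominator contributes 0 — and averaged
#' with equal class weight (macro averaging). All four are returned as
#' percentages.
#'
#' Macro averaging makes the degenerate constant predictor an exact
#' oracle: predicting only the majority class of an 18-sample test set
#' with 11 majority members gives accuracy 61.11, precision 30.56,
#' recall 50.00 and F1 37.93.
#'
#' @param counts A `confusion_counts` object (two classes).
#' @return Named numeric vector `c(accuracy, precision, recall, f1)` in
#'   percent.
#' @export
#' @examples
#' cc <- confusion(rep(c("a", "b"), c(11, 7)), rep("a", 18))
#' round(macro_metrics(cc), 2)
macro_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (!length(counts)) stop("empty confusion counts")
  per <- lapply(counts, function(k) {
    prec <- if (k$tp + k$fp > 0) k$tp / (k$tp + k$fp) else 0
    rec <- if (k$tp + k$fn > 0) k$tp / (k$tp + k$fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec = prec, rec = rec, f1 = f1)
  })
  k1 <- counts[[1]]
  n <- k1$tp + k1$fp + k1$tn + k1$fn
  if (n == 0) stop("empty test set")
  acc <- sum(vapply(counts, function(k) k$tp, 0)) / n
  m <- rowMeans(vapply(per, identity, c(prec = 0, rec = 0, f1 = 0)))
  100 * c(accuracy = acc, precision = unname(m["prec"]),
          recall = unname(m["rec"]), f1 = unname(m["f1"]))
}

#' Repeated stratified split evaluation of a classifier family
#'
#' Draws `n_splits` independent stratified train/test splits
#' (`1 - test_fraction` / `test_fraction`, 80/20 by default). Within
#' each split a [random_search()] tunes the family's hyperparameters on
#' the training portion (skipped for families without hyperparameters),
#' the best model is refit on the whole training portion, and
#' macro-averaged metrics are computed on the held-out portion. Results
#' are reported per split and as mean and standard deviation in percent.
#'
#' @param features Numeric matrix or data.frame, samples in rows.
#' @param labels Two-class labels, one per row.
#' @param family Classifier family (see [hyperparam_space()]).
#' @param n_splits Number of repeated splits (default 10).
#' @param test_fraction Held-out fraction per class (default 0.2).
#' @param seed Integer seed controlling splits, search and fits.
#' @param n_iter,inner_folds Passed to [random_search()].
#' @return An object of class `eeg_eval`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(c(rnorm(40), rnorm(40) + 4), ncol = 2)
#' y <- rep(c("control", "alcoholic"), each = 20)
#' evaluate(x, y, "nb", n_splits = 3, seed = 1)
evaluate <- function(features, labels, family, n_splits = 10,
                     test_fraction = 0.2, seed = NULL,
                     n_iter = 20, inner_folds = 10) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("evaluation requires exactly two classes")
  if (any(table(y) < 2)) stop("each class needs at least 2 samples")
  if (is.null(seed)) seed <- 0
  has_params <- length(hyperparam_space(family)) > 0
  split_rows <- vector("list", n_splits)
  chosen <- vector("list", n_splits)
  metrics <- matrix(NA_real_, n_splits, 4,
                    dimnames = list(NULL, c("accuracy", "precision",
                                            "recall", "f1")))
  for (s in seq_len(n_splits)) {
    split_seed <- (seed + 104729 * s) %% .Machine$integer.max
    with_seed(split_seed, {
      test_idx <- unlist(lapply(levels(y), function(cl) {
        idx <- which(y == cl)
        n_test <- max(1, round(length(idx) * test_fraction))
        sample(idx, n_test)
      }))
      tr_x <- x[-test_idx, , drop = FALSE]
      tr_y <- y[-test_idx]
      te_x <- x[test_idx, , drop = FALSE]
      te_y <- y[test_idx]
      params <- if (has_params)
        random_search(family, tr_x, tr_y, n_iter = n_iter,
                      inner_folds = inner_folds,
                      seed = (split_seed + 1) %% .Machine$integer.max)$params
      else list()
      model <- fit_model(family, params, tr_x, tr_y)
      pred <- predict_model(model, te_x)
      cc <- confusion(te_y, pred, classes = levels(y))
      metrics[s, ] <- macro_metrics(cc)
      chosen[[s]] <- params
      split_rows[[s]] <- test_idx
    })
  }
  structure(list(family = family,
                 per_split = data.frame(split = seq_len(n_splits), metrics),
                 mean = colMeans(metrics),
                 sd = apply(metrics, 2, stats::sd),
                 chosen_params = chosen,
                 test_indices = split_rows,
                 n_splits = n_splits,
                 test_fraction = test_fraction,
                 seed = seed),
            class = "eeg_eval")
}

#' @export
print.eeg_eval <- function(x, digits = 2, ...) {
  cat(sprintf("<eeg_eval> family %s, %d stratified %d/%d splits\n",
              x$family, x$n_splits,
              round(100 * (1 - x$test_fraction)),
              round(100 * x$test_fraction)))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %6.2f +/- %.2f %%\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' @export
summary.eeg_eval <- function(object, ...) {
  out <- data.frame(metric = names(object$mean),
                    mean = unname(object$mean),
                    sd = unname(object$sd))
  attr(out, "family") <- object$family
  out
}
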