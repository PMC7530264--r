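#' Printed hyperparameter search spaces
#'
#' The per-family hyperparameter domains explored by [random_search()]:
#' \describe{
#'   \item{knn}{neighbors k among the odd values 3..15.}
#'   \item{mlp}{hidden-layer size 2..1000, sampled log-uniformly.}
#'   \item{svm}{kernel in \{linear, poly, rbf\}; cost C = 2^e with
#'     integer e in -5..15; gamma = 2^e with e in -15..3 (rbf);
#'     polynomial degree among the odd values 3..9. The fixed-kernel
#'     families `svm_linear`, `svm_poly`, `svm_rbf` restrict the kernel.}
#'   \item{rf}{split criterion in \{gini, entropy\};
#'     min_samples_split 2..6; min_samples_leaf 1..6; 3000 trees
#'     (fixed). Both criterion values run the Gini-impurity backend
#'     (no installed forest implementation offers entropy splitting);
#'     the sampled value is recorded with the chosen parameters.}
#'   \item{nb}{no hyperparameters (Gaussian naive Bayes).}
#' }
#'
#' @param family One of `"nb"`, `"knn"`, `"mlp"`, `"rf"`, `"svm"`,
#'   `"svm_linear"`, `"svm_poly"`, `"svm_rbf"`.
#' @return A named list of parameter domains (class `hyperparam_space`).
#' @export
#' @examples
#' hyperparam_space("knn")
hyperparam_space <- function(family = c("nb", "knn", "mlp", "rf", "svm",
                                        "svm_linear", "svm_poly",
                                        "svm_rbf")) {
  family <- match.arg(family)
  base_svm <- list(kernel = c("linear", "poly", "rbf"),
                   C_exp = -5:15, gamma_exp = -15:3,
                   degree = seq(3, 9, by = 2))
  space <- switch(family,
    nb = list(),
    knn = list(k = seq(3, 15, by = 2)),
    mlp = list(size_range = c(2, 1000)),
    rf = list(criterion = c("gini", "entropy"),
              min_samples_split = 2:6,
              min_samples_leaf = 1:6,
              n_estimators = 3000),
    svm = base_svm,
    svm_linear = modifyList(base_svm, list(kernel = "linear")),
    svm_poly = modifyList(base_svm, list(kernel = "poly")),
    svm_rbf = modifyList(base_svm, list(kernel = "rbf")))
  structure(space, family = family, class = "hyperparam_space")
}

# One random draw from a hyperparameter space (uses the current RNG).
sample_params <- function(space) {
  family <- attr(space, "family")
  switch(family,
    nb = list(),
    knn = list(k = space$k[sample.int(length(space$k), 1)]),
    mlp = {
      lo <- log(space$size_range[1]); hi <- log(space$size_range[2])
      list(size = round(exp(stats::runif(1, lo, hi))))
    },
    rf = list(
      criterion = space$criterion[sample.int(length(space$criterion), 1)],
      min_samples_split =
        space$min_samples_split[sample.int(length(space$min_samples_split), 1)],
      min_samples_leaf =
        space$min_samples_leaf[sample.int(length(space$min_samples_leaf), 1)],
      n_estimators = space$n_estimators),
    { # svm variants
      kernel <- space$kernel[sample.int(length(space$kernel), 1)]
      list(kernel = kernel,
           C = 2^space$C_exp[sample.int(length(space$C_exp), 1)],
           gamma = 2^space$gamma_exp[sample.int(length(space$gamma_exp), 1)],
           degree = space$degree[sample.int(length(space$degree), 1)])
    })
}

feature_standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(x, st) {
  scale(x, center = st$center, scale = st$scale)[, , drop = FALSE]
}

needs_scaling <- function(family) {
  family %in% c("knn", "mlp", "svm", "svm_linear", "svm_poly", "svm_rbf")
}

# Fit one classifier; x is a numeric matrix, y a 2-level factor.
# Returns a fitted-model wrapper consumed by predict_model().
fit_model <- function(family, params, x, y) {
  y <- droplevels(as.factor(y))
  st <- NULL
  if (needs_scaling(family)) {
    st <- feature_standardizer(x)
    x <- apply_standardizer(x, st)
  }
  fit <- switch(family,
    nb = e1071::naiveBayes(x, y),
    knn = list(train_x = x, train_y = y, k = params$k),
    mlp = nnet::nnet(x, nnet::class.ind(y), size = params$size,
                     softmax = TRUE, maxit = 200, trace = FALSE,
                     MaxNWts = 1e6),
    rf = ranger::ranger(
      x = as.data.frame(x), y = y,
      num.trees = params$n_estimators,
      min.node.size = max(params$min_samples_leaf,
                          ceiling(params$min_samples_split / 2)),
      splitrule = "gini",
      num.threads = 1,
      seed = sample.int(.Machine$integer.max, 1)),
    { # svm variants
      e1071::svm(x, y,
                 kernel = switch(params$kernel, linear = "linear",
                                 poly = "polynomial", rbf = "radial"),
                 cost = params$C, gamma = params$gamma,
                 degree = params$degree, scale = FALSE)
    })
  structure(list(family = family, params = params, fit = fit,
                 standardizer = st, levels = levels(y)),
            class = "eeg_classifier")
}

# Predict class labels for new rows.
predict_model <- function(model, newx) {
  stopifnot(inherits(model, "eeg_classifier"))
  if (!is.null(model$standardizer))
    newx <- apply_standardizer(newx, model$standardizer)
  out <- switch(model$family,
    nb = as.character(predict(model$fit, newx)),
    knn = as.character(class::knn(model$fit$train_x, newx,
                                  model$fit$train_y, k = model$fit$k)),
    mlp = {
      pr <- predict(model$fit, newx)
      model$levels[max.col(pr, ties.method = "first")]
    },
    rf = as.character(predict(model$fit, data = as.data.frame(newx),
                              num.threads = 1)$predictions),
    as.character(predict(model$fit, newx)))
  factor(out, levels = model$levels)
}

# Stratified fold assignment: within each class, cycle fold ids over a
# random permutation.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Random hyperparameter search with inner cross-validation
#'
#' Draws `n_iter` candidates from the family's [hyperparam_space()],
#' scores each by mean accuracy over a stratified `inner_folds`-fold
#' cross-validation of the supplied data, and returns the best candidate
#' (ties: first drawn). Families with no hyperparameters (naive Bayes)
#' return their single candidate immediately. Deterministic for a fixed
#' seed.
#'
#' @param family Classifier family (see [hyperparam_space()]).
#' @param features Numeric matrix, samples in rows.
#' @param labels Class labels (coerced to a 2-level factor).
#' @param n_iter Number of candidates (default 20).
#' @param inner_folds Cross-validation folds (default 10); every class
#'   needs at least this many samples.
#' @param seed Integer seed.
#' @return List with `params` (the chosen hyperparameters), `score`
#'   (its mean CV accuracy) and `candidates` (all draws with scores).
#' @export
random_search <- function(family, features, labels, n_iter = 20,
                          inner_folds = 10, seed = NULL) {
  y <- droplevels(as.factor(labels))
  x <- as.matrix(features)
  space <- hyperparam_space(family)
  if (!length(space))
    return(list(params = list(), score = NA_real_, candidates = list()))
  if (any(table(y) < inner_folds))
    stop(sprintf("need >= %d samples per class for %d-fold search",
                 inner_folds, inner_folds))
  with_seed(seed, {
    folds <- stratified_folds(y, inner_folds)
    cand <- vector("list", n_iter)
    scores <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      params <- sample_params(space)
      acc <- vapply(seq_len(inner_folds), function(f) {
        tr <- folds != f
        model <- fit_model(family, params, x[tr, , drop = FALSE], y[tr])
        pred <- predict_model(model, x[!tr, , drop = FALSE])
        mean(as.character(pred) == as.character(y[!tr]))
      }, 0)
      cand[[it]] <- params
      scores[it] <- mean(acc)
    }
    best <- which.max(scores)   # first maximum on ties
    list(params = cand[[best]], score = scores[best],
         candidates = Map(function(p, s) list(params = p, score = s),
                          cand, scores))
  })
}
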