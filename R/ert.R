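#' Configuration of the extremely-randomized-trees regressor
#'
#' Defaults pin the tuned values of the original analysis: 100 trees,
#' max_features = 0.5 (fraction of features drawn as split candidates per
#' node), min_samples_split = 100, assessed by 10-fold cross-validation.
#'
#' @param n_trees ensemble size
#' @param max_features fraction of features considered per split (0, 1]
#' @param min_samples_split minimum node size eligible for splitting
#' @param cv_folds folds for cross-validated performance
#' @param seed integer seed; fits are bit-reproducible given it
#' @return list of class `ert_config`
#' @export
ert_config <- function(n_trees = 100, max_features = 0.5,
                       min_samples_split = 100, cv_folds = 10, seed = 1) {
  stopifnot(n_trees >= 1, max_features > 0, max_features <= 1,
            min_samples_split >= 2, cv_folds >= 2)
  structure(as.list(environment()), class = "ert_config")
}

# Row-major sparse slots (CSR): the CSC representation of t(X).
as_csr <- function(X) {
  Tt <- methods::as(Matrix::t(X), "CsparseMatrix")
  list(p = Tt@p, i = Tt@i, x = Tt@x, n = nrow(X), pfeat = ncol(X))
}

ert_fit_raw <- function(X, y, config, seed) {
  Xc <- methods::as(X, "CsparseMatrix")
  cs <- as_csr(Xc)
  ert_fit_cpp(cs$p, cs$i, cs$x, Xc@p, Xc@i, Xc@x, cs$n, cs$pfeat,
              as.numeric(y),
              config$n_trees, config$max_features, config$min_samples_split,
              as.integer(seed))
}

#' Predict half-lives from a fitted ERT ensemble
#' @param model a fitted model from [train_ert()] (or its `$model` element)
#' @param X sparse feature matrix with the training column universe
#' @return numeric predictions
#' @export
ert_predict <- function(model, X) {
  if (!is.null(model$model)) model <- model$model
  cs <- if (is.list(X)) X else as_csr(X)
  ert_predict_cpp(model$trees, cs$p, cs$i, cs$x, cs$n)
}

#' Train the extremely-randomized-trees half-life model
#'
#' Ensemble of regression trees with uniformly random split thresholds: at
#' each node a random `max_features` fraction of columns is drawn, one random
#' threshold per candidate is scored by variance reduction, and the best
#' candidate splits the node. Performance is the Spearman rank correlation
#' between pooled out-of-fold predictions and the observed half-lives under
#' `cv_folds`-fold cross-validation, followed by a final fit on all genes.
#'
#' @param X sparse gene x feature matrix (e.g. from [count_kmers()])
#' @param y half-lives in minutes (decay-class genes only); must be finite
#' @param config an [ert_config()]
#' @return list of class `ert_model`: `model` (trees + raw importance),
#'   `cv` (spearman, predictions, fold assignment), `config`, `feature_ids`
#' @export
train_ert <- function(X, y, config = ert_config()) {
  if (any(!is.finite(y))) stop("targets must be finite half-lives")
  n <- nrow(X)
  if (n < 2 * config$cv_folds)
    stop("need at least 2 genes per cross-validation fold")
  set.seed(config$seed)
  folds <- sample(rep(seq_len(config$cv_folds), length.out = n))
  preds <- numeric(n)
  for (f in seq_len(config$cv_folds)) {
    hold <- folds == f
    fit <- ert_fit_raw(X[!hold, , drop = FALSE], y[!hold], config,
                       seed = config$seed + f)
    preds[hold] <- ert_predict(fit, X[hold, , drop = FALSE])
  }
  cv_spearman <- stats::cor(preds, y, method = "spearman")
  model <- ert_fit_raw(X, y, config, seed = config$seed)
  structure(list(model = model,
                 cv = list(spearman = cv_spearman, predictions = preds,
                           folds = folds),
                 config = config,
                 feature_ids = colnames(X)),
            class = "ert_model")
}

#' @export
print.ert_model <- function(x, ...) {
  cat(sprintf("ert_model: %d trees, max_features %.2f, min_samples_split %d\n",
              x$config$n_trees, x$config$max_features,
              x$config$min_samples_split))
  cat(sprintf("  %d-fold CV Spearman = %.3f\n", x$config$cv_folds,
              x$cv$spearman))
  invisible(x)
}

#' Impurity-based feature importances with stability direction
#'
#' Mean decrease in impurity (variance, for regression) per feature, averaged
#' over trees and normalized to sum 1 over the reported features. The
#' direction compares the mean half-life of genes containing the motif
#' (count > 0) against genes lacking it: higher with the motif =
#' "stabilizing", lower = "destabilizing".
#'
#' @param model an `ert_model` from [train_ert()]
#' @param X the training feature matrix
#' @param y the training half-lives
#' @param top_n report at most this many features (by importance); Inf for
#'   all features with nonzero importance
#' @return data.frame: feature, importance (sums to 1 over all nonzero
#'   features, before the `top_n` cut), rank, direction
#' @export
feature_importances <- function(model, X, y, top_n = Inf) {
  imp <- model$model$importance
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  nz <- which(imp > 0)
  nz <- nz[order(imp[nz], decreasing = TRUE)]
  if (is.finite(top_n)) nz <- utils::head(nz, top_n)
  direction <- vapply(nz, function(j) {
    present <- X[, j] > 0
    if (all(present) || !any(present)) return(NA_character_)
    if (mean(y[present]) > mean(y[!present])) "stabilizing" else "destabilizing"
  }, character(1))
  data.frame(feature = colnames(X)[nz],
             importance = imp[nz],
             rank = seq_along(nz),
             direction = direction,
             stringsAsFactors = FALSE)
}

#' Gini impurity of a set of class fractions
#'
#' `sum_i f_i * (1 - f_i)` over class fractions that sum to 1 — the impurity
#' used for classification trees (regression trees use variance instead).
#'
#' @param class_fractions non-negative fractions summing to 1
#' @return the Gini index
#' @export
gini_index <- function(class_fractions) {
  if (any(class_fractions < 0))
    stop("class fractions must be non-negative")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class fractions must sum to 1")
  sum(class_fractions * (1 - class_fractions))
}
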