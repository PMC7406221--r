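#' Prepare a biophysical feature table for linear modeling
#'
#' Encoding rules: numeric columns are min-max scaled to [0, 1] (constant
#' columns become 0 with a warning), logical/binary columns become {0, 1},
#' and categorical columns are one-hot expanded (one binary column per
#' level). Typical inputs are transcript length, GC fractions, expression
#' level, operon position, distance from the transcription start site,
#' terminator type, UTR lengths, start codon identity, and externally
#' computed columns such as minimum folding energy or RBS strength.
#'
#' @param columns data.frame of per-gene features (rownames or a `gene_id`
#'   column identify genes)
#' @param schema named character vector mapping each feature column to
#'   "numeric", "binary" or "categorical"
#' @return list of class `biophysical_features`: `matrix` (genes x encoded
#'   columns, all values in [0, 1]), `schema`, `scaling` (per-numeric min and
#'   range)
#' @export
prepare_biophysical <- function(columns, schema) {
  gene_id <- if ("gene_id" %in% names(columns)) columns$gene_id
             else rownames(columns)
  feats <- columns[, names(schema), drop = FALSE]
  blocks <- list()
  scaling <- list()
  for (nm in names(schema)) {
    v <- feats[[nm]]
    type <- schema[[nm]]
    if (type == "numeric") {
      v <- as.numeric(v)
      rng <- range(v, finite = TRUE)
      if (diff(rng) == 0) {
        warning(sprintf("constant numeric column '%s' scaled to 0", nm))
        scaled <- rep(0, length(v))
      } else scaled <- (v - rng[1]) / diff(rng)
      scaling[[nm]] <- c(min = rng[1], range = diff(rng))
      blocks[[nm]] <- matrix(scaled, ncol = 1, dimnames = list(NULL, nm))
    } else if (type == "binary") {
      blocks[[nm]] <- matrix(as.numeric(as.logical(v)), ncol = 1,
                             dimnames = list(NULL, nm))
    } else if (type == "categorical") {
      f <- factor(v)
      oh <- stats::model.matrix(~ f - 1)
      colnames(oh) <- paste0(nm, "_", levels(f))
      blocks[[nm]] <- oh
    } else stop(sprintf("unknown schema type '%s' for column '%s'", type, nm))
  }
  m <- do.call(cbind, blocks)
  rownames(m) <- gene_id
  structure(list(matrix = m, schema = schema, scaling = scaling),
            class = "biophysical_features")
}

#' Linear-kernel support-vector regression on biophysical features
#'
#' Fits an epsilon-SVR with a linear kernel (defaults C = 1, epsilon = 0.1)
#' and ranks features by the absolute value of the primal coefficients
#' w = sum(alpha_i * x_i), the standard relative-importance reading of a
#' linear SVR. The fit report gives the Pearson correlation between fitted
#' and observed half-lives and the RMSE in minutes.
#'
#' @param features a `biophysical_features` object (or a plain numeric
#'   matrix already scaled to [0, 1])
#' @param target half-lives in minutes
#' @param cost,epsilon SVR hyperparameters
#' @return list of class `svr_model`: `coefficients` (data.frame feature,
#'   coefficient, rank by |coefficient|), `fit_report` (pearson_r, rmse_min),
#'   `model` (the underlying e1071 fit), `intercept`
#' @export
train_svr_linear <- function(features, target, cost = 1, epsilon = 0.1) {
  X <- if (inherits(features, "biophysical_features")) features$matrix
       else as.matrix(features)
  if (nrow(X) < 2) stop("need at least 2 genes to fit")
  if (length(target) != nrow(X)) stop("target length must match rows")
  constant <- apply(X, 2, function(col) diff(range(col)) == 0)
  w <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (all(constant)) {
    preds <- rep(mean(target), nrow(X))
    intercept <- mean(target)
  } else {
    fit <- e1071::svm(X[, !constant, drop = FALSE], target,
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    w[!constant] <- drop(crossprod(fit$coefs, fit$SV))
    intercept <- -fit$rho
    preds <- as.numeric(stats::predict(fit, X[, !constant, drop = FALSE]))
  }
  rmse <- sqrt(mean((preds - target)^2))
  pearson <- if (stats::sd(preds) > 0) stats::cor(preds, target) else NA_real_
  coefs <- data.frame(feature = names(w), coefficient = unname(w),
                      stringsAsFactors = FALSE)
  coefs <- coefs[order(abs(coefs$coefficient), decreasing = TRUE), ]
  coefs$rank <- seq_len(nrow(coefs))
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs,
                 fit_report = list(pearson_r = pearson, rmse_min = rmse),
                 intercept = intercept,
                 model = if (all(constant)) NULL else fit),
            class = "svr_model")
}
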