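# Welch t test that tolerates (near-)constant groups: identical means give
# p = 1, separated constant groups give p ~ 0.
welch_p <- function(x, y) {
  tryCatch(stats::t.test(x, y)$p.value,
           error = function(e)
             if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
}

#' Pairwise group comparisons with Bonferroni adjustment
#'
#' Welch two-sample t tests on a per-gene metric (half-life or expression)
#' between every pair of groups passing the size filter; raw p-values are
#' multiplied by the number of pairs and capped at 1. Groups at or below
#' `min_group_size` members are excluded, mirroring the "more than 50 genes"
#' filter of the functional-category comparisons.
#'
#' @param values per-gene metric
#' @param groups matching group labels
#' @param min_group_size exclusive lower bound on group size (default 50)
#' @return list of class `group_comparison`: `groups` (label, n, median),
#'   `pairwise` (symmetric matrix of adjusted p-values), `n_pairs`
#' @export
group_tests <- function(values, groups, min_group_size = 50) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups) & nzchar(as.character(groups))
  split_v <- split(values[keep], as.character(groups[keep]))
  split_v <- split_v[vapply(split_v, length, integer(1)) > min_group_size]
  if (length(split_v) < 2)
    stop("need >= 2 groups above the size filter")
  labs <- names(split_v)
  p <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  n_pairs <- choose(length(labs), 2)
  for (i in seq_along(labs)) for (j in seq_len(i - 1)) {
    adj <- min(1, welch_p(split_v[[i]], split_v[[j]]) * n_pairs)
    p[i, j] <- p[j, i] <- adj
  }
  structure(list(
    groups = data.frame(label = labs,
                        n = vapply(split_v, length, integer(1)),
                        median = vapply(split_v, stats::median, numeric(1)),
                        stringsAsFactors = FALSE),
    pairwise = p,
    n_pairs = n_pairs), class = "group_comparison")
}

#' Pearson correlation between two per-gene variables
#'
#' @param x,y numeric vectors
#' @param subset optional logical/index mask of genes to use
#' @param log10_x,log10_y log10-transform before correlating (expression is
#'   conventionally correlated on the log scale)
#' @return list of class `correlation_report`: r, n, subset_label
#' @param subset_label free-text label stored in the report
#' @export
correlate <- function(x, y, subset = NULL, log10_x = FALSE, log10_y = FALSE,
                      subset_label = "all") {
  if (!is.null(subset)) { x <- x[subset]; y <- y[subset] }
  if (log10_x) x <- log10(x)
  if (log10_y) y <- log10(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  structure(list(r = stats::cor(x, y), n = length(x),
                 subset_label = subset_label),
            class = "correlation_report")
}

#' Bootstrap group medians at a common resample size
#'
#' Resamples each group (with replacement) `iters` times at size
#' `resample_n` and reports the mean of the resample medians with a 2.5/97.5
#' percentile interval — the device used to compare group medians across
#' very different group sizes.
#'
#' @param values per-gene metric
#' @param groups matching labels
#' @param resample_n per-group resample size; default is the smallest group
#' @param iters bootstrap iterations
#' @param seed RNG seed
#' @return data.frame: group, n, median, boot_median (mean of resample
#'   medians), lower, upper
#' @export
bootstrap_medians <- function(values, groups, resample_n = NULL,
                              iters = 1000, seed = 1) {
  keep <- is.finite(values)
  split_v <- split(values[keep], as.character(groups[keep]))
  empty <- names(split_v)[vapply(split_v, length, integer(1)) == 0]
  if (length(empty)) {
    warning(sprintf("empty group(s) excluded: %s", paste(empty, collapse = ", ")))
    split_v <- split_v[!names(split_v) %in% empty]
  }
  if (is.null(resample_n))
    resample_n <- min(vapply(split_v, length, integer(1)))
  set.seed(seed)
  rows <- lapply(names(split_v), function(g) {
    v <- split_v[[g]]
    meds <- vapply(seq_len(iters), function(i)
      stats::median(sample(v, resample_n, replace = TRUE)), numeric(1))
    data.frame(group = g, n = length(v), median = stats::median(v),
               boot_median = mean(meds),
               lower = stats::quantile(meds, 0.025, names = FALSE),
               upper = stats::quantile(meds, 0.975, names = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Half-life trend along operons
#'
#' Least-squares slope of half-life against position within each operon with
#' at least 3 decay-class members, pooled across operons by a sign test
#' (binomial test of positive slopes against one half). A positive pooled
#' trend is the run-off signature of residual transcription: promoter-distal
#' genes keep being transcribed for longer after rifampin blocks initiation.
#'
#' @param fits half-life table (gene_id, class, t_half)
#' @param annotation annotation data.frame with operon_id and operon_index
#' @return list of class `operon_trend`: `per_operon` (data.frame operon_id,
#'   n, slope), `n_positive`, `n_operons`, `sign_test_p` (one-sided, positive
#'   direction)
#' @export
operon_trend <- function(fits, annotation) {
  dec <- fits[fits$class == "decay" & is.finite(fits$t_half), , drop = FALSE]
  idx <- match(dec$gene_id, annotation$gene_id)
  dec$operon_id <- annotation$operon_id[idx]
  dec$operon_index <- annotation$operon_index[idx]
  dec <- dec[!is.na(dec$operon_index) & nzchar(dec$operon_id), , drop = FALSE]
  rows <- lapply(split(dec, dec$operon_id), function(d) {
    if (nrow(d) < 3 || length(unique(d$operon_index)) < 2) return(NULL)
    slope <- unname(stats::coef(stats::lm(t_half ~ operon_index, data = d))[2])
    data.frame(operon_id = d$operon_id[1], n = nrow(d), slope = slope,
               stringsAsFactors = FALSE)
  })
  per_operon <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_operon) || nrow(per_operon) == 0)
    stop("no operon with >= 3 decay-class members")
  n_pos <- sum(per_operon$slope > 0)
  p <- stats::binom.test(n_pos, nrow(per_operon), p = 0.5,
                         alternative = "greater")$p.value
  structure(list(per_operon = per_operon, n_positive = n_pos,
                 n_operons = nrow(per_operon), sign_test_p = p),
            class = "operon_trend")
}
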