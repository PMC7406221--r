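#' Fit first-order exponential decay over a time-point prefix
#'
#' Least-squares fit of log abundance against time over all replicate points
#' at the first `prefix_timepoints` times of the grid. The decay constant is
#' the negated slope, `t_half = ln(2) / k`, and R-squared is taken from the
#' log-space fit. Non-positive abundances (late points of fast decayers whose
#' counts hit zero) are floored at the pseudocount before taking logs so the
#' fit stays defined; positive abundances are never altered.
#'
#' @param times numeric vector, minutes after rifampin (replicate points may
#'   repeat the same time)
#' @param abundances matched non-negative abundances
#' @param prefix_timepoints how many grid times (from t = 0) to include
#' @param grid the time grid; defaults to the sorted unique `times`
#' @param pseudocount floor applied to non-positive abundances (normalized
#'   units, default 0.5)
#' @return list: k (per minute), t_half (minutes, +Inf when k <= 0), r2,
#'   n_timepoints_used, n_points, no_signal (TRUE when every abundance is 0,
#'   in which case no fit is attempted)
#' @export
fit_exponential <- function(times, abundances, prefix_timepoints,
                            grid = sort(unique(times)), pseudocount = 0.5) {
  stopifnot(length(times) == length(abundances), all(abundances >= 0))
  use_times <- grid[seq_len(prefix_timepoints)]
  keep <- times %in% use_times
  t <- times[keep]
  a <- abundances[keep]
  if (length(unique(t)) < 3)
    stop("need >= 3 distinct time values in the fitted prefix")
  if (all(a <= 0))
    return(list(k = NA_real_, t_half = NA_real_, r2 = NA_real_,
                n_timepoints_used = prefix_timepoints, n_points = length(t),
                no_signal = TRUE))
  y <- log(ifelse(a <= 0, pseudocount, a))
  mt <- mean(t); my <- mean(y)
  sxx <- sum((t - mt)^2)
  slope <- sum((t - mt) * (y - my)) / sxx
  fitted <- my + slope * (t - mt)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  k <- -slope   # natural-log slope; k in min^-1, t_half = ln2/k
  list(k = k,
       t_half = if (k > 0) log(2) / k else Inf,
       r2 = r2,
       n_timepoints_used = prefix_timepoints,
       n_points = length(t),
       no_signal = FALSE)
}

#' Choose the time-point prefix with the best exponential fit
#'
#' Fits every candidate prefix (first 3, 4, 5, 6 or all 7 grid times by
#' default) and keeps the one with the highest R-squared; ties (within 1e-9)
#' go to the larger prefix, i.e. more data at equal fit quality. This guards
#' half-life estimates of fast decayers against late time points whose counts
#' have bottomed out.
#'
#' @inheritParams fit_exponential
#' @param prefixes candidate prefix lengths
#' @return list: prefix (chosen), fit (the winning [fit_exponential()]
#'   result), r2_by_prefix (named numeric)
#' @export
select_best_prefix <- function(times, abundances, prefixes = 3:7,
                               grid = sort(unique(times)), pseudocount = 0.5) {
  if (max(prefixes) > length(grid))
    stop("prefix exceeds the number of grid time points")
  fits <- lapply(prefixes, function(p)
    fit_exponential(times, abundances, p, grid, pseudocount))
  r2 <- vapply(fits, function(f) if (isTRUE(f$no_signal)) -Inf else f$r2,
               numeric(1))
  names(r2) <- as.character(prefixes)
  best <- max(r2)
  idx <- max(which(r2 >= best - 1e-9))   # tie -> larger prefix
  list(prefix = prefixes[idx], fit = fits[[idx]], r2_by_prefix = r2)
}

#' Classify one transcript and assemble its decay record
#'
#' Precedence of the four classes: (1) `no_reads` when total raw reads across
#' all samples fall below `min_total_reads`; (2) `stable` when the
#' replicate-mean normalized abundance at the final time point retains more
#' than `stable_fraction` of the t = 0 mean (no half-life is reported);
#' (3) `low_r2` when the best-prefix fit has R-squared below `min_r2`;
#' (4) `decay` otherwise, with the fitted values.
#'
#' @param gene_id gene identifier for the output row
#' @param raw_counts raw counts across samples (same order as `times`)
#' @param normalized matched normalized abundances
#' @param times minutes after rifampin per sample
#' @param min_total_reads raw-read floor below which no fit is attempted
#' @param min_r2 R-squared threshold separating decay from low_r2
#' @param stable_fraction retention fraction at the final time point that
#'   defines stability (default 0.5)
#' @inheritParams fit_exponential
#' @return one-row data.frame: gene_id, class, k, t_half, r2,
#'   n_timepoints_used, expression_level
#' @export
classify_transcript <- function(gene_id, raw_counts, normalized, times,
                                min_total_reads = 50, min_r2 = 0.5,
                                stable_fraction = 0.5,
                                grid = sort(unique(times)),
                                pseudocount = 0.5) {
  stopifnot(min_total_reads > 0, min_r2 > 0, stable_fraction > 0)
  t0 <- min(grid); tf <- max(grid)
  if (!any(times == t0) || !any(times == tf))
    stop("both the first and the final grid time must be present")
  expr <- mean(normalized[times == t0])
  row <- function(class, k = NA_real_, t_half = NA_real_, r2 = NA_real_,
                  n_used = NA_integer_) {
    data.frame(gene_id = gene_id, class = class, k = k, t_half = t_half,
               r2 = r2, n_timepoints_used = n_used, expression_level = expr,
               stringsAsFactors = FALSE)
  }
  if (sum(raw_counts) < min_total_reads) return(row("no_reads"))
  final <- mean(normalized[times == tf])
  if (expr > 0 && final > stable_fraction * expr) return(row("stable"))
  sel <- select_best_prefix(times, normalized, grid = grid,
                            prefixes = 3:length(grid),
                            pseudocount = pseudocount)
  f <- sel$fit
  if (isTRUE(f$no_signal)) return(row("no_reads"))
  if (f$r2 < min_r2)
    return(row("low_r2", k = f$k, t_half = NA_real_, r2 = f$r2,
               n_used = as.integer(f$n_timepoints_used)))
  row("decay", k = f$k, t_half = f$t_half, r2 = f$r2,
      n_used = as.integer(f$n_timepoints_used))
}

#' Fit and classify every gene of a normalized time course
#'
#' @param normalized genes x samples matrix from [normalize_counts()]
#' @param cm the raw [count_matrix()] (for the no_reads criterion)
#' @param min_total_reads,min_r2,stable_fraction,pseudocount see
#'   [classify_transcript()]
#' @return list of class `decay_fits`: `fits` (data.frame, one row per gene)
#'   and `summary` (per-class counts and fractions plus median/mean/sd of
#'   decay-class half-lives)
#' @export
fit_all <- function(normalized, cm, min_total_reads = 50, min_r2 = 0.5,
                    stable_fraction = 0.5, pseudocount = 0.5) {
  genes <- rownames(normalized)
  stopifnot(identical(colnames(normalized), colnames(cm$counts)))
  times <- cm$samples$time
  grid <- sort(unique(times))
  fits <- do.call(rbind, lapply(genes, function(g)
    classify_transcript(g, cm$counts[g, ], normalized[g, ], times,
                        min_total_reads = min_total_reads, min_r2 = min_r2,
                        stable_fraction = stable_fraction, grid = grid,
                        pseudocount = pseudocount)))
  classes <- c("decay", "stable", "low_r2", "no_reads")
  n_by <- vapply(classes, function(cl) sum(fits$class == cl), numeric(1))
  hl <- fits$t_half[fits$class == "decay" & is.finite(fits$t_half)]
  summary <- list(
    n = length(genes),
    class_counts = n_by,
    class_fractions = n_by / max(1, length(genes)),
    halflife_median = if (length(hl)) stats::median(hl) else NA_real_,
    halflife_mean = if (length(hl)) mean(hl) else NA_real_,
    halflife_sd = if (length(hl) > 1) stats::sd(hl) else NA_real_)
  structure(list(fits = fits, summary = summary), class = "decay_fits")
}

#' @export
print.decay_fits <- function(x, ...) {
  s <- x$summary
  cat(sprintf("decay_fits: %d genes\n", s$n))
  for (cl in names(s$class_counts))
    cat(sprintf("  %-8s %5d (%.1f%%)\n", cl, s$class_counts[[cl]],
                100 * s$class_fractions[[cl]]))
  cat(sprintf("  decay-class half-life: median %.3g, mean %.3g, sd %.3g min\n",
              s$halflife_median, s$halflife_mean, s$halflife_sd))
  invisible(x)
}
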