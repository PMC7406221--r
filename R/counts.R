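#' Construct a time-course count matrix
#'
#' The central container for a rifampin run-off experiment: a feature-by-sample
#' matrix of read counts together with per-sample metadata (replicate label and
#' minutes after rifampin addition) and the set of feature ids that are RNA
#' spike-ins rather than genes.
#'
#' @param counts numeric matrix, features in rows, samples in columns. Row and
#'   column names are required. Values must be non-negative; integer counts are
#'   expected for real data, but non-integral values are admitted so that
#'   noiseless simulated expectations can flow through the pipeline unchanged.
#' @param samples data.frame with columns `sample_id`, `replicate`, `time`
#'   (minutes after rifampin, >= 0), one row per column of `counts`.
#' @param spikein_ids character vector of row names that are spike-ins.
#'   Must be disjoint from gene ids.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, spikein_ids = character()) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must be a matrix with row (feature) and column (sample) names")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  required <- c("sample_id", "replicate", "time")
  if (!is.data.frame(samples) || !all(required %in% names(samples)))
    stop("`samples` must contain columns sample_id, replicate, time")
  if (!identical(as.character(samples$sample_id), colnames(counts)))
    stop("samples$sample_id must match colnames(counts) in order")
  if (any(samples$time < 0)) stop("time must be >= 0 minutes")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature id in counts")
  if (!all(spikein_ids %in% rownames(counts)))
    stop("spikein_ids absent from count rows")
  structure(
    list(counts = counts,
         samples = as.data.frame(samples, stringsAsFactors = FALSE),
         spikein_ids = as.character(spikein_ids)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features (%d spike-ins) x %d samples\n",
              nrow(x$counts), length(x$spikein_ids), ncol(x$counts)))
  cat(sprintf("  times (min): %s; replicates: %s\n",
              paste(sort(unique(x$samples$time)), collapse = ", "),
              paste(unique(x$samples$replicate), collapse = ", ")))
  invisible(x)
}

#' Gene ids of a count matrix (features that are not spike-ins)
#' @param x a `count_matrix`
#' @return character vector
#' @export
gene_ids <- function(x) setdiff(rownames(x$counts), x$spikein_ids)

#' Read per-sample HTSeq-style count files into one count matrix
#'
#' Each count file is a two-column tab-separated table (feature id, count)
#' as written by htseq-count; summary rows whose id starts with `__` are
#' dropped with a message. Samples are joined on feature id; features missing
#' from a sample are filled with 0 and reported.
#'
#' @param paths character vector of file paths, one per sample.
#' @param sample_sheet data.frame with columns `sample_id`, `replicate`,
#'   `time`, and optionally `path`; if `path` is absent, `paths` are matched
#'   positionally to rows.
#' @param spikein_ids feature ids to mark as spike-ins.
#' @param integer_counts when TRUE (default), non-integer counts are a format
#'   error, as expected for read-counting output; set FALSE for datasets
#'   written by the simulator in deterministic (dispersion = 0) mode, whose
#'   counts are exact expectations.
#' @return a [count_matrix()].
#' @export
read_counts <- function(paths, sample_sheet, spikein_ids = character(),
                        integer_counts = TRUE) {
  if ("path" %in% names(sample_sheet)) paths <- sample_sheet$path
  if (length(paths) != nrow(sample_sheet))
    stop("one count file per sample sheet row is required")
  tabs <- lapply(paths, function(p) {
    tab <- utils::read.table(p, sep = "\t", header = FALSE,
                             col.names = c("feature", "count"),
                             colClasses = c("character", "numeric"))
    special <- startsWith(tab$feature, "__")
    if (any(special)) {
      message(sprintf("read_counts: dropping %d special '__*' rows from %s",
                      sum(special), p))
      tab <- tab[!special, , drop = FALSE]
    }
    if (anyDuplicated(tab$feature))
      stop(sprintf("duplicate feature id in %s", p))
    if (any(tab$count < 0) ||
        (integer_counts && any(tab$count != round(tab$count))))
      stop(sprintf("negative or non-integer count in %s", p))
    tab
  })
  features <- sort(unique(unlist(lapply(tabs, `[[`, "feature"))))
  counts <- matrix(0, nrow = length(features), ncol = length(tabs),
                   dimnames = list(features, as.character(sample_sheet$sample_id)))
  for (i in seq_along(tabs)) {
    tab <- tabs[[i]]
    missing_n <- length(features) - nrow(tab)
    if (missing_n > 0)
      message(sprintf("read_counts: sample %s missing %d features, filled with 0",
                      sample_sheet$sample_id[i], missing_n))
    counts[tab$feature, i] <- tab$count
  }
  count_matrix(counts, sample_sheet[, c("sample_id", "replicate", "time")],
               intersect(spikein_ids, features))
}

#' Write a count matrix as per-sample HTSeq-style files
#'
#' @param cm a `count_matrix`
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths (named by sample id)
#' @export
write_counts <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(ncol(cm$counts)), function(i) {
    p <- file.path(dir, paste0(colnames(cm$counts)[i], ".counts.tsv"))
    utils::write.table(
      data.frame(feature = rownames(cm$counts),
                 count = format(cm$counts[, i], trim = TRUE, digits = 17,
                                scientific = FALSE)),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  names(paths) <- colnames(cm$counts)
  invisible(paths)
}

#' Restrict a count matrix to a feature subset
#' @param cm a `count_matrix`
#' @param features feature ids to keep
#' @return a `count_matrix`
#' @export
subset_features <- function(cm, features) {
  count_matrix(cm$counts[features, , drop = FALSE], cm$samples,
               intersect(cm$spikein_ids, features))
}
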