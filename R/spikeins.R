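#' Calibrate the spike-in dose response for one sample
#'
#' Ordinary least squares of log10(counts per kilobase) on
#' log10(copies per cell) across the included spike-ins, the log-log
#' calibration line whose linearity underwrites absolute normalization.
#' Spike-ins with zero counts cannot enter a log fit and are excluded with
#' reason "zero count"; ids in `exclude` are excluded with reason
#' "user-excluded". The highest-dose manifest member (1,000 copies/cell in the
#' default design) is conventionally excluded because it saturates the
#' response; pass it via `exclude`.
#'
#' @param cm a [count_matrix()] containing the spike-in rows
#' @param manifest spike-in manifest data.frame (id, length, copies_per_cell)
#' @param sample_id which sample to calibrate
#' @param exclude spike-in ids to leave out of the fit
#' @return list of class `spikein_fit`: slope, intercept, r2, included_ids,
#'   excluded_ids (named character vector, names = reasons), sample_id
#' @export
fit_spikein_curve <- function(cm, manifest, sample_id, exclude = character()) {
  validate_spikein_manifest(manifest)
  if (!sample_id %in% colnames(cm$counts)) stop("unknown sample_id")
  ids <- intersect(manifest$id, rownames(cm$counts))
  counts <- cm$counts[ids, sample_id]
  excluded <- character()
  user_ex <- intersect(ids, exclude)
  if (length(user_ex)) excluded[user_ex] <- "user-excluded"
  zero_ex <- setdiff(ids[counts <= 0], user_ex)
  if (length(zero_ex)) excluded[zero_ex] <- "zero count"
  included <- setdiff(ids, names(excluded))
  if (length(included) < 3)
    stop(sprintf("spike-in calibration for %s needs >= 3 usable spike-ins, have %d",
                 sample_id, length(included)))
  m <- manifest[match(included, manifest$id), ]
  x <- log10(m$copies_per_cell)
  y <- log10(counts[included] / m$length * 1000)   # counts per kilobase
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 included_ids = included,
                 excluded_ids = excluded,
                 sample_id = sample_id),
            class = "spikein_fit")
}

#' Quality control of per-sample spike-in calibrations
#'
#' Flags samples whose calibration R-squared falls below `min_r2`. The
#' default threshold sits just below the 0.971 minimum observed across the
#' original 21 libraries, so a well-behaved experiment passes untouched.
#'
#' @param fits list of `spikein_fit` objects, one per sample
#' @param min_r2 pass threshold (default 0.97)
#' @param strict when TRUE, any flagged sample is an error; otherwise a
#'   warning is raised and the report returned
#' @return data.frame (sample_id, r2, pass)
#' @export
qc_spikein_fits <- function(fits, min_r2 = 0.97, strict = FALSE) {
  report <- data.frame(
    sample_id = vapply(fits, `[[`, character(1), "sample_id"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    stringsAsFactors = FALSE)
  report$pass <- report$r2 >= min_r2
  if (any(!report$pass)) {
    msg <- sprintf("spike-in calibration below R2 = %g for: %s", min_r2,
                   paste(report$sample_id[!report$pass], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  report
}

#' Per-sample normalization factors from spike-in sums
#'
#' The spike-in read sum of each sample is scaled to that of a reference
#' sample: `factor(s) = spikein_sum(reference) / spikein_sum(s)`. Multiplying
#' a sample's counts by its factor makes spike-in sums constant throughout
#' the time course, undoing both library-size variation and the shrinking
#' mRNA pool. The default reference is the t = 0 sample of the first
#' replicate, giving a single scale for all samples (the reference's factor
#' is exactly 1).
#'
#' @param cm a [count_matrix()]
#' @param included_ids spike-in ids contributing to the sums (default: all
#'   spike-ins in `cm`)
#' @param reference reference sample id; default picks the first t = 0 sample
#' @return data.frame of class `normalization_factors`:
#'   sample_id, factor, spikein_sum
#' @export
compute_normalization_factors <- function(cm, included_ids = cm$spikein_ids,
                                          reference = NULL) {
  if (!length(included_ids)) stop("no spike-in ids to sum")
  sums <- colSums(cm$counts[included_ids, , drop = FALSE])
  zero <- names(sums)[sums <= 0]
  if (length(zero))
    stop(sprintf("zero spike-in sum in sample(s): %s",
                 paste(zero, collapse = ", ")))
  if (is.null(reference)) {
    at0 <- cm$samples$sample_id[cm$samples$time == 0]
    if (!length(at0)) stop("no t = 0 sample to use as reference")
    reference <- at0[1]
  }
  if (!reference %in% names(sums)) stop("reference sample not found")
  out <- data.frame(sample_id = names(sums),
                    factor = unname(sums[reference] / sums),
                    spikein_sum = unname(sums),
                    stringsAsFactors = FALSE)
  class(out) <- c("normalization_factors", "data.frame")
  out
}

#' Apply normalization factors to a count matrix
#'
#' Each sample's counts are multiplied by its factor; spike-in rows are
#' dropped from the returned abundance table (their post-normalization sums
#' are equal across samples by construction).
#'
#' @param cm a [count_matrix()]
#' @param factors data.frame from [compute_normalization_factors()]
#' @return numeric matrix of normalized abundances, genes x samples
#' @export
normalize_counts <- function(cm, factors) {
  missing <- setdiff(colnames(cm$counts), factors$sample_id)
  if (length(missing))
    stop(sprintf("samples without a normalization factor: %s",
                 paste(missing, collapse = ", ")))
  f <- factors$factor[match(colnames(cm$counts), factors$sample_id)]
  normalized <- sweep(cm$counts, 2, f, `*`)
  normalized[gene_ids(cm), , drop = FALSE]
}
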