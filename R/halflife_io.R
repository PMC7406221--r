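#' Write the per-transcript half-life table
#'
#' Tab-separated columns: gene_id, class, half_life_min (empty unless
#' class = "decay"), decay_rate_per_min, r2, n_timepoints_used,
#' expression_level. Numbers are written at full double precision so that
#' a write/read round trip is exact.
#'
#' @param fits data.frame of per-gene fits as produced by [fit_all()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_halflife_table <- function(fits, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(
    gene_id = fits$gene_id,
    class = fits$class,
    half_life_min = fmt(ifelse(fits$class == "decay", fits$t_half, NA)),
    decay_rate_per_min = fmt(fits$k),
    r2 = fmt(fits$r2),
    n_timepoints_used = ifelse(is.na(fits$n_timepoints_used), "",
                               fits$n_timepoints_used),
    expression_level = fmt(fits$expression_level),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a half-life table written by [write_halflife_table()]
#' @param path TSV path
#' @return data.frame with typed columns (empty fields become NA)
#' @export
read_halflife_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "character",
                                          "character", "character", "character",
                                          "character"),
                           stringsAsFactors = FALSE)
  num <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  data.frame(
    gene_id = tab$gene_id,
    class = tab$class,
    t_half = num(tab$half_life_min),
    k = num(tab$decay_rate_per_min),
    r2 = num(tab$r2),
    n_timepoints_used = suppressWarnings(
      as.integer(ifelse(nzchar(tab$n_timepoints_used),
                        tab$n_timepoints_used, NA))),
    expression_level = num(tab$expression_level),
    stringsAsFactors = FALSE)
}

#' Export MEME-ready FASTA sets of extreme-stability UTRs
#'
#' Writes two FASTA files of coding-strand UTR sequences: the `n` decay-class
#' genes with the longest half-lives (primary set) and the `n` with the
#' shortest (control set), mirroring the discriminative-mode motif search of
#' the 400 most versus 400 least stable transcripts.
#'
#' @param fits half-life table (data.frame with gene_id, class, t_half)
#' @param utrs data.frame from [extract_utrs()]
#' @param dir output directory
#' @param n set size (default 400)
#' @param region which UTR side to export: "3utr" (downstream, default) or
#'   "5utr" (upstream)
#' @return invisibly, named character vector of the two paths
#'   (`most_stable`, `least_stable`)
#' @export
export_meme_sets <- function(fits, utrs, dir, n = 400,
                             region = c("3utr", "5utr")) {
  region <- match.arg(region)
  col <- if (region == "3utr") "downstream" else "upstream"
  eligible <- fits[fits$class == "decay" & fits$gene_id %in% utrs$gene_id &
                     is.finite(fits$t_half), , drop = FALSE]
  seqs <- utrs[[col]][match(eligible$gene_id, utrs$gene_id)]
  keep <- nzchar(seqs)
  eligible <- eligible[keep, , drop = FALSE]
  seqs <- seqs[keep]
  if (nrow(eligible) < 2 * n)
    stop(sprintf("export_meme_sets: need >= %d eligible decay-class genes with %s sequence, have %d",
                 2 * n, region, nrow(eligible)))
  ord <- order(eligible$t_half, eligible$gene_id, decreasing = TRUE)
  top <- ord[seq_len(n)]
  bottom <- rev(ord)[seq_len(n)]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_set <- function(idx, name) {
    p <- file.path(dir, sprintf("%s_%s.fa", name, region))
    x <- Biostrings::DNAStringSet(seqs[idx])
    names(x) <- eligible$gene_id[idx]
    Biostrings::writeXStringSet(x, p)
    p
  }
  paths <- c(most_stable = write_set(top, "most_stable"),
             least_stable = write_set(bottom, "least_stable"))
  invisible(paths)
}
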