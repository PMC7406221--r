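#' Read genome annotation and sequence
#'
#' Imports gene records from a GFF3 file together with the genome FASTA.
#' GFF3 coordinates (1-based, inclusive) are converted at this boundary to the
#' internal convention used throughout the package: 0-based, half-open
#' `[start, end)`. Functional category and operon structure are read from the
#' attribute keys `category`, `operon_id` and `operon_index` when present.
#'
#' @param gff_path path to a GFF3 file with `gene` (or CDS) features carrying
#'   an `ID` (or `gene_id`) attribute.
#' @param fasta_path path to the genome FASTA; sequence ids must cover every
#'   seqid used in the GFF.
#' @param feature_types GFF types treated as genes.
#' @return list with elements `annotation` (data.frame: gene_id, seq_id,
#'   start, end, strand, category, operon_id, operon_index) and `genome`
#'   (a [Biostrings::DNAStringSet]).
#' @export
read_annotation <- function(gff_path, fasta_path,
                            feature_types = c("gene", "CDS")) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  meta <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else
    as.character(meta$gene_id)
  get_attr <- function(key, default) {
    if (key %in% names(meta)) {
      v <- as.character(meta[[key]])
      v[is.na(v)] <- default
      v
    } else rep(default, length(gr))
  }
  ann <- data.frame(
    gene_id = ids,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    category = get_attr("category", ""),
    operon_id = get_attr("operon_id", ""),
    operon_index = suppressWarnings(as.integer(get_attr("operon_index", NA))),
    stringsAsFactors = FALSE)
  validate_annotation(ann, genome)
  list(annotation = ann, genome = genome)
}

validate_annotation <- function(ann, genome = NULL) {
  if (anyDuplicated(ann$gene_id)) stop("gene_id must be unique")
  if (any(ann$start >= ann$end)) stop("gene start must precede end")
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene")
  bad_idx <- !is.na(ann$operon_index) & ann$operon_index < 1L
  if (any(bad_idx)) stop("operon_index must be >= 1 when present")
  if (!is.null(genome)) {
    missing <- setdiff(unique(ann$seq_id), names(genome))
    if (length(missing))
      stop(sprintf("annotation references contigs absent from FASTA: %s",
                   paste(missing, collapse = ", ")))
    len <- Biostrings::width(genome)[match(ann$seq_id, names(genome))]
    if (any(ann$end > len)) stop("gene extends beyond contig end")
  }
  invisible(ann)
}

#' Write an annotation data.frame as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to GFF3's
#' 1-based inclusive convention, so read/write is an exact round trip.
#'
#' @param ann annotation data.frame as returned by [read_annotation()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  attrs <- paste0("ID=", ann$gene_id)
  add <- function(attrs, key, val, keep) {
    ifelse(keep, paste0(attrs, ";", key, "=", val), attrs)
  }
  attrs <- add(attrs, "category", ann$category,
               !is.na(ann$category) & nzchar(ann$category))
  attrs <- add(attrs, "operon_id", ann$operon_id,
               !is.na(ann$operon_id) & nzchar(ann$operon_id))
  attrs <- add(attrs, "operon_index", ann$operon_index, !is.na(ann$operon_index))
  lines <- c("##gff-version 3",
             paste(ann$seq_id, "rifadecay", "gene",
                   ann$start + 1L, ann$end, ".", ann$strand, ".", attrs,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spike-in manifest
#'
#' Tab-separated columns: `id`, `length` (nt), `copies_per_cell`.
#'
#' @param path TSV path
#' @return data.frame with the three validated columns
#' @export
read_spikein_manifest <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  validate_spikein_manifest(m)
}

validate_spikein_manifest <- function(m) {
  if (!all(c("id", "length", "copies_per_cell") %in% names(m)))
    stop("manifest needs columns id, length, copies_per_cell")
  if (any(m$length <= 0) || any(m$copies_per_cell <= 0))
    stop("spike-in length and copies_per_cell must be positive")
  if (anyDuplicated(m$id)) stop("duplicate spike-in id")
  m
}

#' Default spike-in manifest
#'
#' Six in-vitro transcripts from bacteriophage phiX174 spanning 0.1 to 1,000
#' copies/cell: gene H at 0.1, gene D at 1, genes F and G at 10, fragment 290
#' at 100 and fragment 190 at 1,000 copies/cell. Lengths are the approximate
#' transcript lengths used for per-kilobase normalization.
#'
#' @return data.frame with columns id, length, copies_per_cell
#' @export
default_spikein_manifest <- function() {
  data.frame(
    id = c("spikein_geneH", "spikein_geneD", "spikein_geneF",
           "spikein_geneG", "spikein_frag290", "spikein_frag190"),
    length = c(984L, 456L, 1284L, 528L, 290L, 190L),
    copies_per_cell = c(0.1, 1, 10, 10, 100, 1000),
    stringsAsFactors = FALSE)
}
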