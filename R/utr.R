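#' Extract fixed UTR proxy windows for every gene
#'
#' The upstream window is the `up` nt immediately 5' of the start codon and
#' the downstream window the `down` nt immediately 3' of the stop codon, both
#' on the coding strand (minus-strand genes are reverse-complemented). The
#' defaults, 150 and 100 nt, are the standard proxies for bacterial 5' and 3'
#' UTRs. Windows are truncated at contig ends and flagged.
#'
#' @param annotation annotation data.frame (internal 0-based half-open)
#' @param genome DNAStringSet
#' @param up,down window sizes in nt
#' @return data.frame: gene_id, upstream, downstream, upstream_truncated,
#'   downstream_truncated
#' @export
extract_utrs <- function(annotation, genome, up = 150, down = 100) {
  validate_annotation(annotation, genome)
  n <- nrow(annotation)
  upstream <- downstream <- character(n)
  up_tr <- down_tr <- logical(n)
  for (i in seq_len(n)) {
    contig <- genome[[annotation$seq_id[i]]]
    clen <- length(contig)
    s0 <- annotation$start[i]; e0 <- annotation$end[i]
    if (annotation$strand[i] == "+") {
      ufrom <- max(0, s0 - up); uto <- s0
      dfrom <- e0; dto <- min(clen, e0 + down)
      useq <- if (uto > ufrom) as.character(Biostrings::subseq(contig, ufrom + 1, uto)) else ""
      dseq <- if (dto > dfrom) as.character(Biostrings::subseq(contig, dfrom + 1, dto)) else ""
      up_tr[i] <- (s0 - up) < 0
      down_tr[i] <- (e0 + down) > clen
    } else {
      ufrom <- e0; uto <- min(clen, e0 + up)
      dfrom <- max(0, s0 - down); dto <- s0
      useq <- if (uto > ufrom) as.character(Biostrings::reverseComplement(
        Biostrings::subseq(contig, ufrom + 1, uto))) else ""
      dseq <- if (dto > dfrom) as.character(Biostrings::reverseComplement(
        Biostrings::subseq(contig, dfrom + 1, dto))) else ""
      up_tr[i] <- (e0 + up) > clen
      down_tr[i] <- (s0 - down) < 0
    }
    upstream[i] <- useq
    downstream[i] <- dseq
  }
  data.frame(gene_id = annotation$gene_id,
             upstream = upstream, downstream = downstream,
             upstream_truncated = up_tr, downstream_truncated = down_tr,
             stringsAsFactors = FALSE)
}
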