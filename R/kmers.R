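#' The UTR k-mer feature universe
#'
#' Region-prefixed ids for all 3- to 8-mers over both UTR windows:
#' 2 x (4^3 + ... + 4^8) = 174,720 features, the "~200,000 motif features"
#' scale of the sequence model.
#'
#' @param kmin,kmax k-mer size range
#' @return character vector of feature ids, "5utr_<kmer>" then "3utr_<kmer>"
#' @export
kmer_feature_universe <- function(kmin = 3, kmax = 8) {
  mers <- unlist(lapply(kmin:kmax, function(k)
    Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)))
  c(paste0("5utr_", mers), paste0("3utr_", mers))
}

#' Count overlapping UTR k-mers into a sparse feature matrix
#'
#' Overlapping occurrence counts of every 3- to 8-mer in the upstream and
#' downstream windows, on the coding strand only. Windows containing N
#' contribute no counts for k-mers spanning the N. Counting is delegated to
#' [Biostrings::oligonucleotideFrequency()] in gene chunks and stored sparse;
#' the column universe is always complete (174,720 columns for the default
#' range), independent of which k-mers occur.
#'
#' @param utrs data.frame from [extract_utrs()]
#' @param kmin,kmax k-mer size range
#' @param chunk genes per counting chunk (memory knob)
#' @return a [Matrix::sparseMatrix()] (dgCMatrix), genes x features, with
#'   rownames = gene ids and colnames = the feature universe
#' @export
count_kmers <- function(utrs, kmin = 3, kmax = 8, chunk = 256) {
  universe <- kmer_feature_universe(kmin, kmax)
  n <- nrow(utrs)
  region_offset <- c(`5utr` = 0L, `3utr` = length(universe) %/% 2L)
  k_offsets <- cumsum(c(0, 4^(kmin:kmax)))[seq_len(kmax - kmin + 1)]
  names(k_offsets) <- as.character(kmin:kmax)

  ii <- list(); jj <- list(); xx <- list(); part <- 0
  for (region in c("5utr", "3utr")) {
    seqs <- if (region == "5utr") utrs$upstream else utrs$downstream
    seqs[!nzchar(seqs)] <- paste(rep("N", kmin - 1), collapse = "")
    for (lo in seq(1, n, by = chunk)) {
      hi <- min(n, lo + chunk - 1)
      ss <- Biostrings::DNAStringSet(seqs[lo:hi])
      for (k in kmin:kmax) {
        freq <- Biostrings::oligonucleotideFrequency(ss, width = k)
        nz <- which(freq > 0, arr.ind = TRUE)
        if (nrow(nz)) {
          part <- part + 1
          ii[[part]] <- lo - 1L + nz[, 1]
          jj[[part]] <- region_offset[region] + k_offsets[as.character(k)] +
            nz[, 2]
          xx[[part]] <- freq[nz]
        }
      }
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, length(universe)),
                       dimnames = list(utrs$gene_id, universe))
}
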