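# Independent reference implementations used to cross-check the package.
# These are deliberately written in a different style (naive loops, string
# operations) from the production code paths they validate.

# Brute-force hairpin enumeration: every (start, stem, loop) combination,
# pairing checked with substrings, energy summed directly from the shipped
# tables. Mirrors the scan contract, not its implementation.
oracle_find_hairpins <- function(seq, params = scan_params()) {
  em <- energy_model()
  pair_ok <- function(a, b) paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  rows <- list()
  for (start in seq_len(min(n, params$max_distance_from_orf))) {
    for (stem in params$stem_min:params$stem_max) {
      for (loop in params$loop_min:params$loop_max) {
        last <- start - 1 + 2 * stem + loop
        if (last > n) next
        left <- chars[start:(start + stem - 1)]
        right <- chars[(start + stem + loop):last]
        codes <- character(stem)
        mm <- 0
        for (j in seq_len(stem)) {
          a <- left[j]; b <- right[stem - j + 1]
          if (pair_ok(a, b)) codes[j] <- paste0(a, b) else { codes[j] <- ""; mm <- mm + 1 }
        }
        if (mm > params$max_mismatch) next
        dg <- unname(em$loop[as.character(loop)]) + params$mismatch_penalty * mm
        for (j in seq_len(stem - 1))
          if (nzchar(codes[j]) && nzchar(codes[j + 1]))
            dg <- dg + em$stack[codes[j], codes[j + 1]]
        if (dg <= params$dg_cutoff)
          rows[[length(rows) + 1]] <- data.frame(
            start = start, stem_len = stem, loop_len = loop,
            mismatches = mm, dg = dg)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), stem_len = integer(),
                      loop_len = integer(), mismatches = integer(),
                      dg = numeric()))
  do.call(rbind, rows)
}

# Naive overlapping substring counter for k-mer cross-checks.
oracle_count_kmer <- function(seq, kmer) {
  k <- nchar(kmer)
  n <- nchar(seq)
  if (n < k) return(0L)
  hits <- 0L
  for (i in seq_len(n - k + 1))
    if (substr(seq, i, i + k - 1) == kmer) hits <- hits + 1L
  hits
}

# Grid-search nonlinear least squares in linear space: the independent
# estimator used to sanity-bound the log-space fit on noisy curves.
oracle_nls_halflife <- function(times, abundances,
                                thalf_range = c(0.05, 20), n_grid = 600) {
  ks <- exp(seq(log(log(2) / thalf_range[2]), log(log(2) / thalf_range[1]),
                length.out = n_grid))
  sse <- vapply(ks, function(k) {
    e <- exp(-k * times)
    A <- sum(abundances * e) / sum(e * e)
    sum((abundances - A * e)^2)
  }, numeric(1))
  log(2) / ks[which.min(sse)]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Small helper shared by several files: one noiseless high-expression config.
noiseless_config <- function(n_genes = 20, seed = 11) {
  sim_config(n_genes = n_genes, dispersion = 0,
             expression_meanlog = log(500), expression_sdlog = 0.5,
             seed = seed)
}
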