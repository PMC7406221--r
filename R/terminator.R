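#' Intrinsic-terminator scan parameters
#'
#' Structural bounds and the free-energy cutoff of the hairpin scan:
#' stem 4-12 bp, loop 3-8 nt, at most 3 mismatched stem positions, hairpin
#' start at most 270 nt downstream of the ORF, and a species-specific
#' reporting cutoff of -11.618 kcal/mol. The U-tract rule that separates
#' L-shaped from I-shaped calls (at least `u_min` U's within `u_window` nt of
#' the stem, first U within `u_max_gap` nt) is configurable.
#'
#' @param stem_min,stem_max stem length bounds (bp)
#' @param loop_min,loop_max loop length bounds (nt)
#' @param max_mismatch maximum non-pairing stem positions
#' @param max_distance_from_orf furthest allowed hairpin start (nt downstream
#'   of the stop codon)
#' @param dg_cutoff maximum folding free energy (kcal/mol) for a reported
#'   hairpin
#' @param mismatch_penalty kcal/mol added per mismatched stem position
#' @param u_window,u_min,u_max_gap U-tract rule (see description)
#' @return list of class `scan_params`
#' @export
scan_params <- function(stem_min = 4, stem_max = 12, loop_min = 3,
                        loop_max = 8, max_mismatch = 3,
                        max_distance_from_orf = 270, dg_cutoff = -11.618,
                        mismatch_penalty = 1.0,
                        u_window = 8, u_min = 4, u_max_gap = 2) {
  stopifnot(stem_min <= stem_max, loop_min <= loop_max, max_mismatch >= 0,
            dg_cutoff < 0, loop_min >= 3)
  structure(as.list(environment()), class = "scan_params")
}

.energy_env <- new.env(parent = emptyenv())

#' The shipped nearest-neighbor energy model
#'
#' Loads (and caches) the versioned stacking and hairpin-loop tables bundled
#' with the package. Stacking values are Turner-style RNA free energies in
#' the DNA alphabet (T stands for U); G:T wobble counts as a (weak) pair.
#'
#' @return list: `stack` (6x6 matrix over pair codes AT, TA, CG, GC, GT, TG),
#'   `loop` (named vector of loop penalties by length), `version`
#' @export
energy_model <- function() {
  if (!is.null(.energy_env$model)) return(.energy_env$model)
  stack_tab <- utils::read.table(
    system.file("extdata", "nn_stacking_v1.tsv", package = "rifadecay"),
    sep = "\t", header = TRUE, comment.char = "#", stringsAsFactors = FALSE)
  pairs <- c("AT", "TA", "CG", "GC", "GT", "TG")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  stack[cbind(stack_tab$pair5, stack_tab$pair3)] <- stack_tab$dg
  loop_tab <- utils::read.table(
    system.file("extdata", "hairpin_loop_v1.tsv", package = "rifadecay"),
    sep = "\t", header = TRUE, comment.char = "#", stringsAsFactors = FALSE)
  loop <- stats::setNames(loop_tab$dg, loop_tab$loop_len)
  .energy_env$model <- list(stack = stack, loop = loop, version = "v1")
  .energy_env$model
}

pair_code_r <- function(a, b) {
  key <- paste0(a, b)
  match(key, c("AT", "TA", "CG", "GC", "GT", "TG"))  # NA = mismatch
}

#' Folding free energy of one hairpin
#'
#' Sum of nearest-neighbor stacking terms over consecutive paired stem
#' positions, plus the hairpin-loop initiation penalty for the loop length,
#' plus a flat penalty per mismatched (non-pairing) stem position. Arms are
#' given 5'->3' on the transcript; position j of the left arm is tested
#' against position (stem - j + 1) of the right arm.
#'
#' @param left_arm,right_arm equal-length stem arm sequences (5'->3')
#' @param loop_len loop length in nt (>= 3)
#' @param mismatch_penalty kcal/mol per mismatch
#' @return list: dg (kcal/mol), mismatches
#' @export
fold_energy <- function(left_arm, right_arm, loop_len, mismatch_penalty = 1.0) {
  if (loop_len < 3) stop("loop length must be >= 3 nt")
  la <- strsplit(toupper(left_arm), "")[[1]]
  ra <- strsplit(toupper(right_arm), "")[[1]]
  if (length(la) != length(ra)) stop("stem arms must have equal length")
  em <- energy_model()
  loop_pen <- em$loop[as.character(min(loop_len, max(as.integer(names(em$loop)))))]
  s <- length(la)
  if (s == 0) return(list(dg = unname(loop_pen), mismatches = 0L))
  codes <- vapply(seq_len(s), function(j) pair_code_r(la[j], ra[s - j + 1]),
                  integer(1))
  mm <- sum(is.na(codes))
  dg <- unname(loop_pen) + mismatch_penalty * mm
  for (j in seq_len(s - 1))
    if (!is.na(codes[j]) && !is.na(codes[j + 1]))
      dg <- dg + em$stack[codes[j], codes[j + 1]]
  list(dg = dg, mismatches = as.integer(mm))
}

#' Enumerate candidate hairpins in a 3' flank
#'
#' All (start, stem, loop) combinations within the parameter bounds whose
#' arms pair antiparallel with at most `max_mismatch` non-pairs and whose
#' folding energy is at or below the cutoff. The flank is the coding-strand
#' sequence immediately downstream of the stop codon.
#'
#' @param seq coding-strand flank sequence (character)
#' @param params a [scan_params()]
#' @return data.frame: start (1-based in the flank), stem_len, loop_len,
#'   mismatches, dg
#' @export
find_hairpins <- function(seq, params = scan_params()) {
  em <- energy_model()
  loop_pen <- em$loop[as.character(params$loop_min:params$loop_max)]
  scan_hairpins_cpp(toupper(seq),
                    params$stem_min, params$stem_max,
                    params$loop_min, params$loop_max,
                    params$max_mismatch, params$max_distance_from_orf,
                    params$dg_cutoff, em$stack, unname(loop_pen),
                    params$mismatch_penalty)
}

#' Classify a gene's 3' flank as L-shaped, I-shaped, or terminator-free
#'
#' If no hairpin passes the cutoff the call is `none`. Otherwise the
#' minimum-energy hairpin is selected (ties broken toward the stop codon)
#' and the downstream window decides the form: L when at least `u_min` U's
#' occur within `u_window` nt after the right arm and the first U starts
#' within `u_max_gap` nt; I otherwise.
#'
#' @param hairpins data.frame from [find_hairpins()] on the same flank
#' @param seq the flank sequence the hairpins came from
#' @param params a [scan_params()]
#' @return list: type ("L"/"I"/"none"), hairpin (one-row data.frame or NULL),
#'   u_tract_length (U count in the window; 0 when type is none)
#' @export
classify_terminator <- function(hairpins, seq, params = scan_params()) {
  if (nrow(hairpins) == 0)
    return(list(type = "none", hairpin = NULL, u_tract_length = 0L))
  ord <- order(hairpins$dg, hairpins$start)
  best <- hairpins[ord[1], , drop = FALSE]
  stem_end <- best$start - 1L + 2L * best$stem_len + best$loop_len
  chars <- strsplit(toupper(seq), "")[[1]]
  win <- chars[seq.int(stem_end + 1L,
                       min(length(chars), stem_end + params$u_window))]
  n_u <- sum(win == "T")
  first_u <- if (n_u > 0) which(win == "T")[1] else Inf
  is_l <- n_u >= params$u_min && (first_u - 1) <= params$u_max_gap
  list(type = if (is_l) "L" else "I", hairpin = best,
       u_tract_length = as.integer(n_u))
}

#' Extract coding-strand 3' flanks downstream of each stop codon
#'
#' The flank runs up to `max_len` nt downstream of the gene on the coding
#' strand, truncated at the contig end and at the start of the next annotated
#' gene (any strand). Minus-strand genes are reverse-complemented.
#'
#' @param annotation annotation data.frame (internal 0-based half-open)
#' @param genome DNAStringSet
#' @param max_len flank length (default 300, comfortably covering the 270-nt
#'   scan window plus the widest hairpin)
#' @param truncate_at_next_gene logical
#' @return named character vector of flank sequences (names = gene_id)
#' @export
extract_3prime_flanks <- function(annotation, genome, max_len = 300,
                                  truncate_at_next_gene = TRUE) {
  validate_annotation(annotation, genome)
  flanks <- character(nrow(annotation))
  names(flanks) <- annotation$gene_id
  for (i in seq_len(nrow(annotation))) {
    seqid <- annotation$seq_id[i]
    contig <- genome[[seqid]]
    clen <- length(contig)
    others <- annotation[annotation$seq_id == seqid &
                           annotation$gene_id != annotation$gene_id[i], ,
                         drop = FALSE]
    if (annotation$strand[i] == "+") {
      from0 <- annotation$end[i]
      to0 <- min(from0 + max_len, clen)
      if (truncate_at_next_gene && nrow(others)) {
        nxt <- others$start[others$start >= from0]
        if (length(nxt)) to0 <- min(to0, min(nxt))
      }
      flanks[i] <- if (to0 > from0)
        as.character(Biostrings::subseq(contig, from0 + 1, to0)) else ""
    } else {
      to0 <- annotation$start[i]
      from0 <- max(to0 - max_len, 0)
      if (truncate_at_next_gene && nrow(others)) {
        prv <- others$end[others$end <= to0]
        if (length(prv)) from0 <- max(from0, max(prv))
      }
      flanks[i] <- if (to0 > from0)
        as.character(Biostrings::reverseComplement(
          Biostrings::subseq(contig, from0 + 1, to0))) else ""
    }
  }
  flanks
}

#' Scan every gene for an intrinsic terminator and classify its form
#'
#' @param annotation annotation data.frame
#' @param genome DNAStringSet
#' @param params a [scan_params()]
#' @return data.frame of class `terminator_calls`: gene_id, type, start,
#'   stem_len, loop_len, mismatches, dg, u_tract_length (NA fields when type
#'   is none)
#' @export
scan_terminators <- function(annotation, genome, params = scan_params()) {
  flanks <- extract_3prime_flanks(annotation, genome,
                                  max_len = params$max_distance_from_orf + 30)
  rows <- lapply(annotation$gene_id, function(g) {
    fl <- flanks[[g]]
    hp <- if (nchar(fl) >= 2 * params$stem_min + params$loop_min)
      find_hairpins(fl, params)
    else data.frame(start = integer(), stem_len = integer(),
                    loop_len = integer(), mismatches = integer(),
                    dg = numeric())
    cl <- classify_terminator(hp, fl, params)
    if (is.null(cl$hairpin))
      data.frame(gene_id = g, type = "none", start = NA_integer_,
                 stem_len = NA_integer_, loop_len = NA_integer_,
                 mismatches = NA_integer_, dg = NA_real_,
                 u_tract_length = 0L, stringsAsFactors = FALSE)
    else
      data.frame(gene_id = g, type = cl$type, cl$hairpin,
                 u_tract_length = cl$u_tract_length,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("terminator_calls", "data.frame")
  out
}

#' Write terminator calls as BED6
#'
#' One record per gene with a hairpin; chromStart/chromEnd span the hairpin
#' on the genome, the name field carries the call type, the score is
#' `round(-dg * 10)`, and the strand is the gene's coding strand.
#'
#' @param calls data.frame from [scan_terminators()]
#' @param annotation annotation data.frame
#' @param path output BED path
#' @return invisibly, `path`
#' @export
write_terminator_bed <- function(calls, annotation, path) {
  hit <- calls[calls$type != "none", , drop = FALSE]
  ann <- annotation[match(hit$gene_id, annotation$gene_id), , drop = FALSE]
  hp_len <- 2L * hit$stem_len + hit$loop_len
  start0 <- ifelse(ann$strand == "+",
                   ann$end + hit$start - 1L,
                   ann$start - (hit$start - 1L) - hp_len)
  lines <- paste(ann$seq_id, start0, start0 + hp_len,
                 hit$type, round(-hit$dg * 10), ann$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Association between terminator form and transcript half-life
#'
#' Median half-life per terminator type over decay-class genes, with pairwise
#' Welch t tests Bonferroni-adjusted over the three comparisons
#' (L vs I, L vs none, I vs none).
#'
#' @param calls data.frame from [scan_terminators()]
#' @param fits half-life table (gene_id, class, t_half)
#' @return list: groups (data.frame type, n, median), tests (data.frame
#'   group1, group2, p_raw, p_adjusted)
#' @export
terminator_association <- function(calls, fits) {
  dec <- fits[fits$class == "decay" & is.finite(fits$t_half), , drop = FALSE]
  dec$type <- calls$type[match(dec$gene_id, calls$gene_id)]
  dec <- dec[!is.na(dec$type), , drop = FALSE]
  split_hl <- split(dec$t_half, dec$type)
  small <- names(split_hl)[vapply(split_hl, length, integer(1)) < 2]
  if (length(small)) {
    warning(sprintf("terminator group(s) with < 2 members excluded: %s",
                    paste(small, collapse = ", ")))
    split_hl <- split_hl[!names(split_hl) %in% small]
  }
  if (length(split_hl) < 2)
    stop("need >= 2 terminator type groups with >= 2 decay-class members")
  groups <- data.frame(
    type = names(split_hl),
    n = vapply(split_hl, length, integer(1)),
    median = vapply(split_hl, stats::median, numeric(1)),
    stringsAsFactors = FALSE)
  combos <- utils::combn(names(split_hl), 2)
  n_comparisons <- 3   # the full L/I/none family
  tests <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    g1 <- combos[1, i]; g2 <- combos[2, i]
    p <- welch_p(split_hl[[g1]], split_hl[[g2]])
    data.frame(group1 = g1, group2 = g2, p_raw = p,
               p_adjusted = min(1, p * n_comparisons),
               stringsAsFactors = FALSE)
  }))
  list(groups = groups, tests = tests)
}
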