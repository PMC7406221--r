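test_that("fold_energy sums the shipped stacking table plus loop penalty", {
  em <- energy_model()
  # six G-C pairs: five GC/GC stacks plus the loop-4 initiation penalty
  expect_equal(fold_energy("GGGGGG", "CCCCCC", 4)$dg,
               5 * em$stack["GC", "GC"] + em$loop[["4"]])
  expect_equal(fold_energy("GGGGGG", "CCCCCC", 4)$dg, 5 * -3.26 + 5.6)
  # alternating G/C stem uses the two alternating stack terms
  expect_equal(fold_energy("GCGCGCGC", "GCGCGCGC", 4)$dg,
               4 * em$stack["GC", "CG"] + 3 * em$stack["CG", "GC"] +
                 em$loop[["4"]])
  # zero-length stem is the loop penalty alone and can never pass the cutoff
  expect_equal(fold_energy("", "", 4)$dg, em$loop[["4"]])
  expect_gt(fold_energy("", "", 4)$dg, scan_params()$dg_cutoff)
  expect_error(fold_energy("GG", "CC", 2), ">= 3")
})

test_that("each mismatch adds exactly the flat penalty", {
  # left arm GGAGG against CCCCC: position 3 cannot pair
  base <- fold_energy("GGAGG", "CCTCC", 4)   # A-T pairs: 0 mismatches
  mm <- fold_energy("GGAGG", "CCCCC", 4)     # A-C: 1 mismatch
  expect_equal(mm$mismatches, 1L)
  mm0 <- fold_energy("GGAGG", "CCCCC", 4, mismatch_penalty = 0)
  expect_equal(mm$dg - mm0$dg, 1.0)
  # G:T wobble counts as a pair, not a mismatch
  expect_equal(fold_energy("GGGGG", "CCTCC", 4)$mismatches, 0L)
})

test_that("find_hairpins equals the brute-force enumeration oracle", {
  set.seed(77)
  params <- scan_params()
  for (i in 1:60) {
    s <- random_dna(sample(40:100, 1))
    got <- find_hairpins(s, params)
    want <- oracle_find_hairpins(s, params)
    got <- got[order(got$start, got$stem_len, got$loop_len), ]
    want <- want[order(want$start, want$stem_len, want$loop_len), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("planted perfect stems are detected and weak stems rejected", {
  arm <- "GCGGCCGC"
  hp_seq <- paste0(random_dna(20), arm, "AACA",
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(arm))), random_dna(30))
  hits <- find_hairpins(hp_seq)
  expect_gt(nrow(hits), 0)
  exact <- hits[hits$start == 21 & hits$stem_len == 8, ]
  expect_equal(nrow(exact), 1)
  expect_equal(exact$mismatches, 0L)
  expect_lt(exact$dg, scan_params()$dg_cutoff)
  # no complementarity at all
  expect_equal(nrow(find_hairpins(strrep("A", 60))), 0)
  # a weak short A-T stem folds above the -11.618 kcal/mol cutoff
  weak <- paste0(strrep("G", 10), "AATT", "CACA", "AATT", strrep("G", 10))
  expect_equal(nrow(find_hairpins(weak)), 0)
})

test_that("every reported hairpin satisfies the scan parameter bounds", {
  set.seed(99)
  params <- scan_params()
  seqs <- c(replicate(25, random_dna(300)),
            vapply(1:10, function(i) {
              arm <- paste(sample(c("G", "C"), 9, replace = TRUE), collapse = "")
              paste0(random_dna(sample(0:250, 1)), arm, "GACA",
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(arm))), random_dna(40))
            }, character(1)))
  for (s in seqs) {
    hp <- find_hairpins(s, params)
    if (!nrow(hp)) next
    expect_true(all(hp$stem_len >= params$stem_min &
                      hp$stem_len <= params$stem_max))
    expect_true(all(hp$loop_len >= params$loop_min &
                      hp$loop_len <= params$loop_max))
    expect_true(all(hp$mismatches <= params$max_mismatch))
    expect_true(all(hp$dg <= params$dg_cutoff))
    expect_true(all(hp$start <= params$max_distance_from_orf))
  }
})

test_that("the U-tract rule separates L from I and absent hairpins are none", {
  arm <- "GCGGCCGC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
  mk <- function(tail) paste0(random_dna(10), arm, "AACA", rc, tail,
                              random_dna(20))
  set.seed(5)
  l_seq <- mk("TTTTTT")
  i_seq <- mk("GCGCGCGC")
  cl_l <- classify_terminator(find_hairpins(l_seq), l_seq)
  cl_i <- classify_terminator(find_hairpins(i_seq), i_seq)
  expect_equal(cl_l$type, "L")
  expect_gte(cl_l$u_tract_length, 4L)
  expect_equal(cl_i$type, "I")
  empty <- classify_terminator(find_hairpins(strrep("A", 60)), strrep("A", 60))
  expect_equal(empty$type, "none")
  expect_null(empty$hairpin)
})

test_that("scanning is reverse-complement symmetric across strands", {
  set.seed(11)
  arm <- "GGCGCCGG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
  flank <- paste0(random_dna(12), arm, "CAAC", rc, "TTTTTT", random_dna(260))
  gene_seq <- random_dna(120)
  left_pad <- random_dna(320)
  # + strand gene: flank sits right of the gene
  plus_contig <- paste0(left_pad, gene_seq, flank)
  # - strand gene: the same coding construct, reverse-complemented, left of
  # the gene's genomic start
  minus_contig <- paste0(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(flank))),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_seq))),
    random_dna(320))
  ann <- data.frame(
    gene_id = c("gp", "gm"), seq_id = c("cp", "cm"),
    start = c(320L, nchar(flank)), end = c(440L, nchar(flank) + 120L),
    strand = c("+", "-"), category = "", operon_id = "",
    operon_index = NA_integer_, stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(c(cp = plus_contig, cm = minus_contig))
  calls <- scan_terminators(ann, genome)
  expect_equal(calls$type, c("L", "L"))
  expect_equal(calls$start[1], calls$start[2])
  expect_equal(calls$dg[1], calls$dg[2])
})

test_that("BED export places hairpins on genomic coordinates by strand", {
  ann <- data.frame(gene_id = c("gp", "gm"), seq_id = "chr",
                    start = c(100L, 900L), end = c(200L, 1000L),
                    strand = c("+", "-"), category = "", operon_id = "",
                    operon_index = NA_integer_, stringsAsFactors = FALSE)
  calls <- data.frame(gene_id = c("gp", "gm"), type = c("L", "I"),
                      start = c(16L, 16L), stem_len = c(8L, 8L),
                      loop_len = c(4L, 4L), mismatches = c(0L, 0L),
                      dg = c(-15.25, -13.4), u_tract_length = c(6L, 0L),
                      stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".bed")
  write_terminator_bed(calls, ann, p)
  bed <- read.table(p, sep = "\t")
  # + strand: starts 15 nt after the gene end; span = 2*8+4 = 20
  expect_equal(bed$V2[1], 200 + 15); expect_equal(bed$V3[1], 200 + 35)
  # - strand: ends 15 nt before the gene start
  expect_equal(bed$V3[2], 900 - 15); expect_equal(bed$V2[2], 900 - 35)
  expect_equal(bed$V5, round(-calls$dg * 10))
  expect_equal(bed$V4, calls$type)
  expect_equal(bed$V6, c("+", "-"))
})

test_that("terminator association detects a planted L effect", {
  set.seed(42)
  n <- 200
  hl <- c(rlnorm(n, log(1), 0.25 * log(10)) + 0.5,   # L, +0.5 min
          rlnorm(n, log(1), 0.25 * log(10)))          # none
  fits <- data.frame(gene_id = sprintf("g%03d", 1:(2 * n)), class = "decay",
                     t_half = hl, stringsAsFactors = FALSE)
  calls <- data.frame(gene_id = fits$gene_id,
                      type = rep(c("L", "none"), each = n),
                      stringsAsFactors = FALSE)
  res <- terminator_association(calls, fits)
  p_ln <- res$tests$p_adjusted[res$tests$group1 == "L" |
                                 res$tests$group2 == "L"]
  expect_lt(min(p_ln), 0.01)
  expect_gt(res$groups$median[res$groups$type == "L"],
            res$groups$median[res$groups$type == "none"])
  # Bonferroni: adjusted = min(1, 3 * raw)
  expect_equal(res$tests$p_adjusted, pmin(1, 3 * res$tests$p_raw))
})

test_that("identical groups give capped adjusted p-values of one", {
  fits <- data.frame(gene_id = sprintf("g%02d", 1:30), class = "decay",
                     t_half = rep(c(1, 2, 3), 10), stringsAsFactors = FALSE)
  calls <- data.frame(gene_id = fits$gene_id,
                      type = rep(c("L", "I", "none"), each = 10),
                      stringsAsFactors = FALSE)
  res <- terminator_association(calls, fits)
  expect_true(all(res$tests$p_adjusted == 1))
  # groups of one member are excluded with a warning
  fits2 <- fits[1:11, ]; fits2$gene_id -> ids
  calls2 <- data.frame(gene_id = ids, type = c(rep("L", 10), "I"),
                       stringsAsFactors = FALSE)
  expect_error(expect_warning(terminator_association(calls2, fits2), "I"),
               ">= 2")
})
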