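#' Simulation configuration for a rifampin run-off experiment
#'
#' Defaults mirror the measured study design: 7 time points (0, 0.5, 1, 2.5,
#' 5, 7.5, 10 min) x 3 biological replicates, a heavy-right-tailed half-life
#' distribution with median 1 min (log-normal, log10-sd 0.25, right-truncated
#' at 10 min), negative-binomial count noise, spike-ins spanning 0.1 to 1,000
#' copies/cell, and an optional residual-transcription onset delay at
#' 25 nt/s. The shrinking mRNA pool emerges mechanistically from decay; no
#' extra global factor is injected.
#'
#' @param n_genes number of genes.
#' @param time_grid minutes after rifampin; strictly increasing, starts at 0.
#' @param n_replicates biological replicates.
#' @param halflife_median,halflife_log10_sd,halflife_max log-normal half-life
#'   distribution (minutes); values above `halflife_max` are redrawn.
#' @param expression_meanlog,expression_sdlog log-normal initial abundance
#'   (arbitrary copy units; with the default 1-kb genes and `depth = 1`, the
#'   median gene yields ~100 expected counts at t = 0).
#' @param dispersion negative-binomial overdispersion (NB size = 1/dispersion);
#'   0 switches noise off entirely and emits expected counts.
#' @param depth mean library scale per sample; per-sample log-normal
#'   variability with sd `depth_sdlog` emulates library-size differences.
#' @param stable_fraction fraction of genes with no decay.
#' @param elongation_rate nt/s used to convert distance from the transcription
#'   start site into an onset delay (0 disables the delay).
#' @param gene_length nt per simulated gene (constant).
#' @param n_operons,operon_size leading genes are grouped into operons of this
#'   size on the + strand; members share the operon's half-life draw and get
#'   `tss_distance` from their position.
#' @param terminator_plan NULL, or list(fraction = c(L=,I=,none=),
#'   effect = c(L=,I=,none=)) of per-type planting probabilities and additive
#'   half-life effects (minutes).
#' @param motif_plan NULL, or list(motif =, region = "3utr"|"5utr",
#'   fraction =, effect =) planting one k-mer with an additive half-life
#'   effect.
#' @param spikein_manifest data.frame (id, length, copies_per_cell).
#' @param spike_scale expected spike-in counts per (copy/cell x kb) at
#'   depth 1.
#' @param seed integer seed; all outputs are deterministic given the config.
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_genes = 100,
                       time_grid = c(0, 0.5, 1, 2.5, 5, 7.5, 10),
                       n_replicates = 3,
                       halflife_median = 1.0,
                       halflife_log10_sd = 0.25,
                       halflife_max = 10,
                       expression_meanlog = log(100),
                       expression_sdlog = 1,
                       dispersion = 0.1,
                       depth = 1,
                       depth_sdlog = 0.15,
                       stable_fraction = 0,
                       elongation_rate = 25,
                       gene_length = 1000,
                       n_operons = 0,
                       operon_size = 1,
                       terminator_plan = NULL,
                       motif_plan = NULL,
                       spikein_manifest = default_spikein_manifest(),
                       spike_scale = 100,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 0, n_replicates >= 1,
            halflife_median > 0, halflife_log10_sd >= 0, halflife_max > 0,
            dispersion >= 0, depth > 0, spike_scale > 0, gene_length > 0,
            stable_fraction >= 0, stable_fraction <= 1,
            elongation_rate >= 0,
            n_operons * operon_size <= n_genes)
  if (time_grid[1] != 0 || any(diff(time_grid) <= 0))
    stop("time_grid must be strictly increasing and start at 0")
  validate_spikein_manifest(cfg$spikein_manifest)
  class(cfg) <- "sim_config"
  cfg
}

.BASES <- c("A", "C", "G", "T")

revcomp_chars <- function(ch) rev(chartr("ACGT", "TGCA", ch))

# GC-rich stem arms for planted hairpins: 8 stacked G/C pairs fold far below
# the -11.618 kcal/mol reporting cutoff under the shipped energy table.
random_stem <- function(len = 9) sample(c("G", "C"), len, replace = TRUE)

#' Simulate a genome with annotation and planted sequence elements
#'
#' Genes are laid out on a single contig with 350-nt flanks on both sides, so
#' every gene has >= 270 nt of intergenic room downstream for terminator
#' planting and 150 nt upstream for the 5' UTR window. Planted intrinsic
#' terminators are a 9-bp G/C stem with a 4-nt loop starting 15 nt after the
#' stop codon; L-shaped plants append six consecutive T's (U's on the
#' transcript) immediately after the hairpin, I-shaped plants append a fixed
#' U-free spacer. Planted UTR k-mers are written into the designated window.
#' Everything planted is recorded in the returned ground truth.
#'
#' @param config a [sim_config()]
#' @return list with `genome` (DNAStringSet), `annotation` (data.frame) and
#'   `truth` (data.frame: gene_id, true_halflife, stable,
#'   true_initial_abundance, planted_terminator, planted_motif, operon_id,
#'   operon_index, tss_distance)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  L <- config$gene_length
  pad <- 350L
  block <- 2L * pad + L
  if (n == 0) {
    return(list(genome = Biostrings::DNAStringSet(c(contig1 = paste(
                  sample(.BASES, 1000, replace = TRUE), collapse = ""))),
                annotation = empty_annotation(),
                truth = empty_truth()))
  }

  chars <- sample(.BASES, n * block, replace = TRUE)
  gene_id <- sprintf("gene%04d", seq_len(n))

  # operon membership
  operon_id <- rep("", n)
  operon_index <- rep(NA_integer_, n)
  n_op_genes <- config$n_operons * config$operon_size
  if (n_op_genes > 0) {
    operon_id[seq_len(n_op_genes)] <-
      rep(sprintf("op%03d", seq_len(config$n_operons)),
          each = config$operon_size)
    operon_index[seq_len(n_op_genes)] <-
      rep(seq_len(config$operon_size), times = config$n_operons)
  }
  # within an operon, genes share the genomic block spacing
  tss_distance <- ifelse(is.na(operon_index), 0,
                         (operon_index - 1) * (L + 2 * pad))
  strand <- ifelse(nzchar(operon_id), "+",
                   sample(c("+", "-"), n, replace = TRUE))

  start0 <- (seq_len(n) - 1L) * block + pad   # 0-based
  end0 <- start0 + L

  # half-lives: log-normal, redraw above the truncation bound; operon members
  # share their operon's draw
  draw_hl <- function(m) {
    x <- 10^stats::rnorm(m, log10(config$halflife_median),
                         config$halflife_log10_sd)
    while (any(bad <- x > config$halflife_max))
      x[bad] <- 10^stats::rnorm(sum(bad), log10(config$halflife_median),
                                config$halflife_log10_sd)
    x
  }
  hl <- draw_hl(n)
  if (n_op_genes > 0) {
    per_op <- draw_hl(config$n_operons)
    hl[seq_len(n_op_genes)] <- rep(per_op, each = config$operon_size)
  }
  stable <- stats::runif(n) < config$stable_fraction
  a0 <- stats::rlnorm(n, config$expression_meanlog, config$expression_sdlog)

  # terminator planting
  term_type <- rep("none", n)
  if (!is.null(config$terminator_plan)) {
    fr <- config$terminator_plan$fraction[c("L", "I", "none")]
    fr[is.na(fr)] <- 0
    term_type <- sample(c("L", "I", "none"), n, replace = TRUE, prob = fr)
    eff <- config$terminator_plan$effect
    for (ty in c("L", "I", "none"))
      if (!is.null(eff) && !is.na(eff[ty]))
        hl[term_type == ty & !stable] <- hl[term_type == ty & !stable] + eff[ty]
  }
  plant_at <- function(i, offset_in_flank, coding_chars) {
    # offset_in_flank: 0-based offset of the element start downstream of the
    # stop codon, in coding orientation
    m <- length(coding_chars)
    if (strand[i] == "+") {
      g0 <- end0[i] + offset_in_flank          # 0-based genomic start
      chars[g0 + seq_len(m)] <<- coding_chars
    } else {
      g_end <- start0[i] - offset_in_flank     # element occupies [g_end-m, g_end)
      chars[(g_end - m) + seq_len(m)] <<- revcomp_chars(coding_chars)
    }
  }
  term_end_in_flank <- rep(0L, n)  # coding-strand offset where planting ends
  if (!is.null(config$terminator_plan)) {
    # Zero-sequence-noise backgrounds: redraw each 3' flank until it carries
    # no chance hairpin at or below the reporting cutoff, so the only
    # terminator signal is the planted one.
    flank_len <- 300L
    params <- scan_params()
    for (i in seq_len(n)) {
      repeat {
        f <- sample(.BASES, flank_len, replace = TRUE)
        if (nrow(find_hairpins(paste(f, collapse = ""), params)) == 0) break
      }
      if (term_type[i] != "none") {
        stem <- random_stem(9)
        loop <- sample(c("A", "C", "G"), 4, replace = TRUE)
        tail <- if (term_type[i] == "L") strsplit("TTTTTT", "")[[1]]
                else strsplit("GACAGGCA", "")[[1]]
        hp <- c(stem, loop, revcomp_chars(stem), tail)
        f[15L] <- if (term_type[i] == "L") "C" else "A"  # blocks stem extension
        f[15L + seq_along(hp)] <- hp
        term_end_in_flank[i] <- 15L + length(hp)
      }
      if (strand[i] == "+") {
        chars[end0[i] + seq_len(flank_len)] <- f
      } else {
        chars[(start0[i] - flank_len) + seq_len(flank_len)] <- revcomp_chars(f)
      }
    }
  }

  # motif planting
  motif_flag <- rep("", n)
  if (!is.null(config$motif_plan)) {
    mp <- config$motif_plan
    mot <- strsplit(mp$motif, "")[[1]]
    window <- if (identical(mp$region, "5utr")) 150L else 100L
    chosen <- which(stats::runif(n) < mp$fraction)
    for (i in chosen) {
      if (identical(mp$region, "3utr")) {
        lo <- term_end_in_flank[i]
        hi <- window - length(mot)
        if (lo > hi) next   # no room left in the window
        off <- sample(lo:hi, 1)
        plant_at(i, off, mot)
      } else {
        off <- sample(0:(window - length(mot)), 1)
        m <- length(mot)
        if (strand[i] == "+") {
          g0 <- start0[i] - window + off
          chars[g0 + seq_len(m)] <- mot
        } else {
          g_end <- end0[i] + window - off
          chars[(g_end - m) + seq_len(m)] <- revcomp_chars(mot)
        }
      }
      motif_flag[i] <- mp$motif
      hl[i] <- if (stable[i]) hl[i] else hl[i] + mp$effect
    }
  }

  genome <- Biostrings::DNAStringSet(c(contig1 = paste(chars, collapse = "")))
  annotation <- data.frame(
    gene_id = gene_id, seq_id = "contig1",
    start = start0, end = end0, strand = strand,
    category = "", operon_id = operon_id, operon_index = operon_index,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = gene_id,
    true_halflife = ifelse(stable, Inf, hl),
    stable = stable,
    true_initial_abundance = a0,
    planted_terminator = term_type,
    planted_motif = motif_flag,
    operon_id = operon_id, operon_index = operon_index,
    tss_distance = tss_distance,
    stringsAsFactors = FALSE)
  list(genome = genome, annotation = annotation, truth = truth)
}

empty_annotation <- function() {
  data.frame(gene_id = character(), seq_id = character(),
             start = integer(), end = integer(), strand = character(),
             category = character(), operon_id = character(),
             operon_index = integer(), stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(gene_id = character(), true_halflife = numeric(),
             stable = logical(), true_initial_abundance = numeric(),
             planted_terminator = character(), planted_motif = character(),
             operon_id = character(), operon_index = integer(),
             tss_distance = numeric(), stringsAsFactors = FALSE)
}

#' Simulate the rifampin time-course count matrix
#'
#' Expected abundance follows first-order decay in base-2 form,
#' `a_i(t) = A0_i * 2^(-max(0, t - d_i) / thalf_i)`, where the onset delay
#' `d_i = tss_distance_i / (elongation_rate * 60)` minutes models residual
#' run-off transcription after rifampin blocks initiation. Stable genes stay
#' constant. Counts are negative binomial with mean
#' `depth_s * a_i(t) * length_i/1000` and size `1/dispersion`; spike-in means
#' are `depth_s * spike_scale * copies_per_cell * length/1000` and are
#' unaffected by the shrinking mRNA pool. With `dispersion = 0` the expected
#' values are returned unchanged (deterministic mode).
#'
#' @param truth truth data.frame from [simulate_genome()]
#' @param config the same [sim_config()]
#' @return list with `counts` (a [count_matrix()]) and `depths` (the drawn
#'   per-sample library scales, named by sample id)
#' @export
simulate_timecourse <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000003L)
  grid <- config$time_grid
  reps <- seq_len(config$n_replicates)
  samples <- expand.grid(time = grid, replicate = reps,
                         KEEP.OUT.ATTRS = FALSE)
  samples <- data.frame(
    sample_id = sprintf("rep%d_t%g", samples$replicate, samples$time),
    replicate = paste0("rep", samples$replicate),
    time = samples$time, stringsAsFactors = FALSE)
  ns <- nrow(samples)
  depths <- config$depth * stats::rlnorm(ns, 0, config$depth_sdlog)
  names(depths) <- samples$sample_id

  delay <- if (config$elongation_rate > 0)
    truth$tss_distance / (config$elongation_rate * 60) else rep(0, nrow(truth))
  len_kb <- config$gene_length / 1000
  draw <- function(mu) {
    if (config$dispersion == 0) mu
    else stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  gene_counts <- vapply(seq_len(ns), function(s) {
    t <- samples$time[s]
    eff_t <- pmax(0, t - delay)
    a <- ifelse(truth$stable, truth$true_initial_abundance,
                truth$true_initial_abundance * 2^(-eff_t / truth$true_halflife))
    draw(depths[s] * a * len_kb)
  }, numeric(nrow(truth)))
  man <- config$spikein_manifest
  spike_counts <- vapply(seq_len(ns), function(s) {
    draw(depths[s] * config$spike_scale * man$copies_per_cell * man$length / 1000)
  }, numeric(nrow(man)))
  counts <- rbind(gene_counts, spike_counts)
  dimnames(counts) <- list(c(truth$gene_id, man$id), samples$sample_id)
  list(counts = count_matrix(counts, samples, man$id), depths = depths)
}

#' Deterministic named fixtures
#'
#' Fixed-seed simulated bundles used throughout the test suite and
#' documentation:
#' \describe{
#'   \item{tiny}{20 genes, 21 samples, noiseless (`dispersion = 0`); runs
#'     end to end in seconds.}
#'   \item{default}{500 genes at ~100 mean counts per median gene at t = 0,
#'     NB size 10 (`dispersion = 0.1`).}
#'   \item{operon}{25 operons x 4 genes sharing a half-life, residual
#'     transcription delay at 25 nt/s.}
#'   \item{terminator}{300 genes planted L/I/none in equal thirds, with a
#'     +0.5 min half-life effect for L.}
#'   \item{ml}{2,000 genes with one stabilizing 3' UTR 6-mer (CTTCGG, +1.0
#'     min) planted in half the genes; narrow baseline half-life spread so
#'     the planted effect dominates the learnable signal.}
#' }
#'
#' @param name fixture name
#' @param dir optional directory; when given, FASTA, GFF3, per-sample count
#'   files, spike-in manifest and truth table are written there.
#' @param seed base seed (default 42); the same seed always yields the same
#'   bundle.
#' @return list with `genome`, `annotation`, `truth`, `counts`, `depths`,
#'   `config`
#' @export
make_fixture <- function(name = c("tiny", "default", "operon", "terminator", "ml"),
                         dir = NULL, seed = 42L) {
  name <- match.arg(name)
  config <- switch(name,
    tiny = sim_config(n_genes = 20, dispersion = 0, seed = seed),
    default = sim_config(n_genes = 500, dispersion = 0.1,
                         expression_meanlog = log(100),
                         expression_sdlog = 0.5, seed = seed),
    operon = sim_config(n_genes = 100, n_operons = 25, operon_size = 4,
                        dispersion = 0.05, elongation_rate = 25,
                        halflife_median = 1.5, seed = seed),
    terminator = sim_config(
      n_genes = 300, dispersion = 0.1,
      terminator_plan = list(
        fraction = c(L = 1 / 3, I = 1 / 3, none = 1 / 3),
        effect = c(L = 0.5, I = 0, none = 0)),
      seed = seed),
    ml = sim_config(
      n_genes = 2000, dispersion = 0.1, halflife_log10_sd = 0.15,
      motif_plan = list(motif = "CTTCGG", region = "3utr",
                        fraction = 0.5, effect = 1.0),
      seed = seed))
  g <- simulate_genome(config)
  tc <- simulate_timecourse(g$truth, config)
  out <- list(genome = g$genome, annotation = g$annotation, truth = g$truth,
              counts = tc$counts, depths = tc$depths, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(g$genome, file.path(dir, "genome.fa"))
    write_annotation(g$annotation, file.path(dir, "genes.gff3"))
    write_counts(tc$counts, file.path(dir, "counts"))
    utils::write.table(config$spikein_manifest,
                       file.path(dir, "spikein_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(g$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tc$counts$samples, file.path(dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
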