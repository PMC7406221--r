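test_that("fixtures are deterministic given the seed", {
  a <- make_fixture("tiny")
  b <- make_fixture("tiny")
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
})

test_that("noiseless expected abundance follows the base-2 decay closed form", {
  cfg <- sim_config(n_genes = 1, dispersion = 0, depth_sdlog = 0, seed = 3)
  truth <- data.frame(gene_id = "g1", true_halflife = 1, stable = FALSE,
                      true_initial_abundance = 100,
                      planted_terminator = "none", planted_motif = "",
                      operon_id = "", operon_index = NA_integer_,
                      tss_distance = 0, stringsAsFactors = FALSE)
  tc <- simulate_timecourse(truth, cfg)
  counts <- tc$counts$counts["g1", ]
  times <- tc$counts$samples$time
  # A0 = 100, t1/2 = 1 min, 1-kb gene, depth 1: expected count at t is
  # exactly 100 * 2^-t; at t = 1 that is 50
  expect_equal(unname(counts[times == 1]), rep(50, 3))
  expect_equal(unname(counts), 100 * 2^(-times))
})

test_that("tss distance and elongation rate set the onset delay", {
  # 1,500 nt at 25 nt/s is a 1-minute delay: flat until t = 1, halving after
  cfg <- sim_config(n_genes = 1, dispersion = 0, depth_sdlog = 0,
                    elongation_rate = 25, seed = 3)
  truth <- data.frame(gene_id = "g1", true_halflife = 1, stable = FALSE,
                      true_initial_abundance = 100,
                      planted_terminator = "none", planted_motif = "",
                      operon_id = "op1", operon_index = 2L,
                      tss_distance = 1500, stringsAsFactors = FALSE)
  tc <- simulate_timecourse(truth, cfg)
  counts <- tc$counts$counts["g1", ]
  times <- tc$counts$samples$time
  expect_equal(unname(counts[times == 0.5]), rep(100, 3))
  expect_equal(unname(counts[times == 1]), rep(100, 3))
  expect_equal(unname(counts[times == 2]), numeric(0)) # not on the grid
  expect_equal(unname(counts[times == 2.5]), rep(100 * 2^-1.5, 3))
  # disabling the rate disables the delay
  cfg0 <- sim_config(n_genes = 1, dispersion = 0, depth_sdlog = 0,
                     elongation_rate = 0, seed = 3)
  tc0 <- simulate_timecourse(truth, cfg0)
  expect_equal(unname(tc0$counts$counts["g1", times == 1]), rep(50, 3))
})

test_that("count noise matches the negative-binomial parameterization", {
  # stable genes at a fixed mean: across many genes the sample variance must
  # approach mu * (1 + mu * dispersion)
  n <- 5000
  cfg <- sim_config(n_genes = n, dispersion = 0.1, depth_sdlog = 0,
                    expression_meanlog = log(100), expression_sdlog = 0,
                    stable_fraction = 1, n_replicates = 1, seed = 5)
  truth <- data.frame(gene_id = sprintf("g%d", 1:n), true_halflife = Inf,
                      stable = TRUE, true_initial_abundance = 100,
                      planted_terminator = "none", planted_motif = "",
                      operon_id = "", operon_index = NA_integer_,
                      tss_distance = 0, stringsAsFactors = FALSE)
  tc <- simulate_timecourse(truth, cfg)
  x <- tc$counts$counts[truth$gene_id, 1]
  expect_equal(mean(x), 100, tolerance = 0.05)
  expect_equal(var(x), 100 * (1 + 100 * 0.1), tolerance = 0.15)
})

test_that("spike-in counts do not shrink with the mRNA pool", {
  fx <- cached_fixture("default")
  spikes <- fx$counts$counts[fx$counts$spikein_ids, , drop = FALSE]
  sums <- colSums(spikes) / fx$depths   # remove library-scale variation
  fit <- lm(sums ~ fx$counts$samples$time)
  slope_rel <- coef(fit)[2] / mean(sums)
  expect_lt(abs(slope_rel), 0.01)
  # while the gene pool does shrink
  genes <- colSums(fx$counts$counts[gene_ids(fx$counts), ]) / fx$depths
  expect_lt(mean(genes[fx$counts$samples$time == 10]),
            0.5 * mean(genes[fx$counts$samples$time == 0]))
})

test_that("planted terminators are written into the 3' flank as specified", {
  cfg <- sim_config(
    n_genes = 12, dispersion = 0,
    terminator_plan = list(fraction = c(L = 1, I = 0, none = 0),
                           effect = c(L = 0.5, I = 0, none = 0)),
    seed = 9)
  g <- simulate_genome(cfg)
  flanks <- extract_3prime_flanks(g$annotation, g$genome)
  for (fl in flanks) {
    # a hairpin detectable by the independent enumeration oracle ...
    hp <- oracle_find_hairpins(substr(fl, 1, 60))
    expect_gt(nrow(hp), 0)
    # ... followed by the six-U tract on the coding strand
    expect_match(fl, "TTTTTT")
  }
  expect_true(all(g$truth$planted_terminator == "L"))
})

test_that("zero genes give an empty but well-formed simulation", {
  g <- simulate_genome(sim_config(n_genes = 0, seed = 1))
  expect_equal(nrow(g$annotation), 0)
  expect_equal(nrow(g$truth), 0)
  expect_s4_class(g$genome, "DNAStringSet")
})

test_that("invalid configurations and fixture names are rejected", {
  expect_error(sim_config(time_grid = c(0.5, 1)), "start at 0")
  expect_error(sim_config(time_grid = c(0, 1, 1)), "increasing")
  expect_error(sim_config(dispersion = -1))
  expect_error(make_fixture("nope"))
})

test_that("fixture bundles written to disk re-read into the same data", {
  d <- withr::local_tempdir()
  fx <- make_fixture("tiny", dir = d)
  expect_true(all(file.exists(file.path(d, c("genome.fa", "genes.gff3",
                                             "spikein_manifest.tsv",
                                             "truth.tsv", "samples.tsv")))))
  sheet <- read.table(file.path(d, "samples.tsv"), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  man <- read_spikein_manifest(file.path(d, "spikein_manifest.tsv"))
  cm <- read_counts(file.path(d, "counts", paste0(sheet$sample_id, ".counts.tsv")),
                    sheet, spikein_ids = man$id, integer_counts = FALSE)
  expect_equal(cm$counts[rownames(fx$counts$counts), ],
               fx$counts$counts)
  ref <- read_annotation(file.path(d, "genes.gff3"), file.path(d, "genome.fa"))
  expect_equal(ref$annotation$start, fx$annotation$start)
  expect_equal(ref$annotation$end, fx$annotation$end)
})
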