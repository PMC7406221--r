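grid7 <- c(0, 0.5, 1, 2.5, 5, 7.5, 10)
rep3 <- function(grid = grid7) rep(grid, times = 3)

test_that("an exact exponential recovers its half-life with r2 = 1", {
  times <- rep3()
  a <- 100 * 2^(-times)   # t1/2 = 1 min
  sel <- select_best_prefix(times, a, grid = grid7)
  expect_equal(sel$prefix, 7)   # ties across prefixes resolve to all 7 points
  expect_equal(sel$fit$t_half, 1, tolerance = 1e-9)
  expect_equal(sel$fit$r2, 1, tolerance = 1e-12)
  expect_equal(sel$fit$k * sel$fit$t_half, log(2), tolerance = 1e-12)
})

test_that("a constant series has zero slope and an infinite half-life flag", {
  times <- rep3()
  f <- fit_exponential(times, rep(50, length(times)), 7, grid7)
  expect_equal(f$k, 0, tolerance = 1e-12)
  expect_equal(f$t_half, Inf)
})

test_that("prefix selection matches independently computed r2 values", {
  # exponential down to t = 2.5, then a flat floor: the floor wrecks the
  # late-prefix fits and an early prefix wins
  times <- rep3()
  a <- ifelse(times <= 2.5, 100 * 2^(-2 * times), 100 * 2^(-2 * 2.5))
  sel <- select_best_prefix(times, a, grid = grid7)
  r2_direct <- vapply(3:7, function(p) {
    keep <- times %in% grid7[1:p]
    # perfect fits here are the point; silence summary.lm's caution
    suppressWarnings(summary(lm(log(a[keep]) ~ times[keep]))$r.squared)
  }, numeric(1))
  expect_equal(unname(sel$r2_by_prefix), r2_direct, tolerance = 1e-9)
  # prefixes 3 and 4 are both exactly exponential (tied at r2 = 1); the tie
  # resolves to the larger prefix, and prefixes 5..7 are wrecked by the floor
  expect_equal(sel$prefix, max(which(r2_direct >= max(r2_direct) - 1e-9)) + 2)
  expect_equal(sel$prefix, 4)
})

test_that("prefix 3 uses only the first three grid times", {
  times <- rep3()
  a <- 100 * 2^(-times)
  a[times > 1] <- runif(sum(times > 1), 0, 1000)  # garbage beyond the prefix
  f <- fit_exponential(times, a, 3, grid7)
  expect_equal(f$t_half, 1, tolerance = 1e-9)
  expect_equal(f$n_points, 9)
})

test_that("log-space estimate stays near the nonlinear grid-search oracle", {
  set.seed(21)
  times <- rep3()
  mu <- 500 * 2^(-times / 0.75)
  a <- rnbinom(length(mu), mu = mu, size = 10)
  sel <- select_best_prefix(times, a, grid = grid7)
  oracle <- oracle_nls_halflife(times, a)
  expect_equal(sel$fit$t_half, oracle, tolerance = 0.15)
})

test_that("half-life is invariant to uniform abundance scaling", {
  # strictly positive series: the zero-count pseudocount floor is the one
  # deliberate exception to scale invariance
  set.seed(31)
  times <- rep3()
  a <- rnbinom(length(times), mu = 3000 * 2^(-times / 2), size = 10) + 1
  f1 <- select_best_prefix(times, a, grid = grid7)
  f2 <- select_best_prefix(times, a * 7.3, grid = grid7)
  expect_equal(f1$fit$t_half, f2$fit$t_half, tolerance = 1e-12)
  expect_equal(f1$fit$r2, f2$fit$r2, tolerance = 1e-12)
})

test_that("changing time units rescales k and t_half equivariantly", {
  times <- rep3()
  a <- 100 * 2^(-times / 1.4)
  f_min <- fit_exponential(times, a, 7, grid7)
  f_sec <- fit_exponential(times * 60, a, 7, grid7 * 60)
  expect_equal(f_sec$k, f_min$k / 60, tolerance = 1e-12)
  expect_equal(f_sec$t_half, f_min$t_half * 60, tolerance = 1e-9)
})

test_that("classification follows the no_reads/stable/low_r2/decay order", {
  times <- rep3()
  norm <- 100 * 2^(-times)
  # raw total below the floor wins over everything
  expect_equal(classify_transcript("g", rep(1, 21), norm, times)$class,
               "no_reads")
  # 60% retention at t = 10 is stable, and no half-life is reported
  st <- classify_transcript("g", rep(100, 21),
                            ifelse(times == 10, 60, 100), times)
  expect_equal(st$class, "stable")
  expect_true(is.na(st$t_half))
  # 40% retention is not stable
  expect_false(classify_transcript("g", rep(100, 21),
                                   ifelse(times == 10, 40, 100),
                                   times)$class == "stable")
  # a sawtooth along the grid fits nothing: low_r2 (its final point is low
  # enough that the stable rule does not trigger first)
  saw <- rep(c(100, 5, 100, 5, 100, 5, 5), 3)
  cl <- classify_transcript("g", rep(100, 21), saw, rep3())
  expect_equal(cl$class, "low_r2")
  expect_lt(cl$r2, 0.5)
  # clean decay
  dc <- classify_transcript("g", rep(100, 21), norm, times)
  expect_equal(dc$class, "decay")
  expect_equal(dc$t_half, 1, tolerance = 1e-9)
  # all-zero counts are no_reads
  expect_equal(classify_transcript("g", rep(0, 21), rep(0, 21), times)$class,
               "no_reads")
  # missing boundary time points violate the contract
  expect_error(classify_transcript("g", rep(100, 18), norm[times < 10],
                                   times[times < 10], grid = grid7),
               "final")
})

test_that("fit_all on a noiseless course recovers every half-life exactly", {
  cfg <- noiseless_config(n_genes = 25, seed = 13)
  g <- simulate_genome(cfg)
  tc <- simulate_timecourse(g$truth, cfg)
  norm <- normalize_counts(tc$counts, compute_normalization_factors(tc$counts))
  res <- fit_all(norm, tc$counts)
  expect_true(all(res$fits$class == "decay"))
  rel <- abs(res$fits$t_half - g$truth$true_halflife) / g$truth$true_halflife
  expect_lt(max(rel), 1e-6)
  expect_true(all(res$fits$r2 > 1 - 1e-9))
  expect_true(all(res$fits$expression_level > 0))
})

test_that("fit_all summaries are complete and class fractions sum to one", {
  fx <- cached_fixture("tiny")
  norm <- normalize_counts(fx$counts,
                           compute_normalization_factors(fx$counts))
  res <- fit_all(norm, fx$counts)
  expect_equal(sum(res$summary$class_fractions), 1)
  expect_equal(sum(res$summary$class_counts), res$summary$n)
  hl <- res$fits$t_half[res$fits$class == "decay"]
  expect_equal(res$summary$halflife_median, median(hl))
  expect_equal(res$summary$halflife_mean, mean(hl))
  # every decay-class row satisfies t_half * k = ln 2
  dec <- res$fits[res$fits$class == "decay", ]
  expect_equal(dec$t_half * dec$k, rep(log(2), nrow(dec)), tolerance = 1e-12)
})

test_that("a simulated stable fraction is classified as stable", {
  cfg <- sim_config(n_genes = 60, dispersion = 0.05,
                    expression_meanlog = log(300), expression_sdlog = 0.3,
                    stable_fraction = 0.3, seed = 17)
  g <- simulate_genome(cfg)
  tc <- simulate_timecourse(g$truth, cfg)
  norm <- normalize_counts(tc$counts, compute_normalization_factors(tc$counts))
  res <- fit_all(norm, tc$counts)
  called_stable <- res$fits$class == "stable"
  expect_equal(mean(called_stable == g$truth$stable), 1, tolerance = 0.05)
})
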