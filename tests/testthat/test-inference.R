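test_that("NB tail p-values match closed forms and degenerate conventions", {
  # whole support
  expect_equal(nb_tail_pvalue(0, 5, 2), 1)
  expect_equal(nb_tail_pvalue(0, 0, Inf), 1)
  # Poisson closed form: P(Y >= 1) = 1 - e^-1
  expect_equal(nb_tail_pvalue(1, 1, Inf), 1 - exp(-1), tolerance = 1e-12)
  # geometric tail (theta = 1): P(Y >= 2) = (mu/(mu+theta))^2 = 0.25
  expect_equal(nb_tail_pvalue(2, 1, 1), 0.25, tolerance = 1e-12)
  # lambda_t = 0 with observed signal is maximal evidence
  expect_equal(nb_tail_pvalue(3, 0, 2), 0)
  expect_error(nb_tail_pvalue(-1, 1, 1), "non-negative")
  expect_error(nb_tail_pvalue(1, 1, -2), "positive")
})

test_that("NB tail matches brute-force pmf summation over random triples", {
  set.seed(101)
  n <- 300
  y <- sample(0:50, n, replace = TRUE)
  mu <- runif(n, 0.01, 20)
  th <- sample(c(0.5, 1, 5), n, replace = TRUE)
  diffs <- vapply(seq_len(n), function(k) {
    abs(nb_tail_pvalue(y[k], mu[k], th[k]) - oracle_tail(y[k], mu[k], th[k]))
  }, numeric(1))
  expect_lt(max(diffs), 1e-12)
})

test_that("p, score and z are monotone in the observed count", {
  y <- 0:60
  p <- nb_tail_pvalue(y, 8, 2)
  expect_true(all(diff(p) <= 0))
  expect_true(all(diff(enrichment_score(y, 8)) > 0))
  expect_true(all(diff(nb_z_score(y, 8, 2)) > 0))
})

test_that("heavier overdispersion is more conservative above the mean", {
  for (y in c(10, 20, 40)) {
    expect_gte(nb_tail_pvalue(y, 5, 0.5), nb_tail_pvalue(y, 5, 2))
    expect_gte(nb_tail_pvalue(y, 5, 2), nb_tail_pvalue(y, 5, 10))
  }
})

test_that("the NB tail converges to the Poisson tail at huge dispersion", {
  y <- seq(0, 100, by = 5)
  for (mu in c(1, 10, 50)) {
    expect_lt(max(abs(nb_tail_pvalue(y, mu, 1e6) - nb_tail_pvalue(y, mu, Inf))),
              1e-4)
  }
})

test_that("BH adjustment reproduces the hand-run step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.7)), "\\[0, 1\\]")

  set.seed(77)
  for (n in c(1, 7, 100, 2000)) {
    p <- runif(n)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("blacklisted NA p-values stay NA and do not enter the correction", {
  p <- c(0.01, NA, 0.02, 0.03, NA, 0.04)
  adj <- bh_adjust(p)
  expect_true(all(is.na(adj[c(2, 5)])))
  expect_equal(adj[!is.na(p)], oracle_bh(p[!is.na(p)]))
  expect_true(all(adj >= p, na.rm = TRUE))
})

test_that("enrichment scores follow the pseudo-counted log ratio", {
  expect_equal(enrichment_score(4, 4), 0)
  expect_equal(enrichment_score(7, 1, epsilon = 1), 2.0)
  expect_equal(enrichment_score(0, 0, epsilon = 1), 0)
  expect_true(is.finite(enrichment_score(0, 1000)))
  expect_error(enrichment_score(1, 1, epsilon = 0), "positive")
})

test_that("z-scores standardise by the NB variance with Poisson reduction", {
  expect_equal(nb_z_score(4, 4, 2), 0)
  expect_equal(nb_z_score(8, 4, Inf), 2.0)
  expect_equal(nb_z_score(8, 4, 4), 4 / sqrt(8))
  expect_true(is.na(nb_z_score(3, 0, 2)))
  expect_lt(nb_z_score(1, 4, 2), 0)
})

test_that("presence calls use strict thresholds and NA for blacklisted", {
  expect_equal(call_presence(2.0, 0.01), 1L)
  expect_equal(call_presence(1.5, 0.01), 0L)   # not strictly above
  expect_equal(call_presence(2.0, 0.25), 0L)   # not strictly below
  expect_equal(call_presence(2.0, 0.01, blacklisted = TRUE), NA_integer_)
  expect_equal(call_presence(c(2, 1), c(0.01, 0.01)), c(1L, 0L))
})

test_that("using the experiment as its own control suppresses all calls", {
  spec <- study_spec(seed = 31, enriched = c(5L, 50L), fold = 8)
  man <- simulate_dataset(spec, tempfile("selfctrl"), control = FALSE)
  sizes <- read_chrom_sizes(man$chrom_sizes)
  regions <- read_regions_bed(man$regions, 2000, sizes)
  calls <- call_regions(regions, man$experiment, sizes, control = man$experiment)

  lg <- attr(calls, "background")$lambda_g
  # any region at or below the global background cannot be called
  expect_true(all(calls$call[calls$y <= lg] == 0L))
  # self-modulation caps the score by the global-background ratio
  expect_true(all(calls$score <= enrichment_score(calls$y, lg) + 1e-9))
})

test_that("blacklisted regions carry NA through testing but keep counts", {
  spec <- study_spec(seed = 32)
  man <- simulate_dataset(spec, tempfile("bl"), control = FALSE)
  sizes <- read_chrom_sizes(man$chrom_sizes)
  regions <- read_regions_bed(man$regions, 2000, sizes)
  bl <- regions[3:4, c("chrom", "start", "end")]
  calls <- call_regions(regions, man$experiment, sizes, blacklist = bl)

  expect_true(all(calls$blacklisted[3:4]))
  expect_true(all(is.na(calls$p[3:4])))
  expect_true(all(is.na(calls$padj[3:4])))
  expect_true(all(is.na(calls$call[3:4])))
  expect_true(all(!is.na(calls$y[3:4])))
  expect_true(all(!is.na(calls$padj[-(3:4)])))
  # blacklist also removed those windows' tiles from background estimation
  expect_gte(attr(calls, "background")$n_tiles + 2L,
             nrow(tile_genome(sizes, 2000)))
})

test_that("call tables round-trip through the TSV writer", {
  spec <- study_spec(seed = 33, enriched = 10L, fold = 8)
  man <- simulate_dataset(spec, tempfile("tsv"))
  calls <- run_study(man, control = man$control)
  f <- tempfile(fileext = ".tsv")
  write_calls_tsv(calls, f)
  back <- read_calls_tsv(f)
  expect_equal(back$name, calls$name)
  expect_equal(back$call, calls$call)
  expect_equal(back$score, signif(calls$score, 6))
  expect_equal(back$padj, signif(calls$padj, 6))
})
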