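test_that("the saturation curve inverts consistently", {
  pr <- make_test_prior()
  pr$read_umi_curve <- c(0, 1000)
  expect_equal(mean_umi_from_reads(pr, 6907.755), 1000, tolerance = 1e-4)
  # inverse consistency over a range
  for (u in c(1.5, 10, 500, 20000))
    expect_equal(mean_umi_from_reads(pr, reads_from_mean_umi(pr, u)), u,
                 tolerance = 1e-9)
  # at reads = b0 the implied UMI is exp(0) = 1 (floor boundary)
  expect_equal(mean_umi_from_reads(pr, 1e-9 + 0), 1)
  pr$read_umi_curve <- c(5000, 1000)
  expect_warning(mean_umi_from_reads(pr, 100), "floored")
  pr$read_umi_curve <- c(0, -5)
  expect_error(mean_umi_from_reads(pr, 1000), "slope")
})

test_that("mixture_at_depth converts moments and closes the weights", {
  pr <- make_test_prior()                      # constant curves
  for (u in c(800, 1500, 4000)) {
    mix <- mixture_at_depth(pr, u)
    expect_equal(mix$p, c(0.25, 0.70, 0.05))
    # component 1: mean 0.3 sd 0.4 -> shape 0.5625 rate 1.875
    expect_equal(mix$shape[1], 0.3^2 / 0.4^2)
    expect_equal(mix$rate[1], 0.3 / 0.4^2)
  }
  # mean 2 sd 1 -> shape 4 rate 2
  pr$curves$mean1 <- c(2, 0); pr$curves$sd1 <- c(1, 0)
  mix <- mixture_at_depth(pr, 1000)
  expect_equal(mix$shape[1], 4)
  expect_equal(mix$rate[1], 2)
  # out-of-range curves error with the curve name
  pr$curves$mean1 <- c(-1, 0)
  expect_error(mixture_at_depth(pr, 1000), "mean1")
})

test_that("rank mapping matches the exponential closed form", {
  # single Exp(1) component: quantile(q) = -ln(1 - q); G = 100, rank 50
  mix <- gamma_mixture(c(0, 1, 0) + c(1e-15, 0, 1e-15),
                       shape = c(1, 1), rate = c(1, 1))
  expect_equal(rank_to_mean(mix, 50, 100), -log(0.495), tolerance = 1e-6)
  # half-rank correction: rank 1 -> q = 1 - 0.005
  expect_equal(rank_to_mean(mix, 1, 100), -log(0.005), tolerance = 1e-6)
  expect_error(rank_to_mean(mix, 101, 100), "rank")
})

test_that("rank mapping is monotone and returns 0 inside the zero mass", {
  mix <- make_truth_mixture()                   # p1 = 0.25
  mus <- rank_to_mean(mix, 1:1000, 1000)
  expect_true(all(diff(mus) <= 1e-9))
  # ranks deep enough that q <= p1 are exactly zero
  deep <- which(1 - (1:1000 - 0.5) / 1000 <= 0.25)
  expect_true(all(mus[deep] == 0))
  expect_true(all(mus[-deep] > 0))
})

test_that("mixture quantiles invert the mixture CDF", {
  mix <- make_truth_mixture()
  qs <- c(0.3, 0.5, 0.9, 0.99, 0.9999)
  xs <- mixture_quantile(mix, qs)
  expect_equal(powersc:::mixture_cdf(mix, xs), qs, tolerance = 1e-8)
})

test_that("dispersion trend evaluates and clamps", {
  pr <- make_test_prior()
  pr$dispersion_trend <- c(0.1, 2)
  expect_equal(dispersion_from_mean(pr, 4), 0.6)
  pr$dispersion_trend <- c(0.3, 0)
  expect_equal(dispersion_from_mean(pr, c(1, 10, 100)), rep(0.3, 3))
  pr$dispersion_trend <- c(-1, 0.5)
  expect_equal(dispersion_from_mean(pr, 10), 1e-8)  # negative -> clamp
  expect_error(dispersion_from_mean(pr, 0), "mu")
})

test_that("expression probability matches its closed form", {
  thr <- expression_threshold(min_count = 0, individual_fraction = 0.5)
  # mu' = 1, phi' = 0.02 (size 50): p = 1 - (50/51)^50
  p_is <- 1 - (50 / 51)^50
  expected <- 1 - pbinom(1, 2, p_is)
  expect_equal(gene_expression_probability(0.01, 2, 100, 2, thr), expected,
               tolerance = 1e-9)
  # mu = 0 -> 0 for any threshold
  expect_equal(gene_expression_probability(0, 1, 100, 10, test_threshold()), 0)
  # saturated gene -> 1
  expect_equal(gene_expression_probability(1e4, 0.1, 100, 10,
                                           test_threshold()), 1)
})

test_that("nonzero-cells mode follows the binomial composition", {
  thr <- expression_threshold(min_count = 3, individual_fraction = 0.5,
                              mode = "nonzero-cells")
  mu <- 0.05; phi <- 1.5; n_cs <- 60; n_s <- 8
  p0 <- 1 - (1 / (1 + phi * mu))^(1 / phi)
  p_is <- 1 - pbinom(2, n_cs, p0)
  expected <- 1 - pbinom(4, n_s, p_is)
  expect_equal(gene_expression_probability(mu, phi, n_cs, n_s, thr), expected,
               tolerance = 1e-12)
})

test_that("length-normalized thresholds rescale the count cutoff", {
  thr <- expression_threshold(min_count = 2, individual_fraction = 0.5,
                              length_normalized = TRUE)
  expect_error(gene_expression_probability(1, 0.5, 50, 4, thr), "gene_length")
  # 2 counts/kb at 3 kb = threshold 6
  ref <- expression_threshold(min_count = 6, individual_fraction = 0.5)
  expect_equal(gene_expression_probability(1, 0.5, 50, 4, thr,
                                           gene_length = 3000),
               gene_expression_probability(1, 0.5, 50, 4, ref))
})

test_that("expression probability is monotone in design and threshold", {
  mus <- c(0.02, 0.1, 0.5)
  for (mu in mus) {
    p_cells <- sapply(c(20, 50, 150, 400), function(nc)
      gene_expression_probability(mu, 1, nc, 8, test_threshold()))
    expect_true(all(diff(p_cells) >= -1e-12))
    p_thr <- sapply(c(0, 5, 20, 60), function(n)
      gene_expression_probability(mu, 1, 100, 8,
                                  expression_threshold(n, 0.5)))
    expect_true(all(diff(p_thr) <= 1e-12))
    p_k <- sapply(c(0.1, 0.3, 0.6, 0.9), function(k)
      gene_expression_probability(mu, 1, 100, 8,
                                  expression_threshold(10, k)))
    expect_true(all(diff(p_k) <= 1e-12))
  }
  p_mu <- gene_expression_probability(mus, 1, 100, 8, test_threshold())
  expect_true(all(diff(p_mu) >= 0))
})

test_that("the pseudobulk law matches summed per-cell draws", {
  # sum of n iid NB(mu, phi) is NB(n mu, phi / n): two-sample KS not
  # rejected at alpha = 0.01 over 10 seeds
  n <- 40; mu <- 0.8; phi <- 1.2
  rejections <- 0L
  for (s in 1:10) {
    set.seed(s)
    sums <- colSums(matrix(rnbinom(n * 400, size = 1 / phi, mu = mu), n))
    direct <- rnbinom(400, size = n / phi, mu = n * mu)
    pv <- suppressWarnings(ks.test(sums, direct)$p.value)
    rejections <- rejections + (pv < 0.01)
  }
  expect_lte(rejections, 1L)
})

test_that("expected expressed genes stay within bounds and degenerate cases", {
  pr <- make_test_prior(G = 400)
  ee <- expected_expressed_genes(pr, 100, 8, 10000, test_threshold())
  expect_true(ee$expected >= 0 && ee$expected <= 400)
  expect_length(ee$per_rank, 400)
  # all-zero mixture -> 0 expressed
  pr$curves$p1 <- c(0.98, 0)
  pr$p3_const <- 1e-9
  ee0 <- expected_expressed_genes(pr, 100, 8, 10000, test_threshold())
  expect_lt(ee0$expected, sum(ee$per_rank > 0))
})

test_that("E(E) agrees with the Monte-Carlo pass-count oracle", {
  pr <- make_test_prior(G = 250)
  thr <- test_threshold()
  ee <- expected_expressed_genes(pr, 100, 4, 10000, thr)
  orc <- mc_power_oracle("expression",
                         list(mu = ee$mu, phi = ee$phi, n_cs = 100, n_s = 4,
                              threshold = thr), reps = 150, seed = 31)
  expect_lt(abs(ee$expected - orc$estimate), 3 * max(orc$se, 1e-6))
})
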