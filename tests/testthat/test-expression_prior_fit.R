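test_that("size factors match the median-of-ratios closed form", {
  # two identical cells
  m <- cbind(c(3, 1, 4), c(3, 1, 4))
  expect_equal(estimate_size_factors(m, "median-ratio"), c(1, 1))
  # cell B = 2 x cell A, all genes positive: factors (1/sqrt 2, sqrt 2)
  m <- cbind(c(2, 4, 6), c(4, 8, 12))
  expect_equal(estimate_size_factors(m, "median-ratio"),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # geometric mean is 1
  set.seed(1)
  m <- matrix(rpois(600, 5), nrow = 30)
  for (meth in c("median-ratio", "poscounts")) {
    sf <- estimate_size_factors(m, meth)
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
  }
})

test_that("median-ratio fails informatively on all-sparse data", {
  m <- rbind(c(1, 0, 2), c(0, 3, 0), c(2, 0, 0))
  expect_error(estimate_size_factors(m, "median-ratio"), "poscounts")
  expect_silent(estimate_size_factors(m, "poscounts"))
})

test_that("per-gene NB parameters are recovered from simulated cells", {
  n_cells <- 2000
  set.seed(42)
  m <- matrix(rnbinom(50 * n_cells, size = 1 / 0.5, mu = 5), nrow = 50)
  ann <- data.frame(cell_id = paste0("c", seq_len(n_cells)),
                    sample_id = "s1", cell_type = "T")
  pc <- pilot_counts(m, paste0("g", 1:50), ann)
  fit <- fit_gene_nb(pc, "T", size_factors = rep(1, n_cells))
  expect_lt(median(abs(fit$fits$mu - 5) / 5), 0.05)
  expect_lt(median(abs(fit$fits$phi - 0.5) / 0.5), 0.15)
})

test_that("cell types below the cell floor are skipped with a warning", {
  sim <- simulate_pilot_counts(make_truth_mixture(), c(0.2, 1.5),
                               n_genes = 100, n_cells = 30, seed = 1)
  expect_warning(out <- fit_gene_nb(sim$counts, "synthetic"), "30 cells")
  expect_null(out)
})

test_that("constant genes get the clamped dispersion and leave the trend", {
  m <- rbind(rep(3L, 100), matrix(rpois(300, 4), nrow = 3))
  ann <- data.frame(cell_id = paste0("c", 1:100), sample_id = "s1",
                    cell_type = "T")
  pc <- pilot_counts(m, paste0("g", 1:4), ann)
  fit <- fit_gene_nb(pc, "T", size_factors = rep(1, 100))
  expect_equal(fit$fits$phi[1], 1e-8)
  expect_false(fit$fits$in_trend[1])
})

test_that("a constant dispersion trend recovers its level", {
  sim <- simulate_pilot_counts(make_truth_mixture(), c(0.4, 0),
                               n_genes = 1500, n_cells = 1500, seed = 7)
  fit <- fit_gene_nb(sim$counts, size_factors = rep(1, 1500))
  expect_lt(abs(fit$dispersion_trend[["a0"]] - 0.4) / 0.4, 0.1)
})

test_that("batched annotations produce one fit per batch", {
  sim <- simulate_pilot_counts(make_truth_mixture(), c(0.3, 1),
                               n_genes = 300, n_cells = 200, seed = 2)
  sim$counts$cell_annotations$batch <- rep(c("b1", "b2"), each = 100)
  fits <- fit_gene_nb(sim$counts, "synthetic", min_cells = 50)
  expect_named(fits, c("b1", "b2"))
  expect_equal(fits$b1$n_cells, 100)
})

test_that("gamma mixture EM recovers a known truth (scaled-down)", {
  truth <- gamma_mixture(c(0.3, 0.6, 0.1), shape = c(2, 16),
                         rate = c(4, 0.8), censor_point = 1e-3)
  set.seed(5)
  x <- sample_mixture_means(truth, 6000, censor = 1e-3)
  fit <- fit_gamma_mixture(x, 1000)
  expect_true(fit$converged)
  expect_equal(fit$p, truth$p, tolerance = 0.05)
  means <- fit$shape / fit$rate
  expect_equal(means, c(0.5, 20), tolerance = 0.1)
})

test_that("EM log-likelihood is non-decreasing on arbitrary inputs", {
  set.seed(9)
  for (i in 1:4) {
    x <- c(numeric(rpois(1, 150)),
           rgamma(600, shape = runif(1, 0.3, 3), rate = runif(1, 0.5, 4)),
           rgamma(40, shape = 8, rate = runif(1, 0.1, 0.5)))
    fit <- suppressWarnings(fit_gamma_mixture(x, 500, max_iter = 60))
    trace <- attr(fit, "loglik_trace")
    expect_true(all(diff(trace) >= -1e-6))
  }
})

test_that("degenerate and single-gamma inputs are handled", {
  fit0 <- suppressWarnings(fit_gamma_mixture(numeric(600), 100))
  expect_true(fit0$degenerate)
  expect_gt(fit0$p[1], 0.99)

  set.seed(3)
  x <- rgamma(8000, shape = 2, rate = 4)        # pure single gamma
  fit1 <- fit_gamma_mixture(x, 1000)
  expect_lt(fit1$p[3], 0.02)
  expect_lt(fit1$p[1], 0.02)
})

test_that("fitted mixture mean matches the empirical mean of gene means", {
  truth <- make_truth_mixture()
  set.seed(12)
  x <- sample_mixture_means(truth, 8000, censor = 1e-3)
  fit <- fit_gamma_mixture(x, 1000)
  fitted_mean <- mixture_moments(fit)$mean
  expect_equal(fitted_mean, mean(x), tolerance = 0.1)
})

test_that("depth curves interpolate two exact observations to machine precision", {
  mk <- function(umi) {
    m1 <- 0.1 + 2e-4 * umi; s1 <- 0.15 + 2.5e-4 * umi
    m2 <- 5 + 2e-3 * umi;   s2 <- 2 + 1e-3 * umi
    p1 <- 0.5 - 1e-4 * umi
    gamma_mixture(c(p1, 1 - p1 - 0.05, 0.05),
                  shape = c(m1^2 / s1^2, m2^2 / s2^2),
                  rate = c(m1 / s1^2, m2 / s2^2))
  }
  obs <- list(depth_observation("a", 5000, 800, mk(800), c(0.2, 1.5)),
              depth_observation("b", 12000, 2000, mk(2000), c(0.25, 1.4)))
  pr <- fit_depth_curves(obs, "t", G = 1000)
  expect_equal(pr$curves$mean1, c(0.1, 2e-4), tolerance = 1e-9)
  expect_equal(pr$curves$p1, c(0.5, -1e-4), tolerance = 1e-9)
  expect_equal(pr$p3_const, 0.05)
  expect_equal(pr$dispersion_trend, c(0.225, 1.45), tolerance = 1e-12)
  # saturation curve passes through both points
  expect_equal(reads_from_mean_umi(pr, 800), 5000, tolerance = 1e-6)
  expect_equal(reads_from_mean_umi(pr, 2000), 12000, tolerance = 1e-6)
})

test_that("noisy depth observations recover the underlying line", {
  set.seed(21)
  umis <- seq(500, 4000, length.out = 12)
  obs <- lapply(seq_along(umis), function(i) {
    u <- umis[i]
    m1 <- 0.1 + 2e-4 * u + rnorm(1, 0, 0.01)
    s1 <- 0.15 + 2.5e-4 * u
    m2 <- 5 + 2e-3 * u; s2 <- 2 + 1e-3 * u
    p1 <- max(0.5 - 1e-4 * u + rnorm(1, 0, 0.01), 0.02)
    depth_observation(paste0("o", i), 2000 + 12737 * log(u), u,
                      gamma_mixture(c(p1, 1 - p1 - 0.05, 0.05),
                                    shape = c(m1^2 / s1^2, m2^2 / s2^2),
                                    rate = c(m1 / s1^2, m2 / s2^2)),
                      c(0.2, 1.5))
  })
  pr <- fit_depth_curves(obs, "t", G = 1000)
  # slope within ~3 OLS standard errors of truth
  expect_equal(pr$curves$mean1[2], 2e-4, tolerance = 0.25)
  expect_equal(pr$curves$p1[2], -1e-4, tolerance = 0.25)
  expect_equal(pr$read_umi_curve[2], 12737, tolerance = 1e-6)
})

test_that("single observations degenerate to constant curves with a warning", {
  mix <- make_truth_mixture()
  obs <- list(depth_observation("only", 8000, 1500, mix, c(0.2, 1.5)))
  expect_warning(pr <- fit_depth_curves(obs, "t"), "single")
  expect_equal(pr$curves$mean1[2], 0)
})

test_that("p1 line evaluation is floored at 0.01", {
  pr <- make_test_prior()
  pr$curves$p1 <- c(0.004, 0)                  # would predict 0.004
  mix <- mixture_at_depth(pr, 2000)
  expect_equal(mix$p[1], 0.01)
  pr$curves$p1 <- c(-0.2, 0)
  mix <- mixture_at_depth(pr, 2000)
  expect_equal(mix$p[1], 0.01)
  expect_equal(sum(mix$p), 1)
})
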