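make_power_inputs <- function(G = 2000, n_genes = 40, seed = 11) {
  list(prior = make_test_prior(G = G),
       effects = simulate_de_priors(n_genes, 2, 1, rank_max = G, seed = seed),
       ctx = cell_type_context("synthetic", f_c = 0.1, n_u = 1500, n_cs = 150,
                               r_s = 20000, r_m = 16000),
       design = design_point(8, 1500, 20000),
       threshold = test_threshold())
}

test_that("the heterozygote-frequency threshold follows Hardy-Weinberg", {
  expect_equal(eqtl_population_threshold(0.05), 0.095)
  expect_equal(eqtl_population_threshold(0.5), 0.5)
  expect_lt(eqtl_population_threshold(1e-6), 3e-6)
  expect_error(eqtl_population_threshold(0.6), "maf")
  expect_error(eqtl_population_threshold(0), "maf")
})

test_that("detection power decomposes as expression x significance", {
  inp <- make_power_inputs()
  res <- overall_detection_power(inp$prior, inp$effects, inp$ctx, inp$design,
                                 inp$threshold, mt = "fdr")
  pg <- res$per_gene
  expect_true(all(pg$detection_power <=
                    pmin(pg$expression_probability, pg$significance_power) + 1e-12))
  expect_equal(res$overall_power, mean(pg$detection_power), tolerance = 1e-12)
  expect_true(all(pg$detection_power >= 0 & pg$detection_power <= 1))
  expect_gte(res$expected_expressed, res$expected_expressed_prior)
})

test_that("null effect sizes give power at the adjusted-alpha level", {
  inp <- make_power_inputs()
  eff0 <- effect_size_prior("de", data.frame(rank = seq(5, 200, by = 5),
                                             effect = 0))
  res <- overall_detection_power(inp$prior, eff0, inp$ctx, inp$design,
                                 inp$threshold, mt = "fwer", alpha = 0.05)
  pg <- res$per_gene
  pos <- pg$mu > 0
  expect_equal(pg$significance_power[pos],
               rep(res$alpha_adjusted, sum(pos)), tolerance = 1e-6)
})

test_that("with the expression filter disabled, overall power equals mean significance power", {
  inp <- make_power_inputs()
  # top-ranked genes plus a threshold any expressed gene passes
  eff <- effect_size_prior("de", data.frame(rank = 1:50,
                                            effect = rnorm(50, 2)))
  thr <- expression_threshold(min_count = 0, individual_fraction = 0,
                              individual_count = 1)
  res <- overall_detection_power(inp$prior, eff, inp$ctx, inp$design, thr,
                                 mt = "fwer")
  pg <- res$per_gene
  expect_equal(pg$expression_probability, rep(1, 50), tolerance = 1e-6)
  expect_equal(res$overall_power, mean(pg$significance_power),
               tolerance = 1e-4)
})

test_that("FDR mode is at least as powerful as FWER at equal nominal alpha", {
  for (seed in c(11, 23)) {
    inp <- make_power_inputs(seed = seed)
    p_fdr <- overall_detection_power(inp$prior, inp$effects, inp$ctx,
                                     inp$design, inp$threshold,
                                     mt = "fdr")$overall_power
    p_fwer <- overall_detection_power(inp$prior, inp$effects, inp$ctx,
                                      inp$design, inp$threshold,
                                      mt = "fwer")$overall_power
    expect_gte(p_fdr, p_fwer - 1e-9)
  }
})

test_that("overall power is monotone in n_s, n_c and r without budget coupling", {
  inp <- make_power_inputs()
  base <- list(n_s = 8, n_cs = 150, r_m = 16000)
  pw <- function(n_s = base$n_s, n_cs = base$n_cs, r_m = base$r_m) {
    ctx <- cell_type_context("synthetic", 0.1, n_cs * 10, n_cs, r_m / 0.8, r_m)
    des <- design_point(n_s, n_cs * 10, r_m / 0.8)
    overall_detection_power(inp$prior, inp$effects, ctx, des, inp$threshold,
                            mt = "fwer")$overall_power
  }
  expect_true(all(diff(sapply(c(6, 8, 12, 20), function(n) pw(n_s = n))) >= -1e-9))
  expect_true(all(diff(sapply(c(50, 150, 400), function(nc) pw(n_cs = nc))) >= -1e-9))
  expect_true(all(diff(sapply(c(8000, 16000, 32000), function(r) pw(r_m = r))) >= -1e-9))
})

test_that("eQTL detection power runs both branches through the rank means", {
  G <- 2000
  prior <- make_test_prior(G = G)
  # ranks spanning high and low expression so both branches are exercised
  eff <- effect_size_prior("eqtl", data.frame(rank = c(5, 50, 500, 1200),
                                              effect = c(0.3, 0.2, 0.3, 0.4)))
  ctx <- cell_type_context("synthetic", 0.1, 200, 20, 20000, 16000)
  des <- design_point(60, 2000, 20000)
  res <- overall_detection_power(prior, eff, ctx, des, test_threshold(),
                                 mt = "fwer", alpha = 0.05,
                                 sim_config = eqtl_sim_config(B = 100, seed = 3))
  expect_equal(res$alpha_adjusted,
               0.05 / (res$expected_expressed * 10), tolerance = 1e-9)
  expect_true(all(res$per_gene$detection_power >= 0 &
                    res$per_gene$detection_power <= 1))
})

test_that("threshold optimization returns the argmax of its own table", {
  inp <- make_power_inputs()
  opt <- optimize_expression_threshold(c(0, 5, 10, 20, 40), inp$prior,
                                       inp$effects, inp$ctx, inp$design,
                                       inp$threshold, mt = "fwer")
  expect_equal(opt$best_power, max(opt$table$overall_power))
  # re-scan reproduces the same argmax
  direct <- sapply(c(0, 5, 10, 20, 40), function(n) {
    thr <- inp$threshold; thr$min_count <- n
    overall_detection_power(inp$prior, inp$effects, inp$ctx, inp$design, thr,
                            mt = "fwer")$overall_power
  })
  expect_equal(opt$table$overall_power, unname(direct), tolerance = 1e-12)
  # single candidate returned unchanged
  one <- optimize_expression_threshold(7, inp$prior, inp$effects, inp$ctx,
                                       inp$design, inp$threshold, mt = "fwer")
  expect_equal(one$best_n, 7)
})

test_that("overall DE power matches an end-to-end simulation", {
  inp <- make_power_inputs(n_genes = 50, seed = 5)
  res <- overall_detection_power(inp$prior, inp$effects, inp$ctx, inp$design,
                                 inp$threshold, mt = "fdr", alpha = 0.05)
  pg <- res$per_gene
  a <- res$alpha_adjusted
  n_cs <- 150
  reps <- 200
  set.seed(99)
  det <- matrix(FALSE, nrow(pg), reps)
  for (r in seq_len(reps)) {
    for (i in seq_len(nrow(pg))) {
      mu <- pg$mu[i]
      if (mu == 0) next
      phi <- dispersion_from_mean(inp$prior, mu)
      rho <- 2^pg$effect[i]
      pb0 <- colSums(matrix(rnbinom(n_cs * 4, size = 1 / phi, mu = mu), n_cs))
      pb1 <- colSums(matrix(rnbinom(n_cs * 4, size = 1 / phi, mu = mu * rho),
                            n_cs))
      if (sum(c(pb0, pb1) > inp$threshold$min_count) <= 4) next
      det[i, r] <- powersc:::nb_wald_pvalue(pb0, pb1) < a
    }
  }
  pd <- rowMeans(det)
  se <- sqrt(sum(pd * (1 - pd)) / reps) / nrow(pg)
  expect_lt(abs(res$overall_power - mean(pd)), 3 * se + 0.01)
})
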