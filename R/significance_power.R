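#' Analytic power of the negative-binomial two-group rate-ratio test
#'
#' Power of the two-sided Wald test for the rate ratio `rho = 2^log2fc`
#' between two negative-binomial samples (pseudobulk per-individual
#' counts), with `n1` control samples and `theta * n1` treated samples.
#' The per-`n1`-unit variance under the alternative is
#' `V1 = (1/mu0 + phi) + (1/(rho*mu0) + phi)/theta`; the null variance
#' `V0` depends on the `variant`: 1 evaluates both groups at `mu0`, 2 at
#' the unweighted average of the two means, 3 (default) at the
#' constrained-ML common mean (the sample-size-weighted average).  Power
#' sums both rejection tails and is clipped to `[alpha * 1e-3, 1]`.
#'
#' @param n1 control-group sample size (>= 2); vectorized over `n1`,
#'   `mu0`, `phi`, `log2fc`, `alpha`.
#' @param group_ratio theta, ratio of treated to control sample counts.
#' @param mu0 control-group pseudobulk mean (> 0).
#' @param phi pseudobulk dispersion (> 0).
#' @param log2fc log2 fold change.
#' @param alpha two-sided significance level.
#' @param variant null-variance variant 1, 2 or 3.
#' @return power of the test.
#' @export
nb_de_power <- function(n1, group_ratio = 1, mu0, phi, log2fc, alpha = 0.05,
                        variant = 3) {
  if (any(group_ratio <= 0)) stopf("group_ratio must be > 0")
  if (any(n1 < 2)) stopf("n1 must be >= 2")
  if (any(mu0 <= 0) || any(phi <= 0)) stopf("mu0 and phi must be > 0")
  if (any(alpha <= 0 | alpha >= 1)) stopf("alpha must be in (0, 1)")
  theta <- group_ratio
  rho <- 2^log2fc
  lr <- log(rho)
  V1 <- (1 / mu0 + phi) + (1 / (rho * mu0) + phi) / theta
  mubar <- switch(as.character(variant),
                  "1" = mu0,
                  "2" = mu0 * (1 + rho) / 2,
                  "3" = mu0 * (1 + theta * rho) / (1 + theta),
                  stopf("variant must be 1, 2 or 3"))
  V0 <- (1 + 1 / theta) * (1 / mubar + phi)
  z <- qnorm(1 - alpha / 2)
  pw <- pnorm(lr * sqrt(n1 / V1) - z * sqrt(V0 / V1)) +
    pnorm(-lr * sqrt(n1 / V1) - z * sqrt(V0 / V1))
  pmin(pmax(pw, alpha * 1e-3), 1)
}

#' Analytic eQTL power (noncentral F)
#'
#' Power of the single-regressor F test of a genotype effect explaining a
#' fraction `R2` of expression variance in `n_s` samples: numerator df 1,
#' denominator df `n_s - 2`, effect size `f2 = R2/(1 - R2)`,
#' noncentrality `f2 * n_s`.
#'
#' @param n_s sample size (>= 4).
#' @param R2 coefficient of determination in `[0, 1)`; vectorized.
#' @param alpha significance level.
#' @return power of the F test.
#' @export
eqtl_power_analytic <- function(n_s, R2, alpha = 0.05) {
  if (any(n_s < 4)) stopf("n_s must be >= 4")
  if (any(R2 < 0 | R2 >= 1)) stopf("R2 must lie in [0, 1)")
  u <- 1
  v <- n_s - 2
  f2 <- R2 / (1 - R2)
  lambda <- f2 * (u + v + 1)
  crit <- qf(1 - alpha, u, v)
  pf(crit, u, v, ncp = lambda, lower.tail = FALSE)
}

#' Configuration of the count-level eQTL power simulation
#'
#' @param B simulation repetitions (default 100).
#' @param maf_range uniform allele-frequency bounds (default 0.1 to 0.9).
#' @param mean_switch pseudobulk mean below which [eqtl_power()] uses the
#'   simulation branch (default 5).
#' @param seed integer seed for the simulation branch.
#' @param dispersion_lookup optional lookup from
#'   [build_dispersion_lookup()].
#' @return An object of class `eqtl_sim_config`.
#' @export
eqtl_sim_config <- function(B = 100, maf_range = c(0.1, 0.9), mean_switch = 5,
                            seed = 1L, dispersion_lookup = NULL) {
  assert_scalar_num(B, "B", lower = 1)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] >= 1 ||
      maf_range[1] >= maf_range[2])
    stopf("maf_range must satisfy 0 < low < high < 1")
  assert_scalar_num(mean_switch, "mean_switch", lower = 0, strict_lower = TRUE)
  structure(list(B = B, maf_range = maf_range, mean_switch = mean_switch,
                 seed = seed, dispersion_lookup = dispersion_lookup),
            class = "eqtl_sim_config")
}

# sd of log(X + 1), X ~ NB(mu, dispersion phi), by pmf summation truncated
# at the 1 - 1e-10 quantile; the far tail (where log1p is nearly flat) is
# binned via CDF differences to keep the summation bounded
nb_log1p_sd <- function(mu, phi) {
  size <- 1 / phi
  kmax <- max(qnbinom(1 - 1e-10, size = size, mu = mu), 10)
  head_max <- min(kmax, 4095)
  ks <- 0:head_max
  w <- dnbinom(ks, size = size, mu = mu)
  lg <- log1p(ks)
  m1 <- sum(w * lg)
  m2 <- sum(w * lg^2)
  if (kmax > head_max) {
    breaks <- unique(round(exp(seq(log(head_max + 1), log(kmax + 1),
                                   length.out = 512L)))) - 1
    wt <- diff(pnbinom(c(head_max, breaks), size = size, mu = mu))
    mids <- log1p(sqrt((c(head_max + 1, breaks[-length(breaks)] + 1)) *
                         breaks))
    m1 <- m1 + sum(wt * mids)
    m2 <- m2 + sum(wt * mids^2)
  }
  sqrt(max(m2 - m1^2, 0))
}

#' Dispersion matching a target log-scale standard deviation
#'
#' Root-finds the NB dispersion `phi` such that the standard deviation of
#' `log(X + 1)` equals `sigma` at mean `mu`.  The sd is unimodal in `phi`
#' (at extreme overdispersion zeros dominate and the log-scale sd falls
#' again), so the root is sought on the increasing branch; if even the
#' Poisson limit exceeds `sigma` the minimum dispersion 1e-8 is returned,
#' and if `sigma` is unattainable the dispersion of the closest
#' achievable sd (the mode) is returned.
#'
#' @param mu NB mean (> 0).
#' @param sigma target standard deviation of `log(X + 1)`.
#' @return dispersion value.
#' @export
nb_dispersion_for_logsd <- function(mu, sigma) {
  f <- function(lphi) nb_log1p_sd(mu, exp(lphi)) - sigma
  lo <- log(1e-8)
  if (f(lo) >= 0) return(1e-8)
  pk <- optimize(function(lp) -nb_log1p_sd(mu, exp(lp)), c(lo, log(100)),
                 tol = 1e-3)$minimum
  if (f(pk) <= 0) return(exp(pk))
  exp(uniroot(f, c(lo, pk), tol = 1e-4)$root)
}

#' Precompute a dispersion lookup grid
#'
#' Bilinear-interpolation grid of [nb_dispersion_for_logsd()] over
#' `log(mu)` and `sigma`, used to speed up the eQTL simulation branch.
#'
#' @param mu_grid NB means (log-spaced recommended).
#' @param sd_grid target log-scale standard deviations.
#' @return An object of class `dispersion_lookup`.
#' @export
build_dispersion_lookup <- function(mu_grid = exp(seq(log(0.005), log(500),
                                                      length.out = 30)),
                                    sd_grid = seq(0.3, 1, length.out = 8)) {
  vals <- outer(mu_grid, sd_grid,
                Vectorize(function(m, s) log(nb_dispersion_for_logsd(m, s))))
  structure(list(log_mu = log(mu_grid), sd = sd_grid, log_phi = vals),
            class = "dispersion_lookup")
}

.powersc_cache <- new.env(parent = emptyenv())

# session-cached default lookup, built on first use
default_dispersion_lookup <- function() {
  if (is.null(.powersc_cache$dispersion_lookup))
    .powersc_cache$dispersion_lookup <- build_dispersion_lookup()
  .powersc_cache$dispersion_lookup
}

lookup_dispersion <- function(lookup, mu, sigma) {
  lx <- log(mu)
  if (is.null(lookup) || lx < min(lookup$log_mu) || lx > max(lookup$log_mu) ||
      sigma < min(lookup$sd) || sigma > max(lookup$sd))
    return(nb_dispersion_for_logsd(mu, sigma))
  ix <- findInterval(lx, lookup$log_mu, all.inside = TRUE)
  iy <- findInterval(sigma, lookup$sd, all.inside = TRUE)
  x1 <- lookup$log_mu[ix]; x2 <- lookup$log_mu[ix + 1L]
  y1 <- lookup$sd[iy]; y2 <- lookup$sd[iy + 1L]
  tx <- if (x2 > x1) (lx - x1) / (x2 - x1) else 0
  ty <- if (y2 > y1) (sigma - y1) / (y2 - y1) else 0
  z <- lookup$log_phi
  v <- (1 - tx) * (1 - ty) * z[ix, iy] + tx * (1 - ty) * z[ix + 1L, iy] +
    (1 - tx) * ty * z[ix, iy + 1L] + tx * ty * z[ix + 1L, iy + 1L]
  exp(v)
}

# deterministic Hardy-Weinberg genotype vector by largest-remainder rounding
hwe_genotypes <- function(n_s, fa) {
  probs <- c((1 - fa)^2, 2 * fa * (1 - fa), fa^2)
  raw <- probs * n_s
  counts <- floor(raw)
  rem <- n_s - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  rep(c(0, 1, 2), counts)
}

#' Simulation-based eQTL power for low-mean genes
#'
#' Count-level power estimate for genes whose pseudobulk mean is too
#' small for the normal-theory F test.  Each repetition draws an allele
#' frequency uniformly from `maf_range`, builds a deterministic
#' Hardy-Weinberg genotype vector, computes the genotype effect
#' `beta = sqrt(R2 / (2 fa (1 - fa)))` and residual sd
#' `sigma = sqrt(1 - R2)`, samples counts from NB with per-genotype mean
#' `exp(log(mu_c) + beta * g)` and dispersion chosen so the sd of
#' `log(X + 1)` equals `sigma`, and tests the slope of
#' `log(x + 1) ~ g`.  Power is the fraction of repetitions with
#' `p < alpha`.
#'
#' @param n_s sample size.
#' @param R2 coefficient of determination in `[0, 1)`.
#' @param alpha significance level.
#' @param mu_c pseudobulk mean count of the lower-expressed genotype.
#' @param config an [eqtl_sim_config()]; its `seed` makes the estimate
#'   reproducible.
#' @return power estimate in `[0, 1]`.
#' @export
eqtl_power_simulated <- function(n_s, R2, alpha = 0.05, mu_c,
                                 config = eqtl_sim_config()) {
  stopifnot(inherits(config, "eqtl_sim_config"))
  if (mu_c <= 0) stopf("mu_c must be > 0")
  if (R2 < 0 || R2 >= 1) stopf("R2 must lie in [0, 1)")
  if (is.null(config$dispersion_lookup))
    config$dispersion_lookup <- default_dispersion_lookup()
  run <- function() {
    sigma <- sqrt(1 - R2)
    hits <- logical(config$B)
    for (b in seq_len(config$B)) {
      for (try in 1:20) {
        fa <- runif(1, config$maf_range[1], config$maf_range[2])
        g <- hwe_genotypes(n_s, fa)
        if (var(g) > 0) break
      }
      if (var(g) == 0) { hits[b] <- NA; next }
      beta <- sqrt(R2 / (2 * fa * (1 - fa)))
      mu_g <- exp(log(mu_c) + beta * c(0, 1, 2))
      phi_g <- vapply(mu_g, function(m)
        lookup_dispersion(config$dispersion_lookup, m, sigma), numeric(1))
      idx <- g + 1L
      x <- rnbinom(n_s, size = 1 / phi_g[idx], mu = mu_g[idx])
      y <- log1p(x)
      # closed-form slope t test of y ~ g
      gc <- g - mean(g); yc <- y - mean(y)
      sxx <- sum(gc^2)
      bhat <- sum(gc * yc) / sxx
      rss <- sum((yc - bhat * gc)^2)
      se <- sqrt(rss / (n_s - 2) / sxx)
      tstat <- if (se > 0) bhat / se else 0
      hits[b] <- 2 * pt(-abs(tstat), df = n_s - 2) < alpha
    }
    mean(hits, na.rm = TRUE)
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

#' eQTL power with automatic branch selection
#'
#' Uses the analytic noncentral-F power when the pseudobulk mean `mu_c`
#' is at least `config$mean_switch` (default 5) and the count-level
#' simulation below it, where the normal-theory test overstates power.
#'
#' @inheritParams eqtl_power_simulated
#' @return power estimate.
#' @export
eqtl_power <- function(n_s, R2, alpha = 0.05, mu_c,
                       config = eqtl_sim_config()) {
  if (mu_c < config$mean_switch)
    eqtl_power_simulated(n_s, R2, alpha, mu_c, config)
  else
    eqtl_power_analytic(n_s, R2, alpha)
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha' = alpha / (expected_tests * n_indep_snps)`: one test per
#' expected expressed gene, times the assumed number of independent SNPs
#' per gene for eQTL scans (10 in genome-wide cis analyses).
#'
#' @param expected_tests expected number of expressed genes tested.
#' @param n_indep_snps independent SNPs per gene (default 1).
#' @param alpha nominal family-wise error rate.
#' @return adjusted per-test threshold.
#' @export
bonferroni_alpha <- function(expected_tests, n_indep_snps = 1, alpha = 0.05) {
  if (any(expected_tests <= 0)) stopf("expected_tests must be > 0")
  if (any(n_indep_snps < 1)) stopf("n_indep_snps must be >= 1")
  alpha / (expected_tests * n_indep_snps)
}

#' Invert a target FDR to a raw p-value threshold
#'
#' Solves `FDR(a') = m0 * a' / (m0 * a' + r1(a')) = target` for the raw
#' threshold `a'`, where `m0` is the expected number of expressed
#' non-prior genes (true nulls) and `r1(a')` the expected number of
#' significant prior genes, i.e. the sum over prior genes of expression
#' probability times power at `a'`.  Root found by bisection on
#' `log(a')` over `[1e-12, 1]`.
#'
#' @param r1_fn function of `a'` returning the expected number of
#'   significant prior genes.
#' @param m0 expected number of expressed true-null genes.
#' @param target_fdr desired FDR in (0, 1).
#' @param tol absolute tolerance on the achieved FDR.
#' @return list with `alpha_adj`, `achieved_fdr`, `status`
#'   (`"ok"`, `"m0-zero"`, `"no-solution"` or `"below-target"`).
#' @export
fdr_alpha <- function(r1_fn, m0, target_fdr, tol = 1e-6) {
  if (target_fdr <= 0 || target_fdr >= 1) stopf("target_fdr must be in (0,1)")
  if (m0 < 0) stopf("m0 must be >= 0")
  if (m0 == 0)
    return(list(alpha_adj = target_fdr, achieved_fdr = 0, status = "m0-zero"))
  fdr_at <- function(a) {
    r1 <- r1_fn(a)
    if (r1 <= 0) return(1)
    m0 * a / (m0 * a + r1)
  }
  if (r1_fn(1 - 1e-9) <= 0)
    return(list(alpha_adj = NA_real_, achieved_fdr = NA_real_,
                status = "no-solution"))
  lo <- log(1e-12); hi <- log(1 - 1e-9)
  f_hi <- fdr_at(exp(hi))
  if (f_hi < target_fdr)
    return(list(alpha_adj = 1, achieved_fdr = f_hi, status = "below-target"))
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    fm <- fdr_at(exp(mid))
    if (fm > target_fdr) hi <- mid else lo <- mid
    if (hi - lo < 1e-13) break
  }
  a <- exp((lo + hi) / 2)
  achieved <- fdr_at(a)
  list(alpha_adj = a, achieved_fdr = achieved,
       status = if (abs(achieved - target_fdr) < tol) "ok" else "not-converged")
}
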