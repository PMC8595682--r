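#' Simulate a ranked DE effect-size prior
#'
#' Log2 fold-change magnitudes drawn from Normal(`lfc_mean`, `lfc_sd`)
#' with a random sign, ranks sampled uniformly without replacement from
#' `1..rank_max`.  Defaults reproduce the high-effect-size scenario
#' (250 DE genes, mean 2, sd 1, ranks over the first 10,000 genes).
#'
#' @param n_genes number of DE genes (default 250).
#' @param lfc_mean,lfc_sd mean and sd of the log2 fold-change magnitudes.
#' @param rank_max ranks are sampled from `1..rank_max`.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return An [effect_size_prior()] of kind `"de"`.
#' @export
simulate_de_priors <- function(n_genes = 250, lfc_mean = 2, lfc_sd = 1,
                               rank_max = 10000, seed = 1L) {
  if (n_genes > rank_max) stopf("n_genes must be <= rank_max")
  withr::with_seed(seed, {
    mags <- rnorm(n_genes, lfc_mean, lfc_sd)
    signs <- sample(c(-1, 1), n_genes, replace = TRUE)
    ranks <- sample.int(rank_max, n_genes)
    effect_size_prior("de", data.frame(rank = ranks, effect = signs * mags))
  })
}

#' Simulate a ranked eQTL effect-size prior
#'
#' Z scores drawn from Normal(`z_mean`, `z_sd`) truncated below at
#' `z_mean` (rejection sampling), transformed by the inverse Fisher
#' transformation `R = tanh(Z)`; `R^2` is recorded.  Defaults reproduce
#' the high-effect-size scenario (2000 eQTL genes, mean 0.5, sd 0.2).
#'
#' @param n_genes number of eQTL genes (default 2000).
#' @param z_mean,z_sd mean and sd of the (untruncated) Z distribution.
#' @param rank_max ranks are sampled from `1..rank_max`.
#' @param seed integer seed.
#' @return An [effect_size_prior()] of kind `"eqtl"`.
#' @export
simulate_eqtl_priors <- function(n_genes = 2000, z_mean = 0.5, z_sd = 0.2,
                                 rank_max = 10000, seed = 1L) {
  if (n_genes > rank_max) stopf("n_genes must be <= rank_max")
  withr::with_seed(seed, {
    z <- numeric(0)
    while (length(z) < n_genes) {
      cand <- rnorm(2 * n_genes, z_mean, z_sd)
      z <- c(z, cand[cand >= z_mean])
    }
    z <- z[seq_len(n_genes)]
    r2 <- tanh(z)^2
    ranks <- sample.int(rank_max, n_genes)
    effect_size_prior("eqtl", data.frame(rank = ranks, effect = r2))
  })
}

#' Simulate pilot counts from a known generative truth
#'
#' Inverts the generative model: per-gene means drawn from the (optionally
#' censored) gamma mixture, dispersions from the trend
#' `phi(mu) = a0 + a1/mu`, counts i.i.d. negative binomial per cell.
#' Cells are assigned round-robin to samples.
#'
#' @param mixture a [gamma_mixture()] truth.
#' @param dispersion_trend `c(a0, a1)` truth.
#' @param n_genes,n_cells,n_samples dimensions of the pilot.
#' @param seed integer seed.
#' @param censor set drawn means below `1/n_cells` to zero (default TRUE,
#'   emulating undetectably low expression).
#' @param cell_type label written into the annotation.
#' @return list with `counts` (a [pilot_counts()]) and `truth`
#'   (per-gene `mu`, `phi` actually used).
#' @export
simulate_pilot_counts <- function(mixture, dispersion_trend, n_genes, n_cells,
                                  n_samples = 1, seed = 1L, censor = TRUE,
                                  cell_type = "synthetic") {
  withr::with_seed(seed, {
    if (n_genes == 0) {
      mu <- numeric(0)
    } else {
      mu <- sample_mixture_means(mixture, n_genes,
                                 censor = if (censor) 1 / n_cells else NULL)
    }
    phi <- rep(1e-8, n_genes)
    pos <- mu > 0
    phi[pos] <- dispersion_from_mean(dispersion_trend, mu[pos])
    m <- matrix(0L, n_genes, n_cells)
    if (any(pos)) {
      m[pos, ] <- matrix(rnbinom(sum(pos) * n_cells,
                                 size = rep(1 / phi[pos], n_cells),
                                 mu = rep(mu[pos], n_cells)),
                         nrow = sum(pos))
    }
    ann <- data.frame(cell_id = paste0("cell", seq_len(n_cells)),
                      sample_id = paste0("s", rep_len(seq_len(n_samples), n_cells)),
                      cell_type = cell_type)
    list(counts = pilot_counts(m, paste0("gene", seq_len(n_genes),
                                         recycle0 = TRUE), ann),
         truth = data.frame(mu = mu, phi = phi))
  })
}

# fast two-group NB Wald test: group means are the ML estimates of a
# log-link NB model; common dispersion by Cox-Reid-adjusted profile
# likelihood (the adjustment removes the small-sample downward bias of
# plain ML dispersion, which would otherwise inflate rejection rates)
nb_wald_pvalue <- function(x0, x1) {
  m0 <- mean(x0); m1 <- mean(x1)
  n0 <- length(x0); n1 <- length(x1)
  if (m0 == 0 || m1 == 0) return(1)
  nll <- function(lphi) {
    phi <- exp(lphi)
    size <- 1 / phi
    ll <- sum(dnbinom(x0, size = size, mu = m0, log = TRUE)) +
      sum(dnbinom(x1, size = size, mu = m1, log = TRUE))
    cr <- 0.5 * (log(n0 * m0 / (1 + phi * m0)) +
                   log(n1 * m1 / (1 + phi * m1)))
    -(ll - cr)
  }
  phi <- exp(optimize(nll, c(-12, 6))$minimum)
  v <- (1 / m0 + phi) / n0 + (1 / m1 + phi) / n1
  stat <- log(m1 / m0)^2 / v
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Monte-Carlo power oracles
#'
#' Simulation-based estimates used to validate the analytic power
#' formulas; all are pure functions of `(scenario, reps, seed)`.
#'
#' * `mode = "de"`: two-group pseudobulk NB data
#'   (`scenario: n1, theta, mu0, phi, log2fc, alpha`), ML NB Wald test
#'   per repetition, power = fraction significant.
#' * `mode = "eqtl"`: normal-theory regression
#'   (`scenario: n_s, R2, alpha`), slope t test on simulated
#'   `y = beta * x + e` with the stated `R2`, evaluated in a vectorized
#'   closed form.
#' * `mode = "expression"`: per-gene pass frequency of the expressed-gene
#'   threshold (`scenario: mu, phi (vectors), n_cs, n_s, threshold`),
#'   with honest per-cell count summation into pseudobulk.
#'
#' @param mode `"de"`, `"eqtl"` or `"expression"`.
#' @param scenario named list, see above.
#' @param reps repetitions (>= 100 for power modes).
#' @param seed integer seed.
#' @return list with `estimate`, `se` and mode-specific extras
#'   (`per_gene` pass probabilities for `"expression"`).
#' @export
mc_power_oracle <- function(mode = c("de", "eqtl", "expression"), scenario,
                            reps = 1000, seed = 1L) {
  mode <- match.arg(mode)
  withr::with_seed(seed, {
    if (mode == "de") {
      n1 <- scenario$n1
      n2 <- round(n1 * (scenario$theta %||% 1))
      mu0 <- scenario$mu0
      mu1 <- mu0 * 2^scenario$log2fc
      size <- 1 / scenario$phi
      hits <- vapply(seq_len(reps), function(i) {
        x0 <- rnbinom(n1, size = size, mu = mu0)
        x1 <- rnbinom(n2, size = size, mu = mu1)
        nb_wald_pvalue(x0, x1) < scenario$alpha
      }, logical(1))
      p <- mean(hits)
      list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
    } else if (mode == "eqtl") {
      n <- scenario$n_s
      beta <- sqrt(scenario$R2)
      sig <- sqrt(1 - scenario$R2)
      x <- matrix(rnorm(n * reps), n, reps)
      y <- beta * x + sig * matrix(rnorm(n * reps), n, reps)
      xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
      sxx <- colSums(xc^2)
      bhat <- colSums(xc * yc) / sxx
      rss <- colSums(yc^2) - bhat^2 * sxx
      se <- sqrt(rss / (n - 2) / sxx)
      tt <- bhat / se
      hits <- 2 * pt(-abs(tt), df = n - 2) < scenario$alpha
      p <- mean(hits)
      list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
    } else {
      mu <- scenario$mu; phi <- scenario$phi
      n_cs <- scenario$n_cs; n_s <- scenario$n_s
      thr <- scenario$threshold
      G <- length(mu)
      pos <- which(mu > 0)
      kk <- if (is.null(thr$individual_count))
        floor(thr$individual_fraction * n_s) else thr$individual_count - 1
      pass <- matrix(FALSE, G, reps)
      size <- 1 / phi[pos]
      for (rep in seq_len(reps)) {
        npass <- matrix(0L, length(pos), n_s)
        for (s in seq_len(n_s)) {
          cellcounts <- matrix(rnbinom(length(pos) * n_cs,
                                       size = rep(size, n_cs),
                                       mu = rep(mu[pos], n_cs)),
                               nrow = length(pos))
          if (thr$mode == "pseudobulk-count") {
            npass[, s] <- as.integer(rowSums(cellcounts) > thr$min_count)
          } else {
            npass[, s] <- as.integer(rowSums(cellcounts > 0) >=
                                       max(thr$min_count, 1))
          }
        }
        pass[pos, rep] <- rowSums(npass) > kk
      }
      per_gene <- rowMeans(pass)
      est <- sum(per_gene)
      se <- sqrt(sum(per_gene * (1 - per_gene)) / reps)
      list(estimate = est, se = se, per_gene = per_gene, reps = reps)
    }
  })
}
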