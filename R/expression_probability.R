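nb_cdf <- function(q, mu, phi) {
  # regularized-incomplete-beta NB CDF via pnbinom; Poisson limit for tiny phi
  size <- 1 / phi
  ifelse(phi < 1e-12, stats::ppois(q, mu), pnbinom(q, size = size, mu = mu))
}

#' Probability that one gene passes the expressed-gene threshold
#'
#' Under the pseudobulk model the per-individual sum of `n_cs` i.i.d.
#' NB(`mu`, `phi`) cell counts is NB(`n_cs * mu`, `phi / n_cs`); the
#' per-individual pass probability is the NB upper tail at the count
#' threshold, and the across-individual step is a binomial upper tail over
#' the `n_s` individuals.  In `"nonzero-cells"` mode the per-individual
#' event is instead "at least `min_count` cells with a nonzero count".
#'
#' @param mu per-cell negative-binomial mean(s); vectorized.
#' @param phi per-cell dispersion(s) (> 0 wherever `mu > 0`).
#' @param n_cs cells of the cell type per individual.
#' @param n_s number of individuals.
#' @param threshold an [expression_threshold()].
#' @param gene_length gene length(s) in bp; required when the threshold is
#'   length-normalized.
#' @return probability vector `P(i in E)`.
#' @export
gene_expression_probability <- function(mu, phi, n_cs, n_s, threshold,
                                        gene_length = NULL) {
  stopifnot(inherits(threshold, "expression_threshold"))
  assert_scalar_num(n_cs, "n_cs", lower = 1)
  assert_scalar_num(n_s, "n_s", lower = 1)
  mu <- as.numeric(mu)
  phi <- rep_len(as.numeric(phi), length(mu))
  n_thr <- resolve_count_threshold(threshold, length(mu), gene_length)
  p_is <- per_individual_pass_prob(mu, phi, n_cs, threshold, n_thr)
  kk <- threshold_successes(threshold, n_s)
  ifelse(p_is >= 1, 1, 1 - pbinom(kk, size = n_s, prob = p_is))
}

# P(one individual's signal exceeds the threshold) per gene
per_individual_pass_prob <- function(mu, phi, n_cs, threshold, n_thr) {
  p_is <- numeric(length(mu))
  posm <- mu > 0
  if (any(posm)) {
    if (threshold$mode == "pseudobulk-count") {
      mu_p <- n_cs * mu[posm]
      phi_p <- phi[posm] / n_cs
      p_is[posm] <- 1 - nb_cdf(n_thr[posm], mu_p, phi_p)
    } else {
      p0 <- 1 - nb_cdf(0, mu[posm], phi[posm])      # P(cell count > 0)
      m <- pmax(n_thr[posm], 1)
      p_is[posm] <- 1 - pbinom(m - 1, size = n_cs, prob = p0)
    }
  }
  p_is
}

# number of individuals that must be exceeded (strict) by the criterion
threshold_successes <- function(threshold, n_s) {
  if (is.null(threshold$individual_count))
    floor(threshold$individual_fraction * n_s)
  else threshold$individual_count - 1
}

resolve_count_threshold <- function(threshold, n, gene_length) {
  if (threshold$length_normalized) {
    if (is.null(gene_length))
      stopf("length-normalized threshold requires gene_length")
    ceiling(threshold$min_count * rep_len(gene_length, n) / 1000)
  } else {
    rep_len(threshold$min_count, n)
  }
}

#' Expression probability of a DE gene across two groups
#'
#' Like [gene_expression_probability()], but the treated group's mean is
#' shifted by the rate ratio `rho`, so a strongly regulated gene near the
#' count threshold can pass through either group: the pass count is the
#' sum of two binomials (control at `mu`, treated at `rho * mu`).  At
#' `rho = 1` this reduces exactly to the single-mean form.
#'
#' @param mu control-group per-cell mean(s).
#' @param rho rate ratio(s) of treated to control means.
#' @param phi per-cell dispersion(s).
#' @param n_cs cells of the type per individual.
#' @param n1,n2 control and treated sample counts.
#' @param threshold an [expression_threshold()].
#' @param gene_length gene length(s) for length-normalized thresholds.
#' @return probability vector `P(i in E)`.
#' @export
two_group_expression_probability <- function(mu, rho, phi, n_cs, n1, n2,
                                             threshold, gene_length = NULL) {
  stopifnot(inherits(threshold, "expression_threshold"))
  mu <- as.numeric(mu)
  rho <- rep_len(as.numeric(rho), length(mu))
  phi <- rep_len(as.numeric(phi), length(mu))
  n_thr <- resolve_count_threshold(threshold, length(mu), gene_length)
  p0 <- per_individual_pass_prob(mu, phi, n_cs, threshold, n_thr)
  p1 <- per_individual_pass_prob(mu * rho, phi, n_cs, threshold, n_thr)
  kk <- threshold_successes(threshold, n1 + n2)
  # P(B0 + B1 > kk), B0 ~ Bin(n1, p0), B1 ~ Bin(n2, p1)
  out <- numeric(length(mu))
  for (j in 0:n1) {
    out <- out + stats::dbinom(j, n1, p0) *
      (1 - pbinom(kk - j, n2, p1))
  }
  pmin(pmax(out, 0), 1)
}

#' Expected number of expressed genes under a design
#'
#' Evaluates the expression probability over ranks `1..G`: the prior's
#' mixture is instantiated at the mean UMI implied by the mapped read
#' depth, ranks map to per-cell means through the mixture quantiles, the
#' dispersion trend supplies `phi`, and each gene's pass probability is
#' summed.
#'
#' @param prior an [expression_prior()].
#' @param n_cs cells of the cell type per individual.
#' @param n_s number of individuals.
#' @param mapped_read_depth transcriptome-mapped reads per cell.
#' @param threshold an [expression_threshold()].
#' @param gene_length average gene length (bp) used for all ranks when the
#'   threshold is length-normalized (default 5000).
#' @return list with `expected` (E(E)), `per_rank` probabilities, `mu` and
#'   `phi` per rank, the instantiated `mixture` and `mean_umi`.
#' @export
expected_expressed_genes <- function(prior, n_cs, n_s, mapped_read_depth,
                                     threshold, gene_length = 5000) {
  umi <- mean_umi_from_reads(prior, mapped_read_depth)
  mix <- mixture_at_depth(prior, umi)
  G <- as.integer(prior$G)
  ranks <- seq_len(G)
  mu <- rank_to_mean(mix, ranks, G)
  phi <- rep(1, G)
  pos <- mu > 0
  if (any(pos))
    phi[pos] <- dispersion_from_mean(prior, mu[pos], depth = mapped_read_depth)
  glen <- if (threshold$length_normalized) rep(gene_length, G) else NULL
  probs <- gene_expression_probability(mu, phi, n_cs, n_s, threshold, glen)
  list(expected = sum(probs), per_rank = probs, mu = mu, phi = phi,
       mixture = mix, mean_umi = umi)
}
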