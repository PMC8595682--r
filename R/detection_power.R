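#' Across-individual threshold implied by a minor allele frequency
#'
#' For eQTL studies the smaller genotype group of interest is the
#' heterozygotes; requiring expression in at least that share of
#' individuals gives the fraction `k = 2 * maf * (1 - maf)` under
#' Hardy-Weinberg equilibrium.
#'
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @return fraction of individuals `k`.
#' @export
eqtl_population_threshold <- function(maf) {
  if (any(maf <= 0 | maf > 0.5)) stopf("maf must lie in (0, 0.5]")
  2 * maf * (1 - maf)
}

#' Overall detection power of a design for a DE or eQTL study
#'
#' Composes expression probability and significance power per prior gene
#' (Eq.: detection power = expression probability x test power, the two
#' being conditionally independent given the gene's mean) and averages
#' over the prior genes.  The multiple-testing-adjusted threshold is
#' either Bonferroni on the expected number of expressed genes (times
#' `n_indep_snps` for eQTL) or the FDR-inverted raw threshold with
#' `m0 = E(E) - E(E_prior)` true nulls.
#'
#' @param prior an [expression_prior()].
#' @param effects an [effect_size_prior()].
#' @param ctx a [cell_type_context()] (from [doublet_adjust()] /
#'   [derive_context()] or given directly).
#' @param design a [design_point()].
#' @param threshold an [expression_threshold()].
#' @param mt multiple-testing scheme, `"fdr"` or `"fwer"`.
#' @param alpha nominal adjusted significance level (default 0.05).
#' @param n_indep_snps independent SNPs per gene for eQTL FWER adjustment
#'   (default 10; forced to 1 for DE).
#' @param nb_variant null-variance variant for [nb_de_power()].
#' @param sim_config an [eqtl_sim_config()] for low-mean eQTL genes.
#' @param gene_length_default average gene length (bp) for
#'   length-normalized thresholds when the prior table has none.
#' @return An object of class `power_result`: list with `per_gene`
#'   (data.frame `rank`, `effect`, `mu`, `expression_probability`,
#'   `significance_power`, `detection_power`), `expected_expressed`,
#'   `expected_expressed_prior`, `alpha_adjusted`, `m0`, `r1`,
#'   `overall_power`, plus the inputs.
#' @export
overall_detection_power <- function(prior, effects, ctx, design, threshold,
                                    mt = c("fdr", "fwer"), alpha = 0.05,
                                    n_indep_snps = if (effects$kind == "eqtl") 10 else 1,
                                    nb_variant = 3,
                                    sim_config = eqtl_sim_config(),
                                    gene_length_default = 5000) {
  mt <- match.arg(mt)
  stopifnot(inherits(prior, "expression_prior"),
            inherits(effects, "effect_size_prior"),
            inherits(ctx, "cell_type_context"),
            inherits(design, "design_point"),
            inherits(threshold, "expression_threshold"))
  if (!nrow(effects$records)) stopf("empty effect-size prior")
  if (threshold$length_normalized &&
      prior$technology != "read-plate-smartseq2" &&
      is.null(effects$records$gene_length))
    stopf("length-normalized threshold without gene lengths for a UMI prior")
  kind <- effects$kind
  n_s <- design$n_s
  if (kind == "de" && n_s < 2) stopf("DE designs need n_s >= 2")
  n_cs <- max(floor(ctx$n_cs), 1)

  ee <- expected_expressed_genes(prior, n_cs, n_s, ctx$r_m, threshold,
                                 gene_length = gene_length_default)
  EE <- ee$expected

  rec <- effects$records
  G <- as.integer(prior$G)
  if (any(rec$rank > G)) stopf("effect prior ranks exceed G = %d", G)
  mu <- rank_to_mean(ee$mixture, rec$rank, G)
  phi <- rep(1, nrow(rec))
  pos <- mu > 0
  if (any(pos)) phi[pos] <- dispersion_from_mean(prior, mu[pos], depth = ctx$r_m)
  glen <- if (threshold$length_normalized)
    rec$gene_length %||% rep(gene_length_default, nrow(rec)) else NULL
  if (kind == "de") {
    # the treated group's mean carries the fold change, so a regulated
    # gene near the count threshold can qualify through either group
    theta0 <- design$group_ratio
    n1_f <- max(floor(n_s / (1 + theta0)), 2)
    p_expr <- two_group_expression_probability(mu, 2^rec$effect, phi, n_cs,
                                               n1_f, n_s - n1_f, threshold,
                                               glen)
  } else {
    p_expr <- gene_expression_probability(mu, phi, n_cs, n_s, threshold, glen)
  }
  EE_prior <- sum(p_expr)

  # significance power at a given raw threshold, vectorized over genes
  if (kind == "de") {
    theta <- design$group_ratio
    n1 <- max(floor(n_s / (1 + theta)), 2)
    theta_eff <- (n_s - n1) / n1
    mu_pb <- n_cs * mu
    phi_pb <- phi / n_cs
    sig_power <- function(a) {
      pw <- numeric(length(mu))
      pw[pos] <- nb_de_power(n1, theta_eff, mu_pb[pos], phi_pb[pos],
                             rec$effect[pos], a, variant = nb_variant)
      pw
    }
  } else {
    mu_pb <- n_cs * mu
    sig_power <- function(a) {
      pw <- numeric(length(mu))
      for (i in which(pos))
        pw[i] <- eqtl_power(n_s, rec$effect[i], a, mu_pb[i], sim_config)
      pw
    }
  }

  m0 <- max(EE - EE_prior, 0)
  if (mt == "fwer") {
    a_adj <- bonferroni_alpha(max(EE, 1), n_indep_snps, alpha)
    r1 <- sum(p_expr * sig_power(a_adj))
    fdr_status <- NA_character_
  } else {
    sol <- fdr_alpha(function(a) sum(p_expr * sig_power(a)), m0, alpha)
    fdr_status <- sol$status
    a_adj <- if (is.na(sol$alpha_adj)) alpha / max(EE, 1) else sol$alpha_adj
    r1 <- sum(p_expr * sig_power(a_adj))
  }

  pw <- sig_power(a_adj)
  per_gene <- data.frame(rank = rec$rank, effect = rec$effect, mu = mu,
                         expression_probability = p_expr,
                         significance_power = pw,
                         detection_power = p_expr * pw)
  structure(list(per_gene = per_gene,
                 expected_expressed = EE,
                 expected_expressed_prior = EE_prior,
                 alpha_adjusted = a_adj, m0 = m0, r1 = r1,
                 overall_power = mean(per_gene$detection_power),
                 mt = mt, alpha = alpha, kind = kind,
                 fdr_status = fdr_status,
                 design = design, ctx = ctx),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(paste0("power_result (%s, %s): overall detection power %.4f\n",
                     "  E(expressed) = %.1f, E(expressed prior) = %.1f, ",
                     "alpha' = %.3g\n"),
              x$kind, x$mt, x$overall_power, x$expected_expressed,
              x$expected_expressed_prior, x$alpha_adjusted))
  invisible(x)
}

#' Choose the expression threshold maximizing overall power
#'
#' Exhaustively evaluates [overall_detection_power()] at each candidate
#' per-individual count threshold and returns the argmax (ties broken
#' toward the larger, more conservative threshold).
#'
#' @param candidate_counts integer candidate values of `min_count`.
#' @param prior,effects,ctx,design,threshold,... passed through to
#'   [overall_detection_power()]; `threshold` provides the mode and
#'   across-individual settings shared by all candidates.
#' @return list with `best_n`, `best_power` and `table` (one row per
#'   candidate).
#' @export
optimize_expression_threshold <- function(candidate_counts, prior, effects,
                                          ctx, design, threshold, ...) {
  if (!length(candidate_counts)) stopf("no candidate thresholds")
  powers <- vapply(candidate_counts, function(n) {
    thr <- threshold
    thr$min_count <- n
    overall_detection_power(prior, effects, ctx, design, thr, ...)$overall_power
  }, numeric(1))
  tab <- data.frame(min_count = candidate_counts, overall_power = powers)
  best <- max(powers)
  idx <- which(powers >= best - 1e-12)
  best_n <- max(candidate_counts[idx])
  list(best_n = best_n, best_power = powers[match(best_n, candidate_counts)],
       table = tab)
}
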