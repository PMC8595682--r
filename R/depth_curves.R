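#' One sequencing-depth observation of a cell type
#'
#' A fitted snapshot of a cell type at one read depth (a run or a
#' subsampled run): the mean mapped reads and mean UMI per cell, the gamma
#' mixture fitted at this depth and the dispersion-trend parameters.
#'
#' @param label run / subsample identifier.
#' @param mean_mapped_reads mean transcriptome-mapped reads per cell.
#' @param mean_umi mean UMI count per cell (`<= mean_mapped_reads`).
#' @param mixture the [gamma_mixture()] fitted at this depth.
#' @param dispersion_fit `c(a0, a1)` of `phi(mu) = a0 + a1/mu` at this
#'   depth.
#' @return An object of class `depth_observation`.
#' @export
depth_observation <- function(label, mean_mapped_reads, mean_umi, mixture,
                              dispersion_fit) {
  assert_scalar_num(mean_mapped_reads, "mean_mapped_reads", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(mean_umi, "mean_umi", lower = 0, strict_lower = TRUE)
  if (mean_umi > mean_mapped_reads + 1e-9)
    stopf("mean_umi must be <= mean_mapped_reads")
  stopifnot(inherits(mixture, "gamma_mixture"))
  structure(list(label = label, mean_mapped_reads = mean_mapped_reads,
                 mean_umi = mean_umi, mixture = mixture,
                 dispersion_fit = dispersion_fit),
            class = "depth_observation")
}

#' Fit the depth curves of an expression prior
#'
#' Ordinary-least-squares lines of the two gamma components' means and
#' standard deviations and of the zero weight `p1` against the mean UMI
#' count per cell; `p3` becomes the median of the observed values;
#' mapped reads are regressed on `ln(mean UMI)` (the saturation curve).
#' Dispersion-trend parameters are averaged across observations, or, for
#' Smart-seq2, fitted linearly versus read depth.
#'
#' @param observations list of [depth_observation()]s at >= 2 distinct
#'   depths (a single observation degenerates to constant curves with a
#'   warning).
#' @param cell_type,technology,G stored in the resulting prior.
#' @return An [expression_prior()].
#' @export
fit_depth_curves <- function(observations, cell_type = "unknown",
                             technology = "umi-droplet-10x", G = 21000) {
  stopifnot(length(observations) >= 1L,
            all(vapply(observations, inherits, logical(1), "depth_observation")))
  umi <- vapply(observations, `[[`, numeric(1), "mean_umi")
  reads <- vapply(observations, `[[`, numeric(1), "mean_mapped_reads")
  mom <- lapply(observations, function(o) {
    m <- o$mixture
    c(mean1 = m$shape[1] / m$rate[1], sd1 = sqrt(m$shape[1]) / m$rate[1],
      mean2 = m$shape[2] / m$rate[2], sd2 = sqrt(m$shape[2]) / m$rate[2],
      p1 = m$p[1], p3 = m$p[3])
  })
  mom <- do.call(rbind, mom)

  line_fit <- function(y, x) {
    if (length(unique(x)) < 2L) c(mean(y), 0) else unname(coef(lm(y ~ x)))
  }
  if (length(observations) < 2L)
    warning("single depth observation: curves degenerate to constants",
            call. = FALSE)

  curves <- list(mean1 = line_fit(mom[, "mean1"], umi),
                 sd1 = line_fit(mom[, "sd1"], umi),
                 mean2 = line_fit(mom[, "mean2"], umi),
                 sd2 = line_fit(mom[, "sd2"], umi),
                 p1 = line_fit(mom[, "p1"], umi))
  p3_const <- median(mom[, "p3"])

  disp <- do.call(rbind, lapply(observations, `[[`, "dispersion_fit"))
  if (technology == "read-plate-smartseq2" && length(observations) >= 2L) {
    dispersion_trend <- list(a0 = line_fit(disp[, 1L], reads),
                             a1 = line_fit(disp[, 2L], reads))
  } else {
    dispersion_trend <- c(a0 = mean(disp[, 1L]), a1 = mean(disp[, 2L]))
  }
  read_umi_curve <- line_fit(reads, log(umi))

  expression_prior(cell_type = cell_type, technology = technology,
                   curves = curves, p3_const = min(max(p3_const, 0), 1 - 1e-9),
                   dispersion_trend = dispersion_trend,
                   read_umi_curve = read_umi_curve, G = G,
                   umi_range = range(umi))
}

#' Mean UMI per cell implied by a mapped read depth
#'
#' Inverts the saturation curve `mapped reads = b0 + b1 * ln(mean UMI)`.
#' Values implying fewer than one UMI are floored at 1 with a warning.
#'
#' @param prior an [expression_prior()].
#' @param mapped_reads transcriptome-mapped reads per cell (> 0).
#' @return mean UMI count per cell.
#' @export
mean_umi_from_reads <- function(prior, mapped_reads) {
  b <- prior$read_umi_curve
  if (b[2] <= 0) stopf("invalid saturation curve: slope b1 must be > 0")
  if (any(mapped_reads <= 0)) stopf("mapped_reads must be > 0")
  umi <- exp((mapped_reads - b[1]) / b[2])
  if (any(umi < 1)) {
    warning("read depth implies < 1 UMI per cell; floored at 1", call. = FALSE)
    umi <- pmax(umi, 1)
  }
  umi
}

#' Mapped read depth implied by a mean UMI count
#' @param prior an [expression_prior()].
#' @param mean_umi mean UMI count per cell (>= 1).
#' @return transcriptome-mapped reads per cell.
#' @export
reads_from_mean_umi <- function(prior, mean_umi) {
  b <- prior$read_umi_curve
  b[1] + b[2] * log(mean_umi)
}

#' Instantiate the gamma mixture at a given depth
#'
#' Evaluates the prior's linear curves at `mean_umi`, floors `p1` at 0.01,
#' sets `p3` to its fitted constant and `p2 = 1 - p1 - p3`, and converts
#' each component's (mean, sd) to (shape, rate) via `shape = mean^2/sd^2`,
#' `rate = mean/sd^2`.
#'
#' @param prior an [expression_prior()].
#' @param mean_umi mean UMI count per cell (>= 1).
#' @return A [gamma_mixture()].
#' @export
mixture_at_depth <- function(prior, mean_umi) {
  assert_scalar_num(mean_umi, "mean_umi", lower = 1)
  ev <- function(nm) prior$curves[[nm]][1] + prior$curves[[nm]][2] * mean_umi
  m1 <- ev("mean1"); s1 <- ev("sd1"); m2 <- ev("mean2"); s2 <- ev("sd2")
  for (v in list(c("mean1", m1), c("sd1", s1), c("mean2", m2), c("sd2", s2)))
    if (as.numeric(v[2]) <= 0)
      stopf("curve '%s' evaluates to %.3g at mean UMI %.3g: outside the fitted range",
            v[1], as.numeric(v[2]), mean_umi)
  p1 <- max(ev("p1"), 0.01)
  p3 <- prior$p3_const
  if (p1 + p3 >= 1) stopf("p1 + p3 >= 1 at mean UMI %.3g", mean_umi)
  p2 <- 1 - p1 - p3
  gamma_mixture(c(p1, p2, p3),
                shape = c(m1^2 / s1^2, m2^2 / s2^2),
                rate = c(m1 / s1^2, m2 / s2^2),
                censor_point = 0)
}

#' Map an expression rank to a per-cell mean
#'
#' Transforms rank `i` (1 = most expressed of `G` genes) to the quantile
#' `q = 1 - (i - 0.5)/G` of the uncensored mixture.  Quantiles falling in
#' the zero mass return 0.
#'
#' @param mixture a [gamma_mixture()].
#' @param rank integer rank(s) in `1..G`.
#' @param G total number of genes considered.
#' @return per-cell negative-binomial mean(s).
#' @export
rank_to_mean <- function(mixture, rank, G) {
  if (any(rank < 1) || any(rank > G)) stopf("rank must lie in 1..G")
  q <- 1 - (rank - 0.5) / G
  mixture_quantile(mixture, q)
}

#' Dispersion implied by a mean
#'
#' Evaluates the trend `phi(mu) = a0 + a1/mu`, clamped below at 1e-8.
#' For Smart-seq2 priors whose trend parameters depend on read depth,
#' supply `depth` (mapped reads per cell).
#'
#' @param prior an [expression_prior()] (or a numeric `c(a0, a1)`).
#' @param mu per-cell mean(s), all > 0.
#' @param depth read depth at which to evaluate depth-dependent trend
#'   parameters (Smart-seq2).
#' @return dispersion value(s).
#' @export
dispersion_from_mean <- function(prior, mu, depth = NULL) {
  if (any(mu <= 0)) stopf("dispersion undefined at mu <= 0")
  if (inherits(prior, "expression_prior")) dt <- prior$dispersion_trend
  else dt <- prior
  if (is.list(dt)) {
    if (is.null(depth))
      stopf("depth-dependent dispersion trend needs 'depth'")
    a0 <- dt$a0[1] + dt$a0[2] * depth
    a1 <- dt$a1[1] + dt$a1[2] * depth
  } else {
    a0 <- dt[1]; a1 <- dt[2]
  }
  pmax(a0 + a1 / mu, 1e-8)
}
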