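# censored mixture log-likelihood:
#   zeros:     log(p1 + p2*F1(c) + p3*F2(c))
#   positives: log(p2*f1(x) + p3*f2(x))
censored_mixture_loglik <- function(x, p, shape, rate, cens) {
  pos <- x[x > 0]
  n0 <- sum(x <= 0)
  zc <- p[1] + p[2] * pgamma(cens, shape[1], rate[1]) +
    p[3] * pgamma(cens, shape[2], rate[2])
  dens <- p[2] * dgamma(pos, shape[1], rate[1]) +
    p[3] * dgamma(pos, shape[2], rate[2])
  n0 * log(max(zc, 1e-300)) + sum(log(pmax(dens, 1e-300)))
}

# weighted censored gamma M-step objective (to maximize):
#   sum_i w_i log f(x_i) + w0 * log F(c)
censored_gamma_optim <- function(x, w, w0, cens, shape0, rate0) {
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(1e12)
    ll <- sum(w * dgamma(x, a, b, log = TRUE))
    if (w0 > 0) ll <- ll + w0 * log(max(pgamma(cens, a, b), 1e-300))
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  start <- log(c(shape0, rate0))
  fit <- tryCatch(optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 60)),
                  error = function(e) NULL)
  if (is.null(fit) || fit$value >= obj(start)) {
    c(shape0, rate0)
  } else {
    exp(fit$par)
  }
}

moment_gamma <- function(x) {
  m <- mean(x); v <- var(x)
  if (!is.finite(v) || v <= 0) v <- (m / 2)^2 + 1e-12
  c(shape = m^2 / v, rate = m / v)
}

#' Fit a zero-inflated censored gamma mixture to gene means
#'
#' Maximum-likelihood fit by EM of the mean-expression distribution of a
#' cell type: a structural zero component plus two gamma components
#' left-censored at `1/n_cells` (the smallest observable mean).  Observed
#' zeros are attributed between the structural zero and the censored gamma
#' mass below the censor point; the second component is constrained to the
#' larger mean.  Three deterministic initializations (moment estimates on
#' the positive means split at the 90th/80th/95th percentile) are run and
#' the best likelihood kept.
#'
#' @param gene_means nonnegative per-gene mean expression values
#'   (>= 500 of them for a stable fit).
#' @param n_cells number of cells the means were computed from; sets the
#'   censor point `1/n_cells`.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A [gamma_mixture()] with fields `converged`, `degenerate`,
#'   `loglik` and attribute `loglik_trace`.
#' @export
fit_gamma_mixture <- function(gene_means, n_cells, max_iter = 200, tol = 1e-8) {
  x <- as.numeric(gene_means)
  if (any(!is.finite(x)) || any(x < 0)) stopf("gene means must be >= 0")
  if (length(x) < 500)
    warning("fewer than 500 gene means; mixture fit may be unstable",
            call. = FALSE)
  assert_scalar_num(n_cells, "n_cells", lower = 1)
  cens <- 1 / n_cells
  pos <- x[x > 0]
  n0 <- sum(x <= 0)
  n <- length(x)

  if (!length(pos)) {
    return(gamma_mixture(c(1, 0, 0) + c(0, 1e-12, 1e-12),
                         shape = c(1, 1), rate = c(1, 0.1),
                         censor_point = cens, converged = FALSE,
                         degenerate = TRUE, loglik = 0))
  }

  run_em <- function(split_q) {
    thr <- stats::quantile(pos, split_q)
    lo <- pos[pos <= thr]; hi <- pos[pos > thr]
    if (length(hi) < 2L) { hi <- pos[pos >= max(pos) * 0.5]; lo <- pos }
    if (length(lo) < 2L) lo <- pos
    g1 <- moment_gamma(lo); g2 <- moment_gamma(hi)
    p1 <- max(n0 / n, 1e-4)
    frac_hi <- length(hi) / length(pos)
    p <- c(p1, (1 - p1) * (1 - frac_hi), (1 - p1) * frac_hi)
    shape <- c(g1[1], g2[1]); rate <- c(g1[2], g2[2])

    ll_old <- censored_mixture_loglik(x, p, shape, rate, cens)
    trace <- ll_old
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # E-step
      f1 <- p[2] * dgamma(pos, shape[1], rate[1])
      f2 <- p[3] * dgamma(pos, shape[2], rate[2])
      tot <- pmax(f1 + f2, 1e-300)
      r1 <- f1 / tot; r2 <- f2 / tot
      z <- c(p[1],
             p[2] * pgamma(cens, shape[1], rate[1]),
             p[3] * pgamma(cens, shape[2], rate[2]))
      z <- z / max(sum(z), 1e-300)
      # M-step: weights
      w1 <- sum(r1) + n0 * z[2]
      w2 <- sum(r2) + n0 * z[3]
      p_new <- c(n0 * z[1], w1, w2) / n
      p_new <- pmax(p_new, 1e-12); p_new <- p_new / sum(p_new)
      # M-step: gamma parameters (generalized: improve-or-keep)
      par1 <- censored_gamma_optim(pos, r1, n0 * z[2], cens, shape[1], rate[1])
      par2 <- censored_gamma_optim(pos, r2, n0 * z[3], cens, shape[2], rate[2])
      p_try <- p_new
      shape_try <- c(par1[1], par2[1]); rate_try <- c(par1[2], par2[2])
      ll_new <- censored_mixture_loglik(x, p_try, shape_try, rate_try, cens)
      if (ll_new + 1e-9 < ll_old) {
        # keep old gammas, update weights only (still monotone)
        ll_new <- censored_mixture_loglik(x, p_new, shape, rate, cens)
        if (ll_new + 1e-9 < ll_old) { converged <- TRUE; break }
        p <- p_new
      } else {
        p <- p_try; shape <- shape_try; rate <- rate_try
      }
      trace <- c(trace, ll_new)
      if (abs(ll_new - ll_old) < tol * (1 + abs(ll_old))) {
        converged <- TRUE; ll_old <- ll_new; break
      }
      ll_old <- ll_new
    }
    list(p = p, shape = shape, rate = rate, loglik = ll_old,
         converged = converged, trace = trace)
  }

  fits <- lapply(c(0.90, 0.80, 0.95), run_em)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]

  # order components: component 2 has the larger mean
  means <- best$shape / best$rate
  if (means[1] > means[2]) {
    best$shape <- rev(best$shape); best$rate <- rev(best$rate)
    best$p <- best$p[c(1, 3, 2)]
  }
  out <- gamma_mixture(best$p, best$shape, best$rate, censor_point = cens,
                       converged = best$converged, degenerate = FALSE,
                       loglik = best$loglik)
  attr(out, "loglik_trace") <- best$trace
  out
}

#' Quantile function of the uncensored mixture
#'
#' Quantile of the zero-inflated gamma mixture (zero point mass plus the
#' two uncensored gamma components).  Probabilities at or below the zero
#' mass `p1` return 0.
#'
#' @param mix a [gamma_mixture()].
#' @param q probabilities in `[0, 1)`.
#' @return numeric vector of quantiles.
#' @export
mixture_quantile <- function(mix, q) {
  if (any(q < 0 | q >= 1)) stopf("probabilities must lie in [0, 1)")
  out <- numeric(length(q))
  p <- mix$p
  need <- q > p[1]
  if (!any(need)) return(out)
  cdf <- function(xx)
    p[1] + p[2] * pgamma(xx, mix$shape[1], mix$rate[1]) +
      p[3] * pgamma(xx, mix$shape[2], mix$rate[2])
  pdf <- function(xx)
    p[2] * dgamma(xx, mix$shape[1], mix$rate[1]) +
      p[3] * dgamma(xx, mix$shape[2], mix$rate[2])
  active <- which(p[2:3] > 0)
  lo <- min(qgamma(1e-10, mix$shape[active], mix$rate[active]))
  hi <- max(qgamma(1 - 1e-13, mix$shape[active], mix$rate[active]))
  lo <- max(lo, 1e-300)
  grid <- exp(seq(log(lo), log(hi), length.out = 2048L))
  Fg <- cdf(grid)
  # strictly increasing envelope for interpolation
  keep <- c(TRUE, diff(Fg) > 0)
  xi <- approx(Fg[keep], log(grid[keep]), xout = q[need], rule = 2)$y
  xv <- exp(xi)
  for (i in 1:4) {                       # Newton polish
    fv <- cdf(xv) - q[need]
    dv <- pdf(xv)
    step <- ifelse(dv > 0, fv / dv, 0)
    xv <- pmax(xv - step, xv * 0.1)
  }
  out[need] <- xv
  out
}

# CDF of the uncensored mixture (zero mass + gammas)
mixture_cdf <- function(mix, x) {
  mix$p[1] + mix$p[2] * pgamma(x, mix$shape[1], mix$rate[1]) +
    mix$p[3] * pgamma(x, mix$shape[2], mix$rate[2])
}

#' Draw gene means from a gamma mixture
#'
#' Samples per-gene means from the uncensored mixture: zero with
#' probability `p1`, otherwise one of the two gamma components.  Values
#' below `censor` (when given) are set to 0, emulating means too small to
#' be observed.
#'
#' @param mix a [gamma_mixture()].
#' @param n number of means to draw.
#' @param censor optional left-censor point.
#' @return numeric vector of length `n`.
#' @export
sample_mixture_means <- function(mix, n, censor = NULL) {
  comp <- sample.int(3L, n, replace = TRUE, prob = mix$p)
  x <- numeric(n)
  i2 <- comp == 2L; i3 <- comp == 3L
  x[i2] <- rgamma(sum(i2), mix$shape[1], mix$rate[1])
  x[i3] <- rgamma(sum(i3), mix$shape[2], mix$rate[2])
  if (!is.null(censor)) x[x < censor] <- 0
  x
}
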