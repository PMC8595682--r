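#' Per-cell size factors
#'
#' Median-of-ratios library-size normalization.  `"median-ratio"` uses the
#' geometric mean over all cells of each gene (genes with a zero anywhere
#' drop out); `"poscounts"` computes the geometric mean over the positive
#' entries only and takes the median over a cell's positive ratios, which
#' suits sparse data.  Factors are rescaled to geometric mean 1.
#'
#' @param counts a [pilot_counts()] or a genes-by-cells count matrix.
#' @param method `"median-ratio"` or `"poscounts"`.
#' @return positive numeric vector, one factor per cell.
#' @export
estimate_size_factors <- function(counts, method = c("median-ratio", "poscounts")) {
  method <- match.arg(method)
  m <- if (inherits(counts, "pilot_counts")) counts$matrix else counts
  m <- as.matrix(m)
  if (ncol(m) < 2L) stopf("need at least 2 cells")
  logm <- log(m)
  if (method == "median-ratio") {
    loggeo <- rowMeans(logm)             # -Inf for genes with any zero
    use <- is.finite(loggeo)
    if (!any(use))
      stopf(paste("median-ratio normalization impossible: no gene has",
                  "all-positive counts; use method = 'poscounts'"))
    sf <- apply(logm[use, , drop = FALSE], 2L,
                function(lc) exp(median(lc - loggeo[use])))
  } else {
    pos <- m > 0
    npos <- rowSums(pos)
    loggeo <- ifelse(npos > 0,
                     rowSums(ifelse(pos, logm, 0)) / pmax(npos, 1), NA_real_)
    use <- is.finite(loggeo)
    if (!any(use)) stopf("no gene with a positive count")
    sf <- vapply(seq_len(ncol(m)), function(j) {
      ratios <- logm[use, j] - loggeo[use]
      ratios <- ratios[is.finite(ratios) & m[use, j] > 0]
      if (!length(ratios)) return(NA_real_)
      exp(median(ratios))
    }, numeric(1))
    sf[is.na(sf)] <- 1
  }
  sf / exp(mean(log(sf)))
}

#' Per-gene negative-binomial fits and the mean-dispersion trend
#'
#' For one cell type of a pilot data set, estimates each gene's
#' negative-binomial mean and dispersion on size-factor-normalized counts
#' and fits the dispersion trend `phi(mu) = a0 + a1/mu` across genes by
#' trimmed iterative least squares (top and bottom 5% of residuals
#' removed).  When a `batch` column is present in the annotation, fits are
#' computed per batch and returned as separate entries.
#'
#' Dispersion is estimated by moments on normalized counts, accounting for
#' the size factors: `Var(x_j / s_j) = mu * mean(1/s) + phi * mu^2`.
#' Estimates below `min_dispersion` are clamped there and excluded from
#' the trend fit.
#'
#' @param counts a [pilot_counts()].
#' @param cell_type label selecting the cells to fit.
#' @param size_factors per-cell factors for the *selected* cells; computed
#'   with `sf_method` when `NULL`.
#' @param min_cells minimum number of cells required (default 50); below
#'   it the cell type is skipped with a warning and `NULL` is returned.
#' @param min_dispersion clamp for nonpositive dispersion estimates.
#' @param sf_method size-factor method when `size_factors` is `NULL`.
#' @return list with `fits` (data.frame `gene_id`, `mu`, `phi`,
#'   `in_trend`), `dispersion_trend` (`c(a0, a1)`), `n_cells`; or a list of
#'   such lists (one per batch) when batches are present.
#' @export
fit_gene_nb <- function(counts, cell_type = NULL, size_factors = NULL,
                        min_cells = 50, min_dispersion = 1e-8,
                        sf_method = "poscounts") {
  stopifnot(inherits(counts, "pilot_counts"))
  ann <- counts$cell_annotations
  sel <- if (is.null(cell_type)) rep(TRUE, nrow(ann)) else
    ann$cell_type == cell_type
  if (sum(sel) < min_cells) {
    warning(sprintf("cell type '%s' has %d cells (< %d); skipped",
                    cell_type %||% "(all)", sum(sel), min_cells),
            call. = FALSE)
    return(NULL)
  }
  if (!is.null(ann$batch) && length(unique(ann$batch[sel])) > 1L) {
    batches <- unique(ann$batch[sel])
    out <- lapply(batches, function(b) {
      sub <- counts
      keep <- sel & ann$batch == b
      sub$matrix <- counts$matrix[, keep, drop = FALSE]
      sub$cell_annotations <- ann[keep, , drop = FALSE]
      sub$cell_annotations$batch <- NULL
      fit_gene_nb(sub, cell_type = NULL, size_factors = NULL,
                  min_cells = min_cells, min_dispersion = min_dispersion,
                  sf_method = sf_method)
    })
    names(out) <- as.character(batches)
    return(out)
  }

  m <- as.matrix(counts$matrix[, sel, drop = FALSE])
  if (is.null(size_factors)) size_factors <- estimate_size_factors(m, sf_method)
  norm <- sweep(m, 2L, size_factors, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, var)
  minv <- mean(1 / size_factors)
  phi_raw <- ifelse(mu > 0, (v - mu * minv) / mu^2, NA_real_)
  in_trend <- is.finite(phi_raw) & phi_raw > 0 & mu > 0
  phi <- pmax(ifelse(is.finite(phi_raw), phi_raw, min_dispersion), min_dispersion)

  trend <- fit_dispersion_trend(mu[in_trend], phi_raw[in_trend])
  list(fits = data.frame(gene_id = counts$gene_ids, mu = mu, phi = phi,
                         in_trend = in_trend),
       dispersion_trend = trend, n_cells = ncol(m))
}

# trimmed iteratively reweighted least squares of phi on 1/mu; weights
# 1/fitted^2 emulate a gamma-family GLM (dispersion estimates scatter
# proportionally to their level), keeping noisy low-mean genes from
# dragging the intercept
fit_dispersion_trend <- function(mu, phi, iters = 6L, trim = 0.05) {
  if (length(mu) < 3L) return(c(a0 = NA_real_, a1 = NA_real_))
  x <- 1 / mu
  keep <- rep(TRUE, length(mu))
  w <- rep(1, length(mu))
  a <- c(median(phi), 0)
  for (i in seq_len(iters)) {
    fit <- lm(phi ~ x, subset = keep, weights = w)
    a <- unname(coef(fit))
    fitted_all <- pmax(a[1L] + a[2L] * x, 1e-8)
    w <- 1 / fitted_all^2
    ratio <- phi / fitted_all
    qs <- stats::quantile(ratio[keep], c(trim, 1 - trim))
    keep_new <- ratio >= qs[1L] & ratio <= qs[2L]
    if (sum(keep_new) >= 3L) keep <- keep_new
  }
  c(a0 = a[1L], a1 = a[2L])
}
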