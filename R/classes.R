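#' @importFrom stats approx coef dnbinom dgamma lm median optim optimize
#'   pbinom pchisq pf pgamma pnbinom pnorm pt qf qgamma qnbinom qnorm
#'   rbinom rgamma rnbinom rnorm runif sd uniroot var
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stopf("'%s' must be >= %g", name, lower)
  if (x > upper)
    stopf("'%s' must be <= %g", name, upper)
  invisible(x)
}

#' Pilot single-cell count data
#'
#' Container for a pilot genes-by-cells count matrix plus its per-cell
#' annotation (sample of origin and cell type).  Counts must be
#' non-negative integers; gene identifiers must be unique; every cell must
#' carry exactly one sample id and one cell type label.
#'
#' @param matrix integer count matrix, genes in rows, cells in columns
#'   (dense or `Matrix` sparse).
#' @param gene_ids character vector of row identifiers.
#' @param cell_annotations data.frame with columns `cell_id`, `sample_id`,
#'   `cell_type` (one row per column of `matrix`, same order).
#' @return An object of class `pilot_counts`.
#' @export
pilot_counts <- function(matrix, gene_ids, cell_annotations) {
  if (is.null(dim(matrix))) stopf("'matrix' must be two-dimensional")
  vals <- if (methods::is(matrix, "sparseMatrix")) matrix@x else as.vector(matrix)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stopf("non-count value: counts must be non-negative integers")
  if (length(gene_ids) != nrow(matrix))
    stopf("gene_ids length (%d) != matrix rows (%d)", length(gene_ids), nrow(matrix))
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids")
  req <- c("cell_id", "sample_id", "cell_type")
  if (!all(req %in% names(cell_annotations)))
    stopf("cell_annotations must have columns %s", paste(req, collapse = ", "))
  if (nrow(cell_annotations) != ncol(matrix))
    stopf("dimension mismatch: %d annotation rows vs %d matrix columns",
          nrow(cell_annotations), ncol(matrix))
  if (anyDuplicated(cell_annotations$cell_id)) stopf("duplicate cell ids")
  structure(list(matrix = matrix, gene_ids = as.character(gene_ids),
                 cell_annotations = cell_annotations),
            class = "pilot_counts")
}

#' @export
print.pilot_counts <- function(x, ...) {
  cat(sprintf("pilot_counts: %d genes x %d cells, %d samples, %d cell types\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$cell_annotations$sample_id)),
              length(unique(x$cell_annotations$cell_type))))
  invisible(x)
}

#' Experimental design point
#'
#' The three cost-determining parameters of a multi-sample single-cell
#' experiment: total sample size `n_s`, cells captured per sample `n_c`
#' and target reads sequenced per cell `r`, plus the group-2 : group-1
#' sample-size ratio for two-group comparisons.
#'
#' @param n_s total number of samples (donors).
#' @param n_c cells captured per sample.
#' @param r target reads sequenced per cell.
#' @param group_ratio ratio of group-2 to group-1 sample counts (default 1,
#'   a balanced design).
#' @return An object of class `design_point`.
#' @export
design_point <- function(n_s, n_c, r, group_ratio = 1) {
  assert_scalar_num(n_s, "n_s", lower = 1)
  assert_scalar_num(n_c, "n_c", lower = 1)
  assert_scalar_num(r, "r", lower = 0, strict_lower = TRUE)
  assert_scalar_num(group_ratio, "group_ratio", lower = 0, strict_lower = TRUE)
  structure(list(n_s = n_s, n_c = n_c, r = r, group_ratio = group_ratio),
            class = "design_point")
}

#' Cell-type context of a design
#'
#' Derived per-cell-type quantities of a design point: tissue frequency
#' `f_c` of the target cell type, usable (singlet) cells per sample `n_u`,
#' expected cells of the type per sample `n_cs`, effective singlet read
#' depth `r_s` and transcriptome-mapped read depth `r_m`.
#'
#' @param cell_type cell type label.
#' @param f_c frequency of the cell type in the tissue, in (0, 1].
#' @param n_u usable (singlet) cells per sample.
#' @param n_cs expected cells of the target type per sample.
#' @param r_s effective read depth of singlets.
#' @param r_m transcriptome-mapped read depth (`r_m <= r_s`).
#' @return An object of class `cell_type_context`.
#' @export
cell_type_context <- function(cell_type, f_c, n_u, n_cs, r_s, r_m) {
  assert_scalar_num(f_c, "f_c", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_num(n_u, "n_u", lower = 0)
  assert_scalar_num(n_cs, "n_cs", lower = 0)
  assert_scalar_num(r_s, "r_s", lower = 0, strict_lower = TRUE)
  assert_scalar_num(r_m, "r_m", lower = 0, strict_lower = TRUE)
  if (r_m > r_s + 1e-9) stopf("r_m (%g) must be <= r_s (%g)", r_m, r_s)
  structure(list(cell_type = cell_type, f_c = f_c, n_u = n_u, n_cs = n_cs,
                 r_s = r_s, r_m = r_m),
            class = "cell_type_context")
}

#' Zero-inflated two-component gamma mixture over gene means
#'
#' Distribution of per-cell gene expression means within a cell type: a
#' point mass at zero (weight `p1`) plus two gamma components (weights
#' `p2`, `p3`), the second capturing high-expression outliers.  When
#' fitted from data the gammas are left-censored at `censor_point`
#' (1 / number of cells), the smallest observable mean.
#'
#' @param p vector `c(p1, p2, p3)` of mixture weights summing to 1.
#' @param shape,rate length-2 vectors of gamma shape and rate parameters
#'   (mean of component j is `shape[j]/rate[j]`).
#' @param censor_point left-censoring bound used during fitting.
#' @param converged,degenerate,loglik fit diagnostics.
#' @return An object of class `gamma_mixture`.
#' @export
gamma_mixture <- function(p, shape, rate, censor_point = 0,
                          converged = TRUE, degenerate = FALSE,
                          loglik = NA_real_) {
  if (length(p) != 3L || any(p < -1e-12) || abs(sum(p) - 1) > 1e-9)
    stopf("mixture weights must be length 3, nonnegative, summing to 1")
  p <- pmax(p, 0); p <- p / sum(p)
  if (length(shape) != 2L || length(rate) != 2L || any(shape <= 0) || any(rate <= 0))
    stopf("gamma shapes and rates must be positive, length 2")
  structure(list(p = as.numeric(p), shape = as.numeric(shape),
                 rate = as.numeric(rate), censor_point = censor_point,
                 converged = converged, degenerate = degenerate,
                 loglik = loglik),
            class = "gamma_mixture")
}

#' Component and overall means of a gamma mixture
#' @param mix a [gamma_mixture()].
#' @return list with `component_means` (length 2) and `mean` (including the
#'   zero mass).
#' @export
mixture_moments <- function(mix) {
  cm <- mix$shape / mix$rate
  list(component_means = cm, mean = mix$p[2] * cm[1] + mix$p[3] * cm[2])
}

#' Expressed-gene threshold definition
#'
#' A gene is called expressed when its per-individual signal exceeds a
#' count threshold in a sufficient share of individuals.  In
#' `"pseudobulk-count"` mode the signal is the per-individual pseudobulk
#' sum and the threshold is `min_count`; in `"nonzero-cells"` mode the
#' requirement is at least `min_count` cells with nonzero counts.  The
#' across-individual requirement is a fraction `individual_fraction`
#' (strict: more than `floor(k * n_s)` individuals) or an absolute
#' `individual_count`.
#'
#' @param min_count integer threshold `n` on the per-individual pseudobulk
#'   sum (or minimum number of nonzero cells).
#' @param individual_fraction fraction `k` of individuals required, in
#'   `[0, 1)`.  Ignored when `individual_count` is given.
#' @param individual_count absolute number of individuals required
#'   (alternative to `individual_fraction`).
#' @param mode `"pseudobulk-count"` or `"nonzero-cells"`.
#' @param length_normalized if `TRUE`, `min_count` is interpreted as counts
#'   per kilobase of transcript (full-length protocols); gene lengths are
#'   then required wherever the threshold is applied.
#' @return An object of class `expression_threshold`.
#' @export
expression_threshold <- function(min_count = 10, individual_fraction = 0.5,
                                 individual_count = NULL,
                                 mode = c("pseudobulk-count", "nonzero-cells"),
                                 length_normalized = FALSE) {
  mode <- match.arg(mode)
  assert_scalar_num(min_count, "min_count", lower = 0)
  if (is.null(individual_count)) {
    assert_scalar_num(individual_fraction, "individual_fraction",
                      lower = 0, upper = 1 - 1e-12)
  } else {
    assert_scalar_num(individual_count, "individual_count", lower = 0)
  }
  structure(list(min_count = min_count,
                 individual_fraction = individual_fraction,
                 individual_count = individual_count,
                 mode = mode, length_normalized = length_normalized),
            class = "expression_threshold")
}

#' Sequencing cost model
#'
#' Library-preparation and sequencing cost parameters plus the doublet
#' model.  For droplet 10x-style kits the library cost is per kit (one kit
#' covers `lanes_per_kit` lanes, `cells_loaded_per_lane` cells each) and
#' the doublet rate grows linearly with cells loaded per lane
#' (`doublet_slope * n_c * n_sl`).  Other technologies use a per-cell
#' library cost and a constant doublet rate.
#'
#' @param kit_cost cost of one library-prep kit (`C_k`).
#' @param lanes_per_kit lanes covered by one kit (default 6).
#' @param flowcell_cost cost of one sequencing flow cell (`C_f`).
#' @param reads_per_flowcell reads produced by one flow cell (`r_f`).
#' @param cells_loaded_per_lane cells loaded on one lane (`n_cl`, default
#'   20000).
#' @param doublet_slope slope of the overloading doublet model (default
#'   7.67e-6); set `NULL` to use `doublet_rate` instead.
#' @param doublet_rate constant doublet rate for non-overloading
#'   technologies.
#' @param doublet_read_factor ratio of reads in a doublet vs a singlet
#'   (`f_d`, default 1.8).
#' @param mapping_efficiency fraction of reads mapping to the
#'   transcriptome (default 0.8).
#' @param per_cell_library_cost per-cell library cost for non-kit
#'   technologies (`NULL` for kit-based pricing).
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(kit_cost = 5600, lanes_per_kit = 6,
                       flowcell_cost = 14032, reads_per_flowcell = 4.1e9,
                       cells_loaded_per_lane = 20000,
                       doublet_slope = 7.67e-6, doublet_rate = NULL,
                       doublet_read_factor = 1.8, mapping_efficiency = 0.8,
                       per_cell_library_cost = NULL) {
  assert_scalar_num(kit_cost, "kit_cost", lower = 0)
  assert_scalar_num(lanes_per_kit, "lanes_per_kit", lower = 1)
  assert_scalar_num(flowcell_cost, "flowcell_cost", lower = 0)
  assert_scalar_num(reads_per_flowcell, "reads_per_flowcell",
                    lower = 0, strict_lower = TRUE)
  assert_scalar_num(cells_loaded_per_lane, "cells_loaded_per_lane", lower = 1)
  if (!is.null(doublet_slope))
    assert_scalar_num(doublet_slope, "doublet_slope", lower = 0)
  if (!is.null(doublet_rate))
    assert_scalar_num(doublet_rate, "doublet_rate", lower = 0, upper = 1)
  assert_scalar_num(doublet_read_factor, "doublet_read_factor", lower = 1)
  assert_scalar_num(mapping_efficiency, "mapping_efficiency",
                    lower = 0, upper = 1, strict_lower = TRUE)
  if (!is.null(per_cell_library_cost))
    assert_scalar_num(per_cell_library_cost, "per_cell_library_cost", lower = 0)
  structure(list(kit_cost = kit_cost, lanes_per_kit = lanes_per_kit,
                 flowcell_cost = flowcell_cost,
                 reads_per_flowcell = reads_per_flowcell,
                 cells_loaded_per_lane = cells_loaded_per_lane,
                 doublet_slope = doublet_slope, doublet_rate = doublet_rate,
                 doublet_read_factor = doublet_read_factor,
                 mapping_efficiency = mapping_efficiency,
                 per_cell_library_cost = per_cell_library_cost),
            class = "cost_model")
}

#' Ranked effect-size prior
#'
#' Ranked effect sizes of the genes a study hopes to discover, taken from
#' a reference bulk study or simulated: expression rank (1 = most
#' expressed), log2 fold change for DE studies or R-squared for eQTL
#' studies, and optionally gene length (bp) for full-length protocols.
#'
#' @param kind `"de"` or `"eqtl"`.
#' @param records data.frame with columns `rank`, `effect` and optionally
#'   `gene_length`.
#' @param source_sample_size sample size of the reference study (metadata).
#' @return An object of class `effect_size_prior`.
#' @export
effect_size_prior <- function(kind = c("de", "eqtl"), records,
                              source_sample_size = NA_integer_) {
  kind <- match.arg(kind)
  if (!all(c("rank", "effect") %in% names(records)))
    stopf("records must have columns 'rank' and 'effect'")
  if (any(records$rank < 1) || any(records$rank != round(records$rank)))
    stopf("ranks must be positive integers")
  if (kind == "eqtl" && (any(records$effect < 0) || any(records$effect >= 1)))
    stopf("eQTL effects (R-squared) must lie in [0, 1)")
  if (!is.null(records$gene_length) && any(records$gene_length <= 0, na.rm = TRUE))
    stopf("gene_length must be positive")
  records <- records[order(records$rank), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(kind = kind, records = records,
                 source_sample_size = source_sample_size),
            class = "effect_size_prior")
}

#' @export
print.effect_size_prior <- function(x, ...) {
  cat(sprintf("effect_size_prior (%s): %d genes, ranks %d..%d\n",
              x$kind, nrow(x$records), min(x$records$rank), max(x$records$rank)))
  invisible(x)
}

#' Depth-parameterized expression prior of a cell type
#'
#' The fitted description of a cell type's expression distribution across
#' sequencing depths: linear curves of the gamma-mixture parameters versus
#' mean UMI per cell, a constant high-expression mixture weight, the
#' mean-dispersion trend, and the saturation curve linking transcriptome
#' mapped reads to mean UMI counts.
#'
#' Each curve is a length-2 numeric `c(intercept, slope)` evaluated at the
#' mean UMI count per cell.  The zero-component weight `p1` is floored at
#' 0.01 at evaluation; `p2 = 1 - p1 - p3`.
#'
#' @param cell_type cell type label.
#' @param technology one of `"umi-droplet-10x"`, `"umi-droplet-dropseq"`,
#'   `"read-plate-smartseq2"`.
#' @param curves named list with elements `mean1`, `sd1`, `mean2`, `sd2`,
#'   `p1`, each `c(intercept, slope)` vs mean UMI per cell.
#' @param p3_const constant mixture weight of the second gamma component.
#' @param dispersion_trend `c(a0, a1)` of the trend `phi(mu) = a0 + a1/mu`;
#'   for Smart-seq2 optionally a list with `a0` and `a1` each
#'   `c(intercept, slope)` versus read depth.
#' @param read_umi_curve `c(b0, b1)` of
#'   `mapped reads = b0 + b1 * ln(mean UMI)`.
#' @param G total number of genes considered (default 21000).
#' @param umi_range depth range (mean UMI) the curves were fitted on.
#' @return An object of class `expression_prior`.
#' @export
expression_prior <- function(cell_type, technology = c("umi-droplet-10x",
                                                       "umi-droplet-dropseq",
                                                       "read-plate-smartseq2"),
                             curves, p3_const, dispersion_trend,
                             read_umi_curve, G = 21000,
                             umi_range = c(NA_real_, NA_real_)) {
  technology <- match.arg(technology)
  need <- c("mean1", "sd1", "mean2", "sd2", "p1")
  if (!all(need %in% names(curves)))
    stopf("curves must contain %s", paste(need, collapse = ", "))
  for (nm in need)
    if (length(curves[[nm]]) != 2L || any(!is.finite(curves[[nm]])))
      stopf("curve '%s' must be c(intercept, slope)", nm)
  assert_scalar_num(p3_const, "p3_const", lower = 0, upper = 1 - 1e-12)
  assert_scalar_num(G, "G", lower = 1)
  if (length(read_umi_curve) != 2L)
    stopf("read_umi_curve must be c(b0, b1)")
  # normalize shapes/names so serialization round-trips bit-exactly
  curves <- lapply(curves[need], function(v) unname(as.numeric(v)))
  if (is.list(dispersion_trend))
    dispersion_trend <- lapply(dispersion_trend,
                               function(v) unname(as.numeric(v)))
  else dispersion_trend <- unname(as.numeric(dispersion_trend))
  structure(list(cell_type = cell_type, technology = technology,
                 curves = curves, p3_const = as.numeric(p3_const),
                 dispersion_trend = dispersion_trend,
                 read_umi_curve = unname(as.numeric(read_umi_curve)),
                 G = as.numeric(G),
                 umi_range = unname(as.numeric(umi_range))),
            class = "expression_prior")
}

#' @export
print.expression_prior <- function(x, ...) {
  cat(sprintf("expression_prior: cell type '%s' (%s), G = %d genes\n",
              x$cell_type, x$technology, as.integer(x$G)))
  invisible(x)
}

#' Convert an eQTL regression estimate to R-squared
#'
#' From a reference study's slope `beta`, its standard error and the study
#' sample size `N`: `t = beta/se` and `R2 = t^2 / (N - 2 + t^2)`.
#'
#' @param beta regression slope.
#' @param se standard error of the slope (> 0).
#' @param N sample size of the reference study (> 2).
#' @return R-squared in `[0, 1)`.
#' @export
beta_to_r2 <- function(beta, se, N) {
  if (any(se <= 0)) stopf("se must be > 0")
  if (any(N <= 2)) stopf("N must be > 2")
  t2 <- (beta / se)^2
  t2 / (N - 2 + t2)
}
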