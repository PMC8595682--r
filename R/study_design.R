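#' Doublet and overloading adjustment of a design
#'
#' For droplet kits loaded with `n_cl` cells per lane, the number of
#' samples multiplexed per lane is `n_sl = floor(n_cl / n_c)` and the
#' doublet rate grows linearly with cells loaded:
#' `d = slope * n_c * n_sl` (capped at 1).  Technologies without
#' overloading use the configured constant rate.  Usable (singlet) cells
#' are `n_u = (1 - d) * n_c`; because doublets absorb `f_d` times the
#' reads of a singlet, the singlet read depth is
#' `r_s = r * n_c / (n_u + f_d * (n_c - n_u))`, of which
#' `r_m = mapping_efficiency * r_s` maps to the transcriptome.
#'
#' @param n_c cells captured per sample.
#' @param cost_model a [cost_model()].
#' @param r target reads sequenced per cell.
#' @return list with `d`, `n_u`, `r_s`, `r_m`, `n_sl`.
#' @export
doublet_adjust <- function(n_c, cost_model, r) {
  stopifnot(inherits(cost_model, "cost_model"))
  assert_scalar_num(n_c, "n_c", lower = 1)
  assert_scalar_num(r, "r", lower = 0, strict_lower = TRUE)
  if (!is.null(cost_model$doublet_slope)) {
    n_sl <- floor(cost_model$cells_loaded_per_lane / n_c)
    if (n_sl < 1)
      stopf("cells per sample (%g) exceed lane capacity (%g)",
            n_c, cost_model$cells_loaded_per_lane)
    d <- min(cost_model$doublet_slope * n_c * n_sl, 1)
  } else {
    n_sl <- floor(cost_model$cells_loaded_per_lane / n_c)
    d <- cost_model$doublet_rate %||% 0
  }
  n_u <- (1 - d) * n_c
  f_d <- cost_model$doublet_read_factor
  r_s <- r * n_c / (n_u + f_d * (n_c - n_u))
  r_m <- cost_model$mapping_efficiency * r_s
  list(d = d, n_u = n_u, r_s = r_s, r_m = r_m, n_sl = n_sl)
}

#' Derive the cell-type context of a design
#'
#' Applies [doublet_adjust()] and the target cell type frequency to a
#' design point.  The expected number of cells of the type per sample is
#' `floor(f_c * n_u)`; designs expecting fewer than one such cell are
#' flagged infeasible.
#'
#' @param design a [design_point()].
#' @param f_c frequency of the target cell type in the tissue.
#' @param cost_model a [cost_model()].
#' @param cell_type label carried into the context.
#' @return A [cell_type_context()], or `NULL` (with a warning) when the
#'   design expects under one cell of the type per sample.
#' @export
derive_context <- function(design, f_c, cost_model, cell_type = "target") {
  adj <- doublet_adjust(design$n_c, cost_model, design$r)
  n_cs <- floor(f_c * adj$n_u)
  if (n_cs < 1) {
    warning(sprintf("design expects %.2f cells of the target type per sample (< 1): infeasible",
                    f_c * adj$n_u), call. = FALSE)
    return(NULL)
  }
  cell_type_context(cell_type, f_c, adj$n_u, n_cs, adj$r_s, adj$r_m)
}

#' Total cost of an experiment
#'
#' Kit-based (droplet) pricing:
#' `C_t = ceiling(n_s / (lanes_per_kit * n_sl)) * C_k +
#'  ceiling(n_s * n_c * r / r_f) * C_f`.
#' Technologies priced per cell replace the kit term with
#' `per_cell_library_cost * n_s * n_c`.
#'
#' @param design a [design_point()] (or a list with `n_s`, `n_c`, `r`).
#' @param cost_model a [cost_model()].
#' @return total cost (currency-agnostic).
#' @export
experiment_cost <- function(design, cost_model) {
  stopifnot(inherits(cost_model, "cost_model"))
  n_s <- design$n_s; n_c <- design$n_c; r <- design$r
  if (n_s == 0) return(0)
  seq_cost <- ceiling(n_s * n_c * r / cost_model$reads_per_flowcell) *
    cost_model$flowcell_cost
  if (is.null(cost_model$per_cell_library_cost)) {
    n_sl <- floor(cost_model$cells_loaded_per_lane / n_c)
    if (n_sl < 1) stopf("cells per sample exceed lane capacity")
    lib_cost <- ceiling(n_s / (cost_model$lanes_per_kit * n_sl)) *
      cost_model$kit_cost
  } else {
    lib_cost <- cost_model$per_cell_library_cost * n_s * n_c
  }
  lib_cost + seq_cost
}

#' Sample size affordable under a budget
#'
#' Ceiling-free inversion of the cost formula: with per-sample cost
#' `C_k / (lanes_per_kit * n_sl) + n_c * r * C_f / r_f` (or the per-cell
#' analog), returns `floor(budget / per-sample cost)`.
#'
#' @param budget total budget (>= 0).
#' @param n_c cells per sample.
#' @param r reads per cell.
#' @param cost_model a [cost_model()].
#' @return affordable number of samples.
#' @export
sample_size_for_budget <- function(budget, n_c, r, cost_model) {
  stopifnot(inherits(cost_model, "cost_model"))
  if (budget < 0) stopf("budget must be >= 0")
  seq_per_sample <- n_c * r * cost_model$flowcell_cost /
    cost_model$reads_per_flowcell
  if (is.null(cost_model$per_cell_library_cost)) {
    n_sl <- floor(cost_model$cells_loaded_per_lane / n_c)
    if (n_sl < 1) stopf("cells per sample exceed lane capacity")
    lib_per_sample <- cost_model$kit_cost / (cost_model$lanes_per_kit * n_sl)
  } else {
    lib_per_sample <- cost_model$per_cell_library_cost * n_c
  }
  per_sample <- lib_per_sample + seq_per_sample
  if (per_sample <= 0) stopf("per-sample cost must be > 0")
  floor(budget / per_sample)
}

#' Probability of capturing enough cells of a rare type
#'
#' Probability that every one of `n_s` individuals yields at least
#' `n_cs_target` cells of a type with tissue frequency `f_c` among `n_c`
#' captured cells: the negative-binomial CDF of failures before
#' `n_cs_target` successes, evaluated at `n_c - n_cs_target` and raised to
#' the `n_s`-th power.
#'
#' @param n_c cells captured per individual.
#' @param n_cs_target minimum cells of the type required per individual.
#' @param f_c cell type frequency in `(0, 1]`.
#' @param n_s number of individuals (default 1).
#' @return detection probability.
#' @export
celltype_detection_probability <- function(n_c, n_cs_target, f_c, n_s = 1) {
  assert_scalar_num(f_c, "f_c", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_num(n_cs_target, "n_cs_target", lower = 1)
  if (n_cs_target > n_c) return(0)
  pnbinom(n_c - n_cs_target, size = n_cs_target, prob = f_c)^n_s
}

#' Minimum cells per individual for rare-type detection
#'
#' Smallest integer `n_c` whose [celltype_detection_probability()] reaches
#' `target_prob`, found by a doubling bracket plus bisection and verified
#' at `n_c` and `n_c - 1`.
#'
#' @param f_c cell type frequency.
#' @param n_cs_target minimum cells of the type per individual.
#' @param n_s number of individuals.
#' @param target_prob required detection probability in (0, 1).
#' @return minimal `n_c`.
#' @export
min_cells_for_detection <- function(f_c, n_cs_target, n_s, target_prob) {
  if (target_prob >= 1 || target_prob <= 0)
    stopf("target_prob must be in (0, 1)")
  pr <- function(n_c) celltype_detection_probability(n_c, n_cs_target, f_c, n_s)
  hi <- max(n_cs_target, 1)
  while (pr(hi) < target_prob) {
    hi <- hi * 2
    if (hi > 1e9) stopf("no feasible n_c below 1e9")
  }
  lo <- n_cs_target
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (pr(mid) >= target_prob) hi <- mid else lo <- mid
  }
  n_c <- if (pr(lo) >= target_prob) lo else hi
  stopifnot(pr(n_c) >= target_prob,
            n_c == n_cs_target || pr(n_c - 1) < target_prob)
  n_c
}

#' Grid optimization of a design under a fixed budget
#'
#' For each grid point of cells per sample and reads per cell, derives
#' the affordable sample size from the budget (ceiling-free cost
#' inversion), applies the doublet adjustment, and evaluates
#' [overall_detection_power()].  Returns all feasible points ranked by
#' overall power; ties prefer larger `n_s`, then lower `r`.
#'
#' @param budget total budget.
#' @param grid_cells candidate values of cells per sample.
#' @param grid_reads candidate values of reads per cell.
#' @param prior,effects,threshold,... passed to
#'   [overall_detection_power()].
#' @param f_c target cell type frequency.
#' @param cost_model a [cost_model()].
#' @param min_samples designs with fewer samples are infeasible
#'   (default 2; DE tests additionally need both groups filled).
#' @return list with `table` (ranked data.frame) and `best` (the top
#'   row's [overall_detection_power()] result).
#' @export
optimize_design <- function(budget, grid_cells, grid_reads, prior, effects,
                            threshold, f_c, cost_model, min_samples = 2, ...) {
  if (budget <= 0) stopf("budget must be > 0")
  grid <- expand.grid(n_c = grid_cells, r = grid_reads)
  rows <- list()
  results <- list()
  for (i in seq_len(nrow(grid))) {
    n_c <- grid$n_c[i]; r <- grid$r[i]
    n_s <- tryCatch(sample_size_for_budget(budget, n_c, r, cost_model),
                    error = function(e) 0)
    if (n_s < min_samples) next
    design <- design_point(n_s, n_c, r)
    ctx <- suppressWarnings(derive_context(design, f_c, cost_model))
    if (is.null(ctx)) next
    res <- overall_detection_power(prior, effects, ctx, design, threshold, ...)
    rows[[length(rows) + 1L]] <-
      data.frame(n_c = n_c, r = r, n_s = n_s, n_cs = ctx$n_cs,
                 mapped_depth = ctx$r_m,
                 expected_expressed = res$expected_expressed,
                 alpha_adjusted = res$alpha_adjusted,
                 overall_power = res$overall_power)
    results[[length(results) + 1L]] <- res
  }
  if (!length(rows))
    stopf("no feasible design in the grid under budget %g", budget)
  tab <- do.call(rbind, rows)
  ord <- order(-tab$overall_power, -tab$n_s, tab$r)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, best = results[[ord[1L]]])
}
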