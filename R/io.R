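#' Read pilot counts from disk
#'
#' Reads a genes-by-cells count matrix (Matrix Market `.mtx` or dense
#' delimited table with gene ids in the first column) together with a
#' cell-annotation table (`cell_id`, `sample_id`, `cell_type`).  Matrix
#' orientation is auto-detected by matching the annotation length and can
#' be forced with `transpose`.  Cells absent from the annotation are
#' dropped with a message.
#'
#' @param matrix_path path to `.mtx` or delimited counts.
#' @param annotation_path path to the delimited annotation table.
#' @param gene_ids gene identifiers (required for `.mtx` input without
#'   sidecar; for dense input the first column is used when this is
#'   `NULL`).
#' @param transpose `NA` (auto), `TRUE` (input is cells x genes) or
#'   `FALSE` (input is genes x cells).
#' @param sep field separator of the dense/annotation tables.
#' @return A [pilot_counts()] object.
#' @export
load_pilot_counts <- function(matrix_path, annotation_path, gene_ids = NULL,
                              transpose = NA, sep = "\t") {
  ann <- read.delim(annotation_path, sep = sep, stringsAsFactors = FALSE)
  req <- c("cell_id", "sample_id", "cell_type")
  if (!all(req %in% names(ann)))
    stopf("annotation must have columns %s", paste(req, collapse = ", "))
  ann$cell_id <- as.character(ann$cell_id)

  if (grepl("\\.mtx$", matrix_path)) {
    m <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
    cell_names <- NULL
  } else {
    tab <- read.delim(matrix_path, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (is.null(gene_ids)) {
      gene_ids <- as.character(tab[[1L]])
      tab <- tab[, -1L, drop = FALSE]
    }
    m <- as.matrix(tab)
    cell_names <- colnames(m)
  }

  n_ann <- nrow(ann)
  if (is.na(transpose)) {
    transpose <- (ncol(m) != n_ann && nrow(m) == n_ann)
  }
  if (isTRUE(transpose)) m <- Matrix::t(m)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(m)))
  if (is.null(cell_names)) {
    if (ncol(m) < n_ann)
      stopf("dimension mismatch: %d matrix columns vs %d annotated cells",
            ncol(m), n_ann)
    cell_names <- if (ncol(m) == n_ann) ann$cell_id else
      paste0("cell", seq_len(ncol(m)))
  }
  colnames(m) <- cell_names

  keep <- cell_names %in% ann$cell_id
  if (!all(keep)) {
    warning(sprintf("dropping %d cell(s) absent from the annotation",
                    sum(!keep)), call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  ann <- ann[match(colnames(m), ann$cell_id), , drop = FALSE]
  rownames(ann) <- NULL
  pilot_counts(m, gene_ids, ann)
}

#' Read a ranked effect-size prior
#'
#' Delimited table with a header.  For `kind = "de"` an effect column
#' `log2fc` (or `effect`) is required; for `kind = "eqtl"` either `r2` or
#' the triple `beta`, `se`, `n` (converted via [beta_to_r2()]).  An
#' optional `gene_length` column is carried through.
#'
#' @param path path to the delimited table.
#' @param kind `"de"` or `"eqtl"`.
#' @param sep field separator.
#' @return An [effect_size_prior()].
#' @export
load_effect_prior <- function(path, kind = c("de", "eqtl"), sep = "\t") {
  kind <- match.arg(kind)
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (is.null(tab$rank)) stopf("effect prior table must have a 'rank' column")
  if (kind == "de") {
    eff <- tab$log2fc %||% tab$effect
    if (is.null(eff)) stopf("DE prior needs a 'log2fc' (or 'effect') column")
    N <- NA_integer_
  } else {
    if (!is.null(tab$r2)) {
      eff <- tab$r2
      N <- NA_integer_
    } else if (all(c("beta", "se", "n") %in% names(tab))) {
      eff <- beta_to_r2(tab$beta, tab$se, tab$n)
      N <- tab$n[1L]
    } else {
      stopf("eQTL prior needs 'r2' or ('beta', 'se', 'n') columns")
    }
  }
  rec <- data.frame(rank = tab$rank, effect = eff)
  if (!is.null(tab$gene_length)) rec$gene_length <- tab$gene_length
  effect_size_prior(kind, rec, source_sample_size = N)
}

PRIOR_SCHEMA_VERSION <- "1.0"

#' Serialize / restore a fitted expression prior
#'
#' Priors are written as schema-versioned JSON with full double precision,
#' so `load_prior(save_prior(x))` reproduces `x` field for field.
#'
#' @param prior an [expression_prior()].
#' @param path file path.
#' @return `save_prior` returns `path` invisibly; `load_prior` returns the
#'   restored [expression_prior()].
#' @export
save_prior <- function(prior, path) {
  if (!inherits(prior, "expression_prior")) stopf("not an expression_prior")
  obj <- unclass(prior)
  obj$schema_version <- PRIOR_SCHEMA_VERSION
  # I(17) = 17 *significant* digits: doubles round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_prior
#' @export
load_prior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ver <- obj$schema_version
  if (is.null(ver)) stopf("prior file has no schema-version field")
  if (!identical(ver, PRIOR_SCHEMA_VERSION))
    stopf("unsupported prior schema version '%s' (expected '%s')",
          ver, PRIOR_SCHEMA_VERSION)
  need <- c("cell_type", "technology", "curves", "p3_const",
            "dispersion_trend", "read_umi_curve", "G")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    stopf("prior file missing field(s): %s", paste(missing, collapse = ", "))
  dt <- obj$dispersion_trend
  if (!is.list(dt)) dt <- as.numeric(dt)
  expression_prior(cell_type = obj$cell_type, technology = obj$technology,
                   curves = lapply(obj$curves, as.numeric),
                   p3_const = obj$p3_const, dispersion_trend = dt,
                   read_umi_curve = as.numeric(obj$read_umi_curve),
                   G = obj$G,
                   umi_range = as.numeric(obj$umi_range %||% c(NA, NA)))
}
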