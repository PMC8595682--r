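# shared fixture builders; everything is generated in code at test time

# synthetic 10x-style expression prior; constant curves unless slopes given
make_test_prior <- function(G = 2000, slopes = FALSE) {
  if (slopes) {
    curves <- list(mean1 = c(0.15, 1e-4), sd1 = c(0.2, 1.3e-4),
                   mean2 = c(6, 1.3e-3), sd2 = c(3, 6e-4),
                   p1 = c(0.45, -8e-5))
  } else {
    curves <- list(mean1 = c(0.3, 0), sd1 = c(0.4, 0), mean2 = c(8, 0),
                   sd2 = c(4, 0), p1 = c(0.25, 0))
  }
  expression_prior(cell_type = "synthetic", technology = "umi-droplet-10x",
                   curves = curves, p3_const = 0.05,
                   dispersion_trend = c(0.2, 1.5),
                   read_umi_curve = c(-83480, 12737), G = G,
                   umi_range = c(500, 5000))
}

# ground-truth mixture used by the generators (gamma1 mean 0.3, gamma2 mean 8)
make_truth_mixture <- function() {
  gamma_mixture(c(0.25, 0.70, 0.05), shape = c(0.5625, 4),
                rate = c(1.875, 0.5))
}

# 3 genes x 4 cells MTX + annotation fixture on disk; returns the paths
write_mtx_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  m <- Matrix::Matrix(matrix(c(0, 1, 2, 0,
                               5, 0, 1, 3,
                               2, 2, 0, 1), nrow = 3, byrow = TRUE),
                      sparse = TRUE)
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(m, mtx)
  ann <- data.frame(cell_id = paste0("cell", 1:4),
                    sample_id = c("s1", "s1", "s2", "s2"),
                    cell_type = "T")
  tsv <- file.path(dir, "cells.tsv")
  write.table(ann, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(mtx = mtx, tsv = tsv, dense = m)
}

# default design/threshold/cost used across tests
test_threshold <- function() expression_threshold(10, 0.5)
test_cost_model <- function() cost_model()
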