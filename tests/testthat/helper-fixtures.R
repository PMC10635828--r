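# Shared fixtures, all built in code.

# Tiny named count matrix.
toy_counts <- function(values = c(1, 2, 0, 0, 3, 4), nrow = 3,
                       genes = paste0("g", seq_len(nrow)),
                       cells = paste0("c", seq_len(length(values) / nrow))) {
  expr_matrix(matrix(values, nrow = nrow,
                     dimnames = list(genes, cells)), layer = "raw")
}

# A "one distinct cell per spot" toy: the ST matrix is the cells themselves,
# so the optimal mapping is the identity and precision must be 1.
diagonal_toy <- function(n_cells = 24, n_types = 3, n_genes = 80, seed = 11) {
  atl <- generate_atlas(n_types = n_types, n_genes = n_genes,
                        cells_per_type = n_cells / n_types, seed = seed)
  st <- expr_matrix(unclass(atl$expr),
                    column_ids = paste0("spot_", colnames(atl$expr)),
                    layer = "raw")
  truth <- stats::setNames(colnames(st), colnames(atl$expr))
  fr <- prop.table(table(atl$annotation$cell_type))
  list(sc = atl$expr, ann = atl$annotation, st = st, truth = truth,
       fractions = stats::setNames(as.numeric(fr), names(fr)),
       counts = spot_model(colnames(st), rep(1L, ncol(st))))
}

# Random balanced cost instance built from expression profiles.
random_cost <- function(k, metric, n_genes = 8) {
  a <- matrix(stats::rlnorm(n_genes * k), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("a", seq_len(k))))
  b <- matrix(stats::rlnorm(n_genes * k), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("b", seq_len(k))))
  build_cost_matrix(expr_matrix(a, layer = "log2cpm"),
                    expr_matrix(b, layer = "log2cpm"), metric)
}

# Study-condition simulated tissue: 200 cells, 5 types, ~5 cells per spot.
study_tissue <- function(seed, noise_p = 0) {
  simulate_tissue(n_types = 5, n_genes = 200, cells_per_type = 40,
                  layout = "blocks", target_mean_cells_per_spot = 5,
                  noise_p = noise_p, seed = seed)
}

tissue_fractions <- function(tis) {
  fr <- prop.table(table(tis$annotation$cell_type))
  stats::setNames(as.numeric(fr), names(fr))
}

# Map the noised query of a tissue back onto its pseudo-spots with true
# fractions and true counts (benchmarking configuration).
map_tissue <- function(tis, seed = 1, mode = "generation", ...) {
  map_cells(tis$query, tis$annotation, tis$spot_counts,
            fractions = tissue_fractions(tis),
            cells_per_spot = true_spot_model(tis), mode = mode, seed = seed, ...)
}
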