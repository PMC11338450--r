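# small fixtures built in code at test time

# tiny count matrix with known structure
tiny_counts <- function() {
  m <- matrix(c(5, 0, 1,
                0, 2, 0,
                3, 4, 6,
                0, 0, 0), nrow = 4, byrow = TRUE)
  count_matrix(m, gene_ids = paste0("g", 1:4), cell_ids = paste0("c", 1:3))
}

# small processed matrix from a seeded simulation, suitable for quick fits
small_proc <- function(n_genes = 120, n_cells = 60, n_groups = 3,
                       target_zero = 0.6, seed = 42) {
  p <- sim_params(n_genes = n_genes, n_cells = n_cells,
                  n_groups = n_groups, seed = seed)
  p <- calibrate_dropout(p, target_zero)
  sim <- simulate_groups(p)
  list(sim = sim,
       proc = preprocess_counts(count_matrix(sim$observed_counts),
                                min_cells = 2, hvg_n = n_genes))
}

# strictly positive random low-rank matrix (no zeros anywhere)
positive_lowrank <- function(G = 30, C = 20, k = 2, seed = 11) {
  withr::with_seed(seed, {
    W <- matrix(runif(G * k, 0.5, 2), G, k)
    H <- matrix(runif(k * C, 0.5, 2), k, C)
    list(X = W %*% H, W = W, H = H)
  })
}
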