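# Small shared fixtures, built in code.

tiny_sim <- function(n_genes = 120, n_per_group = c(10, 10), seed = 42, ...) {
  simulate_counts(sim_config(n_genes = n_genes, n_per_group = n_per_group,
                             seed = seed, ...))
}

# A count matrix with deterministic structure for normalization tests.
toy_counts <- function(n_genes = 50, n_samples = 8, seed = 7, lambda = 60) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), nrow = n_genes)
  count_matrix(m, group = rep(1:2, each = n_samples / 2))
}
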