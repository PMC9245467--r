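# Small configurations reused across test files.

tiny_config <- function(seed = 1L, ...) {
  args <- list(n = 120, p_g = 30, p_r = 30, q = 2, L_true = 4,
               support_size = 3, n_causal_genes = 6, effects_per_gene = 2,
               n_causal_regulators = 6, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Orthogonal sparse loading matrix with disjoint supports (for building
# exact low-rank test matrices).
unit_sparse_loadings <- function(p, supports, values) {
  M <- matrix(0, p, length(supports))
  for (l in seq_along(supports)) {
    v <- numeric(p)
    v[supports[[l]]] <- values[[l]]
    M[, l] <- v / sqrt(sum(v^2))
  }
  M
}
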