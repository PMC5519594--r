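# Small in-code fixtures shared across test files.

toy_assoc <- function() {
  association_matrix(
    matrix(c(1, 0, 0,
             0, 1, 0,
             1, 1, 0,
             0, 0, 1), nrow = 4, byrow = TRUE),
    mirna_ids = c("m1", "m2", "m3", "m4"),
    disease_ids = c("d1", "d2", "d3"))
}

# identity-like similarity with a given off-diagonal filler
flat_similarity <- function(ids, off = 0.2, kind = "mirna_functional") {
  k <- length(ids)
  v <- matrix(off, k, k)
  diag(v) <- 1
  similarity_matrix(v, ids, kind = kind)
}

small_network <- function(seed = 1, m = 16, n = 10, density = 0.2) {
  generate_network(synth_config(m = m, n = n, rank = 2, density = density,
                                n_families = 4, seed = seed))
}
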