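# Shared fixtures: a tiny desk-scale model configuration and small seeded
# datasets, built in code at test time.

tiny_config <- function(...) {
  dta_config("synthetic",
             drug_max_len = 24, protein_max_len = 30,
             embed_dim = 4, filters = c(4, 4), se_r = 2,
             gin_depth = 3, gin_hidden = 6, graph_dim = 6,
             heads = 2, la = 8, head_hidden = c(8), dropout = 0,
             ...)
}

tiny_dataset <- function(n = 6, seed = 3) {
  generate_affinity_data(synthetic_spec(n = n, protein_length = 25,
                                        noise = 0.2, seed = seed))
}

# partial dictionaries printed as the worked encoding example
example_protein_dict <- function() {
  codes <- c(A = 1L, N = 14L, C = 2L, Q = 15L, I = 8L, V = 22L, W = 21L)
  structure(codes, modality = "protein", size = length(codes),
            class = "token_dictionary")
}

example_smiles_dict <- function() {
  codes <- c(C = 22L, N = 34L, O = 33L, `(` = 4L, `)` = 3L)
  structure(codes, modality = "smiles", size = length(codes),
            class = "token_dictionary")
}
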