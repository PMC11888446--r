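# Shared fixtures: all synthetic, generated in code at test time.

fixture_repertoire <- function(n_paired = 30, n_uh = 40, n_ul = 20, seed = 101) {
  generate_repertoire(n_paired, n_uh, n_ul, seed = seed)
}

fixture_tokenized <- function(n = 20, seed = 202, vocab = build_vocabulary()) {
  rep <- generate_repertoire(0, n, 0, seed = seed)
  lapply(rep$unpaired, tokenize_record, vocab = vocab)
}

# Reference models exercising the evaluation contracts without training.

# Constant zero logits: a uniform distribution over all 33 tokens.
uniform_model <- function(ids, mask) {
  matrix(0, nrow(ids) * ncol(ids), 33)
}

# Echoes the input token as a near-one-hot prediction.
echo_model <- function(ids, mask) {
  n <- nrow(ids) * ncol(ids)
  L <- matrix(-30, n, 33)
  L[cbind(seq_len(n), as.vector(t(ids)) + 1L)] <- 30
  L
}

# Always predicts one fixed token id.
constant_model <- function(token_id) {
  force(token_id)
  function(ids, mask) {
    n <- nrow(ids) * ncol(ids)
    L <- matrix(-30, n, 33)
    L[, token_id + 1L] <- 30
    L
  }
}

# Argmax uniform over the 20 canonical residue tokens (ids 4..23).
random_residue_model <- function(ids, mask) {
  n <- nrow(ids) * ncol(ids)
  L <- matrix(-1e9, n, 33)
  L[, 5:24] <- matrix(stats::rnorm(n * 20), n, 20)
  L
}

tiny_encoder <- function(seed = 11, pe_type = "rope", n_layers = 1L,
                         n_heads = 2L, hidden_size = 16L,
                         intermediate_size = 32L) {
  build_encoder(encoder_config(n_layers = n_layers, n_heads = n_heads,
                               hidden_size = hidden_size,
                               intermediate_size = intermediate_size,
                               pe_type = pe_type), seed = seed)
}
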