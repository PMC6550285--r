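# Shared fixtures: everything is generated in code at test time.

# Reduced-scale corpus family used across tests: 10 codes in 4 meta groups,
# short notes (mean 40 words), ~3 codes per note, dense keyword evidence.
small_gen_config <- function(seed = 11L, n_codes = 10L, n_meta = 4L,
                             subtypes_per_code = c(2L, 6L),
                             doc_len_mean = 40, doc_len_sd = 10, ...) {
  generator_config(n_codes = n_codes, n_meta = n_meta,
                   subtypes_per_code = subtypes_per_code,
                   background_vocab = 800L, doc_len_mean = doc_len_mean,
                   doc_len_sd = doc_len_sd, mean_labels = 3,
                   kw_injections = 8L, seed = seed, ...)
}

small_tagger_config <- function(seed = 14L, embedding_dim = 32L,
                                hidden_dim = 32L, dropout = 0, ...) {
  tagger_config(embedding_dim = embedding_dim, hidden_dim = hidden_dim,
                dropout = dropout, learning_rate = 3e-3, batch_size = 32L,
                seed = seed, ...)
}

# Hand-built 6-code / 3-meta ontology for unit tests.
toy_ontology <- function() {
  code_ontology(
    subtype_to_disease = c(S1 = 0L, S2 = 0L, S3 = 1L, S4 = 2L, S5 = 3L,
                           S6 = 4L, S7 = 5L, S8 = 5L),
    disease_to_meta = c(0L, 0L, 1L, 1L, 2L, 2L),
    strict = FALSE)
}

rand_probs_labels <- function(n, D, seed) {
  withr::with_seed(seed, {
    list(probs = matrix(runif(n * D), n, D),
         labels = matrix(rbinom(n * D, 1L, 0.3), n, D))
  })
}

# Central finite differences of f at x (vector or matrix), elementwise.
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}
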