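# Encoder and training-loop behaviour. Tiny parameter sets are built through
# the package's own initializer so shapes always match the config.

make_params <- function(cfg, n_ids = 8L, n_codes = 6L, seed = 1L) {
  withr::with_seed(seed, codetag:::init_params(cfg, n_ids, n_codes))
}

test_that("document encodings have the contracted shape and are deterministic", {
  for (bid in c(TRUE, FALSE)) {
    cfg <- small_tagger_config(bidirectional = bid, hidden_dim = 8L,
                               embedding_dim = 5L)
    params <- make_params(cfg)
    ids <- list(c(2L, 3L, 4L), c(5L, 2L))
    H1 <- codetag:::encoder_forward(params, ids, cfg)$H
    expect_equal(dim(H1), c(2L, if (bid) 16L else 8L))
    H2 <- codetag:::encoder_forward(params, ids, cfg)$H
    expect_identical(H1, H2)
  }
})

test_that("the encoder is order sensitive and rejects empty sequences", {
  cfg <- small_tagger_config(hidden_dim = 8L, embedding_dim = 5L)
  params <- make_params(cfg)
  a <- codetag:::encoder_forward(params, list(c(2L, 3L)), cfg)$H
  b <- codetag:::encoder_forward(params, list(c(3L, 2L)), cfg)$H
  expect_gt(max(abs(a - b)), 0)
  expect_error(codetag:::encoder_forward(params, list(integer()), cfg), "empty")
})

test_that("per-code probabilities follow the logistic readout", {
  cfg <- small_tagger_config(hidden_dim = 4L, embedding_dim = 3L)
  params <- make_params(cfg)
  # zero readout weights and bias give probability one half everywhere
  params$E_lab[] <- 0
  params$b_lab[] <- 0
  H <- codetag:::encoder_forward(params, list(c(2L, 3L)), cfg)$H
  expect_equal(as.numeric(codetag:::probs_from_H(params, H)), rep(0.5, 6))
  # raising one bias strictly raises that code's probability only
  params$b_lab[3] <- 1
  p2 <- codetag:::probs_from_H(params, H)
  expect_gt(p2[1, 3], 0.5)
  expect_equal(p2[1, -3], rep(0.5, 5))
})

test_that("probabilities are invariant to batch composition", {
  cfg <- small_tagger_config(hidden_dim = 8L, embedding_dim = 5L)
  params <- make_params(cfg, n_ids = 30L)
  withr::with_seed(2, {
    ids <- lapply(1:7, function(i) sample(2:30, sample(3:12, 1), replace = TRUE))
  })
  alone <- do.call(rbind, lapply(ids, function(x) {
    codetag:::predict_probs_params(params, list(x), cfg)
  }))
  together <- codetag:::predict_probs_params(params, ids, cfg)
  expect_equal(alone, together, tolerance = 1e-12)
})

test_that("encoder backpropagation matches finite differences through the whole chain", {
  cfg <- small_tagger_config(hidden_dim = 4L, embedding_dim = 3L, dropout = 0)
  params <- make_params(cfg, n_ids = 6L, n_codes = 4L, seed = 3L)
  ids <- list(c(2L, 3L, 4L), c(5L, 2L), c(3L, 3L, 3L, 6L))
  withr::with_seed(4, Y <- matrix(rbinom(12, 1, 0.5), 3, 4))
  loss_fn <- function(pp) {
    fw <- codetag:::encoder_forward(pp, ids, cfg, keep_cache = TRUE)
    bce_loss(codetag:::probs_from_H(pp, fw$H), Y)
  }
  fw <- codetag:::encoder_forward(params, ids, cfg, keep_cache = TRUE)
  p <- codetag:::probs_from_H(params, fw$H)
  dH <- ((p - Y) / length(p)) %*% params$E_lab
  enc <- codetag:::lstm_backward_cpp(params$Emb, params$W_f, params$U_f,
                                     params$W_b, params$U_b,
                                     fw$tokens, fw$lengths, TRUE, fw, dH)
  for (nm in c("Emb", "W_f", "U_f", "b_f", "W_b", "U_b", "b_b")) {
    gnum <- numeric_gradient(function(x) {
      pp <- params; pp[[nm]] <- x; loss_fn(pp)
    }, params[[nm]])
    expect_lt(max_rel_err(enc[[paste0("d", nm)]], gnum, floor = 1e-6), 1e-4)
  }
})

test_that("training reduces the loss on a small separable corpus across seeds", {
  synth <- generate_ontology(small_gen_config(seed = 41L))
  notes <- generate_corpus(synth, 220, seed = 42L)
  ok <- 0L
  for (s in 1:5) {
    cfg <- small_tagger_config(seed = 50L + s, hidden_dim = 16L,
                               embedding_dim = 16L, lambda_cluster = 0,
                               max_epochs = 3L, patience = 3L)
    fit <- train_tagger(notes[1:200, ], notes[201:220, ], synth$ontology, cfg)
    if (!is.unsorted(rev(fit$log$loss))) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("training is bitwise reproducible under a fixed seed", {
  synth <- generate_ontology(small_gen_config(seed = 43L))
  notes <- generate_corpus(synth, 150, seed = 44L)
  cfg <- small_tagger_config(seed = 45L, hidden_dim = 12L, embedding_dim = 12L,
                             dropout = 0.2, lambda_cluster = 0.1,
                             beta_meta = 0.1, max_epochs = 2L)
  f1 <- train_tagger(notes[1:130, ], notes[131:150, ], synth$ontology, cfg)
  f2 <- train_tagger(notes[1:130, ], notes[131:150, ], synth$ontology, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
})

test_that("zero-label notes are excluded from training with a warning", {
  synth <- generate_ontology(small_gen_config(seed = 46L))
  notes <- generate_corpus(synth, 60, seed = 47L)
  notes$labels[[1]] <- integer(10)
  cfg <- small_tagger_config(max_epochs = 1L, hidden_dim = 8L, embedding_dim = 8L)
  expect_warning(fit <- train_tagger(notes[1:50, ], notes[51:60, ],
                                     synth$ontology, cfg),
                 "zero-label")
  expect_equal(fit$n_train, 49L)
})

test_that("fitted taggers round-trip through the checkpoint format", {
  synth <- generate_ontology(small_gen_config(seed = 48L))
  notes <- generate_corpus(synth, 80, seed = 49L)
  cfg <- small_tagger_config(max_epochs = 1L, hidden_dim = 8L, embedding_dim = 8L)
  fit <- train_tagger(notes[1:70, ], notes[71:80, ], synth$ontology, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_tagger(fit, path)
  back <- read_tagger(path)
  expect_equal(back$params, fit$params)
  expect_equal(predict_probs(back, notes[1:5, ]), predict_probs(fit, notes[1:5, ]))
})

test_that("tidiers and predictions expose tibble interfaces", {
  synth <- generate_ontology(small_gen_config(seed = 51L))
  notes <- generate_corpus(synth, 80, seed = 52L)
  cfg <- small_tagger_config(max_epochs = 1L, hidden_dim = 8L, embedding_dim = 8L)
  fit <- train_tagger(notes[1:70, ], notes[71:80, ], synth$ontology, cfg)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10L)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  pr <- predict(fit, notes[1:4, ])
  expect_s3_class(pr, "tbl_df")
  expect_equal(dim(pr), c(4L, 11L))
  lab <- predict(fit, notes[1:4, ], type = "label")
  expect_true(all(unlist(lab[, -1]) %in% 0:1))
  expect_s3_class(autoplot(fit), "ggplot")
})
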