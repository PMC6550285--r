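test_that("per-code metrics honour the stated zero-division conventions", {
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  perfect <- per_code_metrics(y * 0.9 + 0.05, y)
  expect_equal(perfect$precision, c(1, 1))
  expect_equal(perfect$recall, c(1, 1))
  expect_equal(perfect$f1, c(1, 1))
  expect_equal(perfect$auc, c(1, 1))
  # all-negative predictions on a code with positives: recall 0, precision 0
  none <- per_code_metrics(matrix(0.1, 2, 2), y)
  expect_equal(none$precision, c(0, 0))
  expect_equal(none$recall, c(0, 0))
  expect_equal(none$f1, c(0, 0))
  # a code with no positives has undefined AUC
  y2 <- cbind(c(1, 0), c(0, 0))
  m <- per_code_metrics(matrix(runif(4), 2, 2), y2)
  expect_true(is.nan(m$auc[2]))
  expect_error(per_code_metrics(matrix(0.5, 2, 2), matrix(0L, 3, 2)), "shape")
})

test_that("metrics equal brute-force confusion-matrix and pairwise AUC oracles", {
  rl <- rand_probs_labels(50, 42, seed = 11)
  got <- per_code_metrics(rl$probs, rl$labels, threshold = 0.5)
  for (j in seq_len(42)) {
    p <- rl$probs[, j]; y <- rl$labels[, j]
    ph <- as.integer(p >= 0.5)
    tp <- sum(ph == 1 & y == 1); fp <- sum(ph == 1 & y == 0)
    fn <- sum(ph == 0 & y == 1)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    # pairwise comparison AUC with half credit for ties
    pos <- p[y == 1]; neg <- p[y == 0]
    auc <- if (length(pos) && length(neg)) {
      cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      mean(cmp)
    } else NaN
    expect_equal(got$precision[j], prec, tolerance = 1e-9)
    expect_equal(got$recall[j], rec, tolerance = 1e-9)
    expect_equal(got$f1[j], f1, tolerance = 1e-9)
    expect_equal(got$auc[j], auc, tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone score transformations", {
  rl <- rand_probs_labels(40, 5, seed = 12)
  a <- per_code_metrics(rl$probs, rl$labels)$auc
  b <- per_code_metrics(plogis(5 * rl$probs - 1), rl$labels)$auc
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("exact match counts only perfectly predicted label sets", {
  y <- rbind(c(1, 1, 1, 0), c(0, 1, 0, 0))
  expect_equal(exact_match(y, y), 1)
  # two of three true codes predicted -> not an exact match
  p <- rbind(c(1, 1, 0, 0), c(0, 1, 0, 0))
  expect_equal(exact_match(p, y), 0.5)
  withr::with_seed(13, {
    for (i in 1:10) {
      A <- matrix(rbinom(60, 1, 0.4), 10, 6)
      B <- matrix(rbinom(60, 1, 0.4), 10, 6)
      loop <- mean(vapply(1:10, function(r) all(A[r, ] == B[r, ]), TRUE))
      expect_equal(exact_match(A, B), loop)
    }
  })
})

test_that("exact match is bounded by mean per-document accuracy", {
  withr::with_seed(14, {
    A <- matrix(rbinom(200, 1, 0.4), 20, 10)
    B <- matrix(rbinom(200, 1, 0.4), 20, 10)
    acc <- mean(rowMeans(A == B))
    expect_lte(exact_match(A, B), acc)
    expect_lte(acc, 1)
  })
})

test_that("aggregation produces unweighted means and positive-count weighted means", {
  pc <- tibble::tibble(code = 0:1, n_pos = c(3L, 1L),
                       precision = c(1, 0), recall = c(1, 0),
                       f1 = c(1, 0), auc = c(1, 0.5))
  agg <- aggregate_metrics(pc)
  expect_equal(agg$f1_unweighted, 0.5)
  expect_equal(agg$f1_weighted, 0.75)
  # identical scores collapse both averages to the common value
  pc2 <- dplyr::mutate(pc, precision = 0.7, recall = 0.7, f1 = 0.7)
  agg2 <- aggregate_metrics(pc2)
  expect_equal(agg2$f1_unweighted, 0.7)
  expect_equal(agg2$f1_weighted, 0.7)
  # equal weights make the two averages coincide
  pc3 <- dplyr::mutate(pc, n_pos = 2L)
  agg3 <- aggregate_metrics(pc3)
  expect_equal(agg3$f1_weighted, agg3$f1_unweighted)
  # aggregates lie between the per-code extremes
  expect_true(agg$f1_weighted >= min(pc$f1) && agg$f1_weighted <= max(pc$f1))
})

test_that("F1 never exceeds the larger of precision and recall", {
  rl <- rand_probs_labels(30, 12, seed = 15)
  m <- per_code_metrics(rl$probs, rl$labels)
  expect_true(all(m$f1 <= pmax(m$precision, m$recall) + 1e-12))
})

test_that("the performance regression recovers planted coefficients", {
  # noiseless construction: F1 is an exact linear function of log10 N
  n_train <- c(10, 100, 1000, 5000, 20000)
  subc <- c(3, 9, 2, 7, 5)
  f1 <- 0.1 + 0.2 * log10(n_train)
  pc <- tibble::tibble(f1 = f1)
  # noiseless construction: lm warns about the perfect fit by design
  reg <- suppressWarnings(performance_regression(pc, n_train, subc))
  expect_equal(reg$estimate[reg$term == "log_n"], 0.2, tolerance = 1e-8)
  expect_equal(reg$estimate[reg$term == "n_subtypes"], 0, tolerance = 1e-8)
  # normal-equation oracle on a 5-point dataset
  withr::with_seed(16, y <- runif(5))
  reg2 <- performance_regression(tibble::tibble(f1 = y), n_train, subc)
  X <- cbind(1, log10(n_train), subc)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(reg2$estimate, as.numeric(beta), tolerance = 1e-8)
  # collinear covariates are refused
  expect_error(performance_regression(tibble::tibble(f1 = y),
                                      n_train, log10(n_train)),
               "collinear")
  expect_error(performance_regression(tibble::tibble(f1 = y[1:2]),
                                      n_train[1:2], subc[1:2]),
               "at least 3")
  expect_error(performance_regression(tibble::tibble(f1 = y),
                                      c(0, n_train[-1]), subc),
               "positive")
})

test_that("evaluation reports serialize and expose tidy interfaces", {
  synth <- generate_ontology(small_gen_config(seed = 61L))
  notes <- generate_corpus(synth, 80, seed = 62L)
  cfg <- small_tagger_config(max_epochs = 1L, hidden_dim = 8L, embedding_dim = 8L)
  fit <- train_tagger(notes[1:70, ], notes[71:80, ], synth$ontology, cfg)
  ev <- evaluate_tagger(fit, notes[71:80, ])
  expect_equal(nrow(tidy(ev)), 10L)
  gl <- glance(ev)
  expect_true(all(c("exact_match", "f1_weighted", "f1_unweighted") %in% names(gl)))
  expect_true(all(unlist(gl[, -(1:2)])[!is.nan(unlist(gl[, -(1:2)]))] >= 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(ev, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.tsv$", ".json", path)))
  agg <- jsonlite::read_json(sub("\\.tsv$", ".json", path))
  expect_equal(agg$exact_match, ev$exact_match)
  expect_s3_class(autoplot(ev), "ggplot")
})
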