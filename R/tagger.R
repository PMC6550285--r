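#' Tagger configuration
#'
#' Hyperparameters of the recurrent multilabel tagger. The architecture is
#' a word-embedding layer, a recurrent LSTM encoder run over the document
#' (bidirectionally by default), and one independent binary logistic
#' classifier per disease code whose weight rows act as disease-code
#' embeddings. With `lambda_cluster = 0` and `beta_meta = 0` the model is
#' exactly the plain BLSTM baseline (or the unidirectional LSTM baseline
#' with `bidirectional = FALSE`); positive weights switch on the
#' cluster-penalty and meta-disease loss variants respectively.
#'
#' @param embedding_dim Word-embedding dimension (default 100).
#' @param hidden_dim Hidden units per direction (default 256).
#' @param bidirectional Run the encoder in both directions (default TRUE).
#' @param dropout Dropout rate on the document representation (default 0.2).
#' @param lambda_cluster Cluster-penalty weight (default 0.1).
#' @param beta_meta Meta-disease loss weight (default 0).
#' @param margin Cluster-penalty margin (default 1).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param clip_norm Global gradient-norm clipping threshold (default 5;
#'   `Inf` disables). Standard stabilizer for recurrent training.
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Maximum training epochs (default 10).
#' @param patience Early-stopping patience on validation weighted F1
#'   (default 3).
#' @param max_len Token sequences are truncated from the tail at this
#'   length (default 512).
#' @param min_freq Vocabulary frequency cutoff (default 1).
#' @param threshold Probability threshold for binarizing predictions
#'   (default 0.5; exactly 0.5 predicts positive).
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @return A `tagger_config` list.
#' @export
tagger_config <- function(embedding_dim = 100L, hidden_dim = 256L,
                          bidirectional = TRUE, dropout = 0.2,
                          lambda_cluster = 0.1, beta_meta = 0,
                          margin = 1, learning_rate = 1e-3,
                          clip_norm = 5, batch_size = 32L, max_epochs = 10L,
                          patience = 3L, max_len = 512L, min_freq = 1L,
                          threshold = 0.5, seed = 1L) {
  if (lambda_cluster < 0 || beta_meta < 0) abort("loss weights must be non-negative")
  stopifnot(dropout >= 0, dropout < 1, margin > 0, batch_size >= 1)
  structure(as.list(environment()), class = "tagger_config")
}

init_params <- function(config, n_ids, n_codes) {
  E <- config$embedding_dim; H <- config$hidden_dim
  outdim <- if (config$bidirectional) 2L * H else H
  u <- function(r, c) matrix(runif(r * c, -0.08, 0.08), r, c)
  lstm_bias <- function() {
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
    b
  }
  p <- list(Emb = matrix(rnorm(n_ids * E, 0, 0.1), n_ids, E),
            W_f = u(4L * H, E), U_f = u(4L * H, H), b_f = lstm_bias(),
            E_lab = u(n_codes, outdim), b_lab = numeric(n_codes))
  if (config$bidirectional) {
    p$W_b <- u(4L * H, E); p$U_b <- u(4L * H, H); p$b_b <- lstm_bias()
  }
  p
}

pad_batch <- function(ids_list) {
  lens <- lengths(ids_list)
  if (any(lens == 0L)) abort("cannot encode an empty token sequence")
  T_max <- max(lens)
  toks <- matrix(0L, length(ids_list), T_max)
  for (r in seq_along(ids_list)) toks[r, seq_len(lens[r])] <- ids_list[[r]]
  list(tokens = toks, lengths = as.integer(lens))
}

encoder_forward <- function(params, ids_list, config, keep_cache = FALSE) {
  b <- pad_batch(ids_list)
  bid <- config$bidirectional
  out <- lstm_forward_cpp(params$Emb, params$W_f, params$U_f, params$b_f,
                          if (bid) params$W_b else params$W_f,
                          if (bid) params$U_b else params$U_f,
                          if (bid) params$b_b else params$b_f,
                          b$tokens, b$lengths, bid, keep_cache)
  c(out, b)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

probs_from_H <- function(params, H) {
  logits <- H %*% t(params$E_lab)
  logits <- sweep(logits, 2L, params$b_lab, "+")
  sigmoid(logits)
}

clip_gradients <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > clip_norm) grads <- lapply(grads, function(g) g * clip_norm / total)
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the multilabel note tagger
#'
#' Minibatch Adam training of the combined objective (joint binary
#' cross-entropy plus the optional cluster penalty and meta-disease loss),
#' with early stopping on validation weighted F1 and full seeding: two runs
#' with identical data, config and seed produce identical models. Notes
#' with all-zero label vectors are excluded from training. The vocabulary
#' is built from the training notes only unless one is supplied.
#'
#' @param train_notes,validation_notes Notes tibbles with `tokens` and
#'   `labels` columns.
#' @param ontology A [code_ontology()]; its code count fixes the label
#'   space and its meta grouping feeds the hierarchical losses.
#' @param config A [tagger_config()].
#' @param vocabulary Optional pre-built [build_vocabulary()] object.
#' @return A fitted `code_tagger`: best-validation parameters, config,
#'   vocabulary, ontology, and a per-epoch training log tibble.
#' @export
train_tagger <- function(train_notes, validation_notes, ontology,
                         config = tagger_config(), vocabulary = NULL) {
  keep <- vapply(train_notes$labels, function(y) sum(y) > 0L, logical(1))
  if (!all(keep)) {
    warn(sprintf("excluding %d zero-label note(s) from training", sum(!keep)))
    train_notes <- train_notes[keep, , drop = FALSE]
  }
  if (nrow(train_notes) == 0L || nrow(validation_notes) == 0L) {
    abort("training and validation splits must be nonempty")
  }
  if (is.null(vocabulary)) vocabulary <- build_vocabulary(train_notes, config$min_freq)
  D <- ontology$n_codes
  ids <- token_ids(train_notes$tokens, vocabulary, config$max_len)
  Y <- labels_matrix(train_notes)
  stopifnot(ncol(Y) == D)
  val_ids <- token_ids(validation_notes$tokens, vocabulary, config$max_len)
  val_Y <- labels_matrix(validation_notes)
  n <- length(ids)
  n_ids <- vocab_size(vocabulary) - 1L  # embedding rows: ids 1..V-1, pad = 0

  withr::with_seed(config$seed, {
    params <- init_params(config, n_ids, D)
    opt <- adam_init(params)
    log <- tibble::tibble()
    best <- list(f1 = -Inf, params = params, epoch = 0L)
    wait <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- c(total = 0, bce = 0, cluster = 0, meta = 0)
      for (bi in batches) {
        fw <- encoder_forward(params, ids[bi], config, keep_cache = TRUE)
        H <- fw$H
        keep_p <- 1 - config$dropout
        if (config$dropout > 0) {
          mask <- matrix(rbinom(length(H), 1L, keep_p), nrow(H)) / keep_p
          Hd <- H * mask
        } else Hd <- H
        p <- probs_from_H(params, Hd)
        yb <- Y[bi, , drop = FALSE]
        l_bce <- bce_loss(p, yb)
        l_cp <- if (config$lambda_cluster > 0)
          cluster_penalty(params$E_lab, ontology, config$margin) else 0
        l_meta <- if (config$beta_meta > 0) meta_loss(p, yb, ontology) else 0
        loss <- l_bce + config$lambda_cluster * l_cp + config$beta_meta * l_meta
        if (!is.finite(loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        }
        ep_loss <- ep_loss + c(loss, l_bce, l_cp, l_meta) * length(bi)
        # gradient at the logits: BCE and (chained through the logistic) meta
        dlogit <- (p - yb) / length(p)
        if (config$beta_meta > 0) {
          dP <- meta_loss_grad(p, yb, ontology)
          dlogit <- dlogit + config$beta_meta * dP * p * (1 - p)
        }
        gE_lab <- t(dlogit) %*% Hd
        if (config$lambda_cluster > 0) {
          # scale by the batch fraction so one epoch's accumulated penalty
          # gradient corresponds to lambda * L_cp, not batches * lambda * L_cp
          gE_lab <- gE_lab + config$lambda_cluster * (length(bi) / n) *
            cluster_penalty_grad(params$E_lab, ontology, config$margin)
        }
        grads <- list(E_lab = gE_lab, b_lab = colSums(dlogit))
        dH <- dlogit %*% params$E_lab
        if (config$dropout > 0) dH <- dH * mask
        enc <- lstm_backward_cpp(params$Emb, params$W_f, params$U_f,
                                 if (config$bidirectional) params$W_b else params$W_f,
                                 if (config$bidirectional) params$U_b else params$U_f,
                                 fw$tokens, fw$lengths, config$bidirectional,
                                 fw, dH)
        grads$Emb <- enc$dEmb
        grads$W_f <- enc$dW_f; grads$U_f <- enc$dU_f; grads$b_f <- as.numeric(enc$db_f)
        if (config$bidirectional) {
          grads$W_b <- enc$dW_b; grads$U_b <- enc$dU_b; grads$b_b <- as.numeric(enc$db_b)
        }
        grads <- clip_gradients(grads, config$clip_norm %||% Inf)
        upd <- adam_step(params, grads, opt, config$learning_rate)
        params <- upd$params; opt <- upd$state
      }
      ep_loss <- ep_loss / n
      val_probs <- predict_probs_params(params, val_ids, config)
      val_f1 <- weighted_f1(val_probs, val_Y, config$threshold)
      log <- dplyr::bind_rows(log, tibble::tibble(
        epoch = epoch, loss = ep_loss[["total"]], bce = ep_loss[["bce"]],
        cluster = ep_loss[["cluster"]], meta = ep_loss[["meta"]],
        val_weighted_f1 = val_f1))
      if (val_f1 > best$f1) {
        best <- list(f1 = val_f1, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(params = best$params, config = config,
                   vocabulary = vocabulary, ontology = ontology,
                   log = log, best_epoch = best$epoch,
                   n_train = n),
              class = "code_tagger")
  })
}

predict_probs_params <- function(params, ids_list, config, batch_size = 128L) {
  chunks <- split(seq_along(ids_list), ceiling(seq_along(ids_list) / batch_size))
  out <- lapply(chunks, function(ix) {
    fw <- encoder_forward(params, ids_list[ix], config, keep_cache = FALSE)
    probs_from_H(params, fw$H)
  })
  do.call(rbind, out)
}

weighted_f1 <- function(probs, labels, threshold = 0.5) {
  pc <- per_code_metrics(probs, labels, threshold)
  aggregate_metrics(pc)$f1_weighted
}

#' Encode documents into their fixed-length representations
#'
#' Runs the recurrent encoder and returns, per document, the concatenated
#' final states of the forward and backward passes (or the single final
#' state in unidirectional mode). Deterministic: dropout is disabled.
#'
#' @param model A fitted `code_tagger`.
#' @param notes Notes tibble with a `tokens` list-column.
#' @return Numeric matrix, one row per note.
#' @export
encode_documents <- function(model, notes) {
  ids <- token_ids(notes$tokens, model$vocabulary, model$config$max_len)
  chunks <- split(seq_along(ids), ceiling(seq_along(ids) / 128L))
  do.call(rbind, lapply(chunks, function(ix) {
    encoder_forward(model$params, ids[ix], model$config)$H
  }))
}

#' Per-code confidence scores for a set of notes
#'
#' For each document d and code c returns
#' `p = logistic(e_c . h_d + b_c)` where `h_d` is the document
#' representation and `e_c` the code's embedding (final-layer weight row).
#'
#' @inheritParams encode_documents
#' @return Numeric matrix (documents x codes) of probabilities.
#' @export
predict_probs <- function(model, notes) {
  ids <- token_ids(notes$tokens, model$vocabulary, model$config$max_len)
  predict_probs_params(model$params, ids, model$config)
}

#' Predict codes for new notes
#'
#' @param object A fitted `code_tagger`.
#' @param notes Notes tibble.
#' @param type `"prob"` for per-code probabilities, `"label"` for 0/1
#'   predictions at the config threshold (a probability of exactly the
#'   threshold predicts positive).
#' @param ... Unused.
#' @return A tibble with `id` and one column per disease code.
#' @export
predict.code_tagger <- function(object, notes, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  probs <- predict_probs(object, notes)
  if (type == "label") probs <- 1L * (probs >= object$config$threshold)
  colnames(probs) <- sprintf("code_%02d", seq_len(ncol(probs)) - 1L)
  dplyr::bind_cols(tibble::tibble(id = notes$id), tibble::as_tibble(probs))
}

#' @export
print.code_tagger <- function(x, ...) {
  cat(sprintf(
    "<code_tagger> %d codes, %s encoder (emb %d, hidden %d), lambda_cluster = %g, beta_meta = %g\n",
    x$ontology$n_codes,
    if (x$config$bidirectional) "bidirectional LSTM" else "LSTM",
    x$config$embedding_dim, x$config$hidden_dim,
    x$config$lambda_cluster, x$config$beta_meta))
  cat(sprintf("  trained %d epochs (best %d), best val weighted F1 %.3f\n",
              nrow(x$log), x$best_epoch, max(x$log$val_weighted_f1)))
  invisible(x)
}

#' @rdname codetag-tidiers
#' @method tidy code_tagger
#' @export
tidy.code_tagger <- function(x, ...) {
  tibble::tibble(
    disease_index = seq_len(x$ontology$n_codes) - 1L,
    disease_name = x$ontology$disease_names,
    meta_index = x$ontology$disease_to_meta,
    bias = x$params$b_lab,
    embedding_norm = sqrt(rowSums(x$params$E_lab^2)))
}

#' @rdname codetag-tidiers
#' @method glance code_tagger
#' @export
glance.code_tagger <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_weighted_f1 = max(x$log$val_weighted_f1),
    lambda_cluster = x$config$lambda_cluster,
    beta_meta = x$config$beta_meta,
    bidirectional = x$config$bidirectional)
}

#' @rdname codetag-tidiers
#' @param object A fitted `code_tagger` (autoplot method).
#' @method autoplot code_tagger
#' @export
autoplot.code_tagger <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("loss", "val_weighted_f1"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training trajectory")
}

#' Intra/inter meta-group embedding distance ratio
#'
#' Diagnostic for the cluster penalty: the ratio of the mean pairwise
#' distance between disease-code embeddings within the same meta group to
#' the mean distance across groups. The penalty should drive this ratio
#' down relative to an unregularized run.
#'
#' @param embeddings Embedding matrix, or a fitted `code_tagger`.
#' @param ontology A [code_ontology()]; taken from the model if omitted.
#' @return Scalar ratio.
#' @export
embedding_distance_ratio <- function(embeddings, ontology = NULL) {
  if (inherits(embeddings, "code_tagger")) {
    ontology <- embeddings$ontology
    embeddings <- embeddings$params$E_lab
  }
  g <- ontology$disease_to_meta
  d <- as.matrix(stats::dist(embeddings))
  same <- outer(g, g, "==")
  up <- upper.tri(d)
  mean(d[up & same]) / mean(d[up & !same])
}

#' Save / load a fitted tagger
#'
#' The checkpoint is a single JSON file holding the parameter tensors, the
#' config, the ontology, and the vocabulary.
#'
#' @param model A fitted `code_tagger`.
#' @param path File path.
#' @return `path` invisibly; `read_tagger` returns the `code_tagger`.
#' @export
write_tagger <- function(model, path) {
  ser <- list(
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), x = as.numeric(p)) else list(x = as.numeric(p))
    }),
    config = unclass(model$config),
    ontology = unclass(model$ontology),
    vocabulary = list(token = model$vocabulary$token, id = model$vocabulary$id,
                      freq = model$vocabulary$freq,
                      min_freq = attr(model$vocabulary, "min_freq")),
    log = model$log, best_epoch = model$best_epoch, n_train = model$n_train)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tagger
#' @export
read_tagger <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(ser$params, function(p) {
    if (!is.null(p$dim)) matrix(p$x, p$dim[1], p$dim[2]) else as.numeric(p$x)
  })
  ont <- ser$ontology
  ontology <- code_ontology(
    subtype_to_disease = setNames(as.integer(ont$subtype_to_disease),
                                  names(ont$subtype_to_disease)),
    disease_to_meta = as.integer(ont$disease_to_meta),
    disease_names = ont$disease_names, meta_names = ont$meta_names,
    other_index = ont$other_index,
    strict = (length(ont$disease_to_meta) == 42L))
  vocab <- structure(
    tibble::tibble(token = ser$vocabulary$token,
                   id = as.integer(ser$vocabulary$id),
                   freq = as.integer(ser$vocabulary$freq)),
    class = c("vocabulary", class(tibble::tibble())),
    pad_id = 0L, unk_id = 1L, min_freq = ser$vocabulary$min_freq)
  cfg <- structure(ser$config, class = "tagger_config")
  structure(list(params = params, config = cfg, vocabulary = vocab,
                 ontology = ontology, log = tibble::as_tibble(ser$log),
                 best_epoch = ser$best_epoch, n_train = ser$n_train),
            class = "code_tagger")
}
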