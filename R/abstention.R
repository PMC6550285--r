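# Selective prediction: deciding which documents to defer to human coders.
# A document's abstention priority score determines removal order; the
# retention curve tracks metric improvement as low-confidence documents
# are dropped.

#' Baseline abstention priority from raw confidences
#'
#' The no-learning baseline scores a document by how far its per-code
#' confidences sit from the decision threshold:
#' `priority = 1 - mean_c 2 |p_c - 0.5|`. A document whose confidences are
#' all near 0 or 1 gets priority 0 (kept longest); one whose confidences
#' hover at 0.5 gets priority 1 (dropped first).
#'
#' @param probs Probability matrix (documents x codes) or wide tibble.
#' @return Numeric vector of priorities in \[0, 1\], one per document.
#' @export
baseline_priority <- function(probs) {
  P <- as_prob_matrix(probs)
  1 - rowMeans(2 * abs(P - 0.5))
}

#' Fit a learned abstention estimator
#'
#' Learns a nonlinear function from the 42-dimensional confidence vector to
#' the document's expected error, giving the system flexibility to weigh
#' codes differently when judging whether to defer. The regression target
#' is the per-document error rate — the fraction of codes mispredicted at
#' the decision threshold — and the estimator is a single-hidden-layer
#' perceptron (logistic output, so predictions stay in \[0, 1\]). The fit
#' split must be disjoint from the final evaluation split.
#'
#' @param probs Confidence matrix on the fit split.
#' @param labels Binary label matrix on the fit split.
#' @param hidden Hidden-layer width (default 64).
#' @param threshold Decision threshold used to define errors.
#' @param code_weights Optional per-code weights for the error target
#'   (e.g. training-set positive counts). Weighting the target aligns the
#'   learned priority with weighted retention metrics; `NULL` weights all
#'   codes equally.
#' @param decay Weight decay passed to the perceptron fit.
#' @param maxit Maximum fit iterations per ensemble member.
#' @param n_restarts Number of random-restart perceptrons averaged at
#'   prediction time; averaging over restarts stabilizes the small-sample
#'   fit (default 5).
#' @param seed Seed; refits with the same seed are identical.
#' @return An `abstainer` object with a [predict()] method returning
#'   priorities (predicted error, higher = dropped earlier).
#' @export
fit_abstainer <- function(probs, labels, hidden = 64L, threshold = 0.5,
                          code_weights = NULL, decay = 1e-3, maxit = 500L,
                          n_restarts = 5L, seed = 1L) {
  P <- as_prob_matrix(probs)
  Y <- as_label_matrix(labels)
  if (nrow(P) < 50L) warn("abstention fit split has fewer than 50 documents")
  w <- if (is.null(code_weights)) rep(1, ncol(P)) else code_weights
  stopifnot(length(w) == ncol(P), all(w >= 0), any(w > 0))
  E <- ((P >= threshold) != (Y == 1L))
  err <- as.numeric(E %*% w) / sum(w)
  X <- abstainer_features(P)
  fits <- withr::with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      nnet::nnet(x = X, y = err, size = hidden, linout = FALSE,
                 decay = decay, maxit = maxit, trace = FALSE,
                 MaxNWts = 100000L)
    })
  })
  structure(list(fits = fits, hidden = hidden, threshold = threshold,
                 seed = seed, n_fit = nrow(P)),
            class = "abstainer")
}

#' @export
print.abstainer <- function(x, ...) {
  cat(sprintf("<abstainer> 1-hidden-layer perceptron (width %d, %d restarts), fit on %d documents\n",
              x$hidden, length(x$fits), x$n_fit))
  invisible(x)
}

#' @param object An `abstainer`.
#' @param probs Confidence matrix to score.
#' @param ... Unused.
#' @rdname fit_abstainer
#' @export
predict.abstainer <- function(object, probs, ...) {
  X <- abstainer_features(as_prob_matrix(probs))
  preds <- vapply(object$fits, function(f) as.numeric(predict(f, X)),
                  numeric(nrow(X)))
  rowMeans(rbind(preds))
}

abstainer_features <- function(P) P

#' @rdname codetag-tidiers
#' @method glance abstainer
#' @export
glance.abstainer <- function(x, ...) {
  tibble::tibble(hidden = x$hidden, n_fit = x$n_fit,
                 threshold = x$threshold, seed = x$seed)
}

#' Retention curve under an abstention policy
#'
#' For each dropped fraction f, removes the `ceiling(f * n)` documents with
#' the highest abstention priority (ties broken by document order) and
#' recomputes the weighted F1 and exact-match ratio on the retained
#' documents. A policy that drops erroneously tagged documents earlier
#' shows a steeper improvement as f grows.
#'
#' @param priorities Numeric vector of abstention priorities.
#' @param probs Confidence matrix for the same documents.
#' @param labels Binary label matrix.
#' @param fractions Dropped fractions (default 0, 0.1, ..., 0.9).
#' @param threshold Decision threshold.
#' @param method Label stored in the `method` column of the result.
#' @return A `retention_curve` tibble: `fraction`, `n_retained`,
#'   `weighted_f1`, `exact_match`, `method`.
#' @export
retention_curve <- function(priorities, probs, labels,
                            fractions = seq(0, 0.9, by = 0.1),
                            threshold = 0.5, method = "custom") {
  P <- as_prob_matrix(probs)
  Y <- as_label_matrix(labels)
  n <- nrow(P)
  stopifnot(length(priorities) == n, all(fractions >= 0), all(fractions < 1))
  ord <- order(priorities, decreasing = TRUE)  # stable: ties keep document order
  out <- purrr::map_dfr(fractions, function(f) {
    n_drop <- ceiling(f * n)
    keep <- if (n_drop > 0) setdiff(seq_len(n), ord[seq_len(n_drop)]) else seq_len(n)
    pc <- per_code_metrics(P[keep, , drop = FALSE], Y[keep, , drop = FALSE], threshold)
    tibble::tibble(
      fraction = f, n_retained = length(keep),
      weighted_f1 = aggregate_metrics(pc)$f1_weighted,
      exact_match = exact_match(1L * (P[keep, , drop = FALSE] >= threshold),
                                Y[keep, , drop = FALSE]))
  })
  out$method <- method
  class(out) <- c("retention_curve", class(out))
  out
}

#' @rdname codetag-tidiers
#' @method autoplot retention_curve
#' @export
autoplot.retention_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("weighted_f1", "exact_match"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$value,
                                   colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "dropped fraction", y = NULL,
                  title = "Retention curves under abstention")
}

#' Compare abstention policies end to end
#'
#' Convenience wrapper reproducing the standard comparison: fits the
#' learned abstainer on a fit split, scores an evaluation split with both
#' the learned priorities and the confidence-margin baseline, and returns
#' the two retention curves stacked.
#'
#' @param model A fitted `code_tagger`.
#' @param fit_notes Notes for fitting the abstainer (disjoint from
#'   `eval_notes`).
#' @param eval_notes Notes for the retention curves.
#' @param fractions Dropped fractions.
#' @param seed Seed for the abstainer fit.
#' @return A `retention_curve` tibble with `method` in
#'   `c("learned", "baseline")`.
#' @export
compare_abstention <- function(model, fit_notes, eval_notes,
                               fractions = seq(0, 0.9, by = 0.1), seed = 1L) {
  thr <- model$config$threshold
  p_fit <- predict_probs(model, fit_notes)
  abst <- fit_abstainer(p_fit, labels_matrix(fit_notes), threshold = thr,
                        seed = seed)
  p_eval <- predict_probs(model, eval_notes)
  Y <- labels_matrix(eval_notes)
  out <- dplyr::bind_rows(
    retention_curve(predict(abst, p_eval), p_eval, Y, fractions, thr, "learned"),
    retention_curve(baseline_priority(p_eval), p_eval, Y, fractions, thr, "baseline"))
  class(out) <- c("retention_curve", setdiff(class(out), "retention_curve"))
  out
}
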