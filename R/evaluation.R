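# Multilabel evaluation protocol: per-code P/R/F1/AUC, exact-match ratio,
# unweighted and weighted aggregates, and the performance-heterogeneity
# regression of per-code F1 on training-set size and subtype diversity.

as_prob_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    return(as.matrix(x[, num, drop = FALSE]))
  }
  rbind(x)
}

as_label_matrix <- function(x) {
  if (is.data.frame(x) && !is.null(x$labels)) return(labels_matrix(x))
  m <- as_prob_matrix(x)
  storage.mode(m) <- "integer"
  m
}

# Mann-Whitney AUC with midrank tie handling; NaN when one class is absent.
auc_rank <- function(scores, y) {
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NaN)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-code precision, recall, F1 and AUC
#'
#' Binarizes the per-code probabilities at `threshold` (a probability equal
#' to the threshold predicts positive) and computes, for each code,
#' precision TP/(TP+FP), recall TP/(TP+FN), their harmonic mean F1, and
#' the area under the ROC curve via the midrank Mann-Whitney statistic.
#' Zero denominators give 0 (stated convention); AUC is `NaN`, and is
#' excluded from averages, for codes with no positive or no negative
#' examples in the evaluation set.
#'
#' @param probs Probability matrix (documents x codes), or the wide tibble
#'   from [predict.code_tagger()].
#' @param labels Binary label matrix, or a notes tibble with a `labels`
#'   list-column.
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return Tibble with one row per code: `code`, `n_pos`, `precision`,
#'   `recall`, `f1`, `auc`.
#' @export
per_code_metrics <- function(probs, labels, threshold = 0.5) {
  P <- as_prob_matrix(probs)
  Y <- as_label_matrix(labels)
  if (!all(dim(P) == dim(Y))) abort("probability and label matrices must match in shape")
  stopifnot(threshold > 0, threshold < 1)
  pred <- P >= threshold
  purrr::map_dfr(seq_len(ncol(P)), function(j) {
    y <- Y[, j]; ph <- pred[, j]
    tp <- sum(ph & y == 1L); fp <- sum(ph & y == 0L); fn <- sum(!ph & y == 1L)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(code = j - 1L, n_pos = sum(y == 1L),
                   precision = prec, recall = rec, f1 = f1,
                   auc = auc_rank(P[, j], y))
  })
}

#' Exact-match ratio
#'
#' Fraction of documents whose predicted code set equals the true set
#' exactly: a note with three true codes counts only if exactly those
#' three codes, no more and no less, are predicted.
#'
#' @param predicted Binary prediction matrix (or wide tibble).
#' @param truth Binary label matrix (or notes tibble).
#' @return Scalar fraction in \[0, 1\].
#' @export
exact_match <- function(predicted, truth) {
  P <- as_label_matrix(predicted)
  Y <- as_label_matrix(truth)
  if (!all(dim(P) == dim(Y))) abort("prediction and label matrices must match in shape")
  mean(rowSums(P != Y) == 0L)
}

#' Aggregate per-code metrics
#'
#' Two summaries of the per-code table: the unweighted arithmetic mean over
#' all codes, and the mean weighted by each code's positive-example count
#' in the evaluation set. AUC averages skip codes where AUC is undefined.
#'
#' @param per_code Tibble from [per_code_metrics()].
#' @return One-row tibble with `precision_unweighted`, `precision_weighted`,
#'   `recall_unweighted`, ..., `auc_weighted`.
#' @export
aggregate_metrics <- function(per_code) {
  w <- per_code$n_pos
  wmean <- function(x) {
    ok <- is.finite(x) & w > 0
    if (!any(ok)) return(NaN)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  umean <- function(x) mean(x[is.finite(x)])
  tibble::tibble(
    precision_unweighted = umean(per_code$precision),
    precision_weighted = wmean(per_code$precision),
    recall_unweighted = umean(per_code$recall),
    recall_weighted = wmean(per_code$recall),
    f1_unweighted = umean(per_code$f1),
    f1_weighted = wmean(per_code$f1),
    auc_unweighted = umean(per_code$auc),
    auc_weighted = wmean(per_code$auc))
}

#' Regression of per-code F1 on training size and subtype diversity
#'
#' Ordinary least squares of per-code F1 on the log of the number of
#' training examples and the number of distinct subtypes binned into each
#' code. A negative subtype coefficient indicates that codes realized by
#' more diverse lower-level descriptions are harder to tag, over and above
#' their frequency.
#'
#' @param per_code Tibble with `f1` (e.g. from [per_code_metrics()]).
#' @param n_train Per-code positive training-example counts (> 0).
#' @param n_subtypes Per-code distinct subtype counts (e.g. from
#'   [count_subtypes()]).
#' @param log_base Base of the log transform on `n_train` (default 10).
#' @return Tibble of coefficients: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, with the fitted `lm` as attribute `"fit"`.
#' @export
performance_regression <- function(per_code, n_train, n_subtypes, log_base = 10) {
  stopifnot(length(n_train) == nrow(per_code),
            length(n_subtypes) == nrow(per_code))
  if (nrow(per_code) < 3L) abort("need at least 3 codes for the regression")
  if (any(n_train <= 0)) abort("n_train must be positive to take logs")
  df <- data.frame(f1 = per_code$f1, log_n = log(n_train, log_base),
                   n_subtypes = n_subtypes)
  fit <- lm(f1 ~ log_n + n_subtypes, data = df)
  if (any(is.na(stats::coef(fit)))) abort("collinear covariates in performance regression")
  sm <- summary(fit)$coefficients
  out <- tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                        std.error = unname(sm[, 2]),
                        statistic = unname(sm[, 3]),
                        p.value = unname(sm[, 4]))
  attr(out, "fit") <- fit
  out
}

#' Evaluate a fitted tagger on a note collection
#'
#' Computes the full evaluation report: the per-code table, the exact-match
#' ratio, and the unweighted/weighted aggregates.
#'
#' @param model A fitted `code_tagger`.
#' @param notes Notes tibble with `tokens` and `labels`.
#' @param threshold Decision threshold (defaults to the model's).
#' @return A `tag_eval` object; see [tidy()] / [glance()] methods.
#' @export
evaluate_tagger <- function(model, notes, threshold = model$config$threshold) {
  probs <- predict_probs(model, notes)
  Y <- labels_matrix(notes)
  pc <- per_code_metrics(probs, Y, threshold)
  pc$disease_name <- model$ontology$disease_names
  structure(list(per_code = pc,
                 aggregates = aggregate_metrics(pc),
                 exact_match = exact_match(1L * (probs >= threshold), Y),
                 n_documents = nrow(notes), threshold = threshold),
            class = "tag_eval")
}

#' @export
print.tag_eval <- function(x, ...) {
  cat(sprintf("<tag_eval> %d documents, %d codes, threshold %.2f\n",
              x$n_documents, nrow(x$per_code), x$threshold))
  cat(sprintf("  exact match %.3f | weighted F1 %.3f | unweighted F1 %.3f\n",
              x$exact_match, x$aggregates$f1_weighted, x$aggregates$f1_unweighted))
  invisible(x)
}

#' @rdname codetag-tidiers
#' @method tidy tag_eval
#' @export
tidy.tag_eval <- function(x, ...) x$per_code

#' @rdname codetag-tidiers
#' @method glance tag_eval
#' @export
glance.tag_eval <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(exact_match = x$exact_match,
                                  n_documents = x$n_documents),
                   x$aggregates)
}

#' @rdname codetag-tidiers
#' @method autoplot tag_eval
#' @export
autoplot.tag_eval <- function(object, ...) {
  df <- dplyr::filter(object$per_code, .data$n_pos > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$n_pos), y = .data$f1)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "log10 positive examples", y = "per-code F1",
                  title = "Per-code F1 vs code frequency")
}

#' Serialize an evaluation report
#'
#' Writes the per-code table as TSV and the aggregate block (including the
#' exact-match ratio) as JSON alongside it.
#'
#' @param report A `tag_eval`.
#' @param path Output TSV path; the JSON goes to `path` with extension
#'   `.json`.
#' @return `path` invisibly.
#' @export
write_eval_report <- function(report, path) {
  readr::write_tsv(report$per_code, path)
  agg <- c(list(exact_match = report$exact_match,
                n_documents = report$n_documents),
           as.list(report$aggregates))
  jsonlite::write_json(agg, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
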