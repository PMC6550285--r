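# Training objectives. All three losses are also differentiated analytically
# here; the *_grad functions return the exact gradient used by the training
# loop (chained through the logistic link there) and are validated against
# central finite differences in the test suite.

PROB_EPS <- 1e-7

clamp_probs <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

#' Joint binary cross-entropy loss
#'
#' The tagger is a bank of independent per-code binary classifiers trained
#' jointly: the loss is the mean over documents and codes of
#' `-[y log p + (1 - y) log(1 - p)]`, with probabilities clamped away from
#' 0 and 1 by `1e-7`.
#'
#' @param probs Numeric matrix (documents x codes) of predicted
#'   probabilities, or a single probability vector.
#' @param labels Binary matrix (or vector) of the same shape.
#' @return Scalar loss.
#' @export
bce_loss <- function(probs, labels) {
  probs <- rbind(probs); labels <- rbind(labels)
  stopifnot(all(dim(probs) == dim(labels)))
  if (!all(labels %in% c(0, 1))) abort("labels must be binary")
  p <- clamp_probs(probs)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' @rdname bce_loss
#' @return `bce_grad`: matrix of `d loss / d probs`.
#' @export
bce_grad <- function(probs, labels) {
  probs <- rbind(probs); labels <- rbind(labels)
  p <- clamp_probs(probs)
  g <- (p - labels) / (p * (1 - p)) / length(p)
  # clamped region has zero gradient
  g[probs < PROB_EPS | probs > 1 - PROB_EPS] <- 0
  g
}

#' Cluster penalty on disease-code embeddings
#'
#' An L2-based objective on the final-layer weight rows (the disease-code
#' embeddings) that encodes expert-defined label similarity: embeddings of
#' codes in the same meta-disease are pulled together, embeddings of codes
#' in different meta-diseases are pushed at least a margin `m` apart.
#' Concretely,
#' `L = mean_intra ||e_i - e_j||^2 + mean_inter max(0, m - ||e_i - e_j||)^2`
#' where the first mean runs over all within-group pairs pooled across
#' groups (groups of size 1 contribute none) and the second over all
#' between-group pairs.
#'
#' @param embeddings Numeric matrix, one row per disease code.
#' @param ontology A [code_ontology()] supplying the meta-group partition.
#' @param margin Inter-group margin `m` (> 0, default 1).
#' @return Scalar penalty.
#' @export
cluster_penalty <- function(embeddings, ontology, margin = 1) {
  cp_terms(embeddings, ontology, margin)$loss
}

#' @rdname cluster_penalty
#' @return `cluster_penalty_grad`: matrix of `d penalty / d embeddings`.
#' @export
cluster_penalty_grad <- function(embeddings, ontology, margin = 1) {
  cp_terms(embeddings, ontology, margin, grad = TRUE)$grad
}

cp_terms <- function(embeddings, ontology, margin, grad = FALSE) {
  stopifnot(margin > 0)
  D <- nrow(embeddings)
  if (D != ontology$n_codes) abort("embedding rows must match the code count")
  if (ontology$n_meta < 2L) abort("cluster penalty needs at least 2 meta groups")
  g <- ontology$disease_to_meta
  # pairwise squared distances via the Gram matrix
  sq <- rowSums(embeddings^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(embeddings)
  d2[d2 < 0] <- 0
  same <- outer(g, g, "==")
  up <- upper.tri(d2)
  intra <- up & same
  inter <- up & !same
  n_intra <- sum(intra)
  n_inter <- sum(inter)
  d1 <- sqrt(d2)
  hinge <- pmax(0, margin - d1)
  loss <- (if (n_intra > 0) sum(d2[intra]) / n_intra else 0) +
    sum(hinge[inter]^2) / n_inter
  if (!grad) return(list(loss = loss))
  # coefficient c_ij on (e_i - e_j) per pair; gradient rows via weighted sums
  C <- matrix(0, D, D)
  if (n_intra > 0) C[intra] <- 2 / n_intra
  active <- inter & hinge > 0 & d1 > 1e-12
  C[active] <- -2 * hinge[active] / d1[active] / n_inter
  C <- C + t(C)  # symmetric full coefficient matrix
  G <- (rowSums(C) * embeddings) - C %*% embeddings
  list(loss = loss, grad = G)
}

#' Meta-disease prediction loss (noisy-OR aggregation)
#'
#' Encourages correct predictions at the meta-disease level as well as the
#' code level. A meta-disease is present iff any of its member codes is
#' present, so its predicted probability is the noisy-OR of the member
#' code probabilities, `q_g = 1 - prod_{d in g} (1 - p_d)`, and its label
#' is the OR of the member labels. The loss is the mean binary
#' cross-entropy between `q_g` and the meta labels over documents and the
#' meta groups.
#'
#' @inheritParams bce_loss
#' @param ontology A [code_ontology()].
#' @return Scalar loss.
#' @export
meta_loss <- function(probs, labels, ontology) {
  mp <- meta_probs(rbind(probs), ontology)
  ml <- meta_labels(rbind(labels), ontology)
  bce_loss(mp, ml)
}

#' @rdname meta_loss
#' @return `meta_probs`: matrix (documents x meta groups) of noisy-OR
#'   probabilities; `meta_labels`: the OR-aggregated binary meta labels.
#' @export
meta_probs <- function(probs, ontology) {
  probs <- rbind(probs)
  groups <- meta_groups(ontology)
  if (any(lengths(groups) == 0L)) abort("every meta group must contain a code")
  out <- vapply(groups, function(d) {
    1 - apply(1 - probs[, d + 1L, drop = FALSE], 1, prod)
  }, numeric(nrow(probs)))
  out <- rbind(out)
  dimnames(out) <- NULL
  out
}

#' @rdname meta_loss
#' @export
meta_labels <- function(labels, ontology) {
  labels <- rbind(labels)
  groups <- meta_groups(ontology)
  out <- vapply(groups, function(d) {
    as.integer(rowSums(labels[, d + 1L, drop = FALSE]) > 0)
  }, integer(nrow(labels)))
  out <- rbind(out)
  dimnames(out) <- NULL
  out
}

#' @rdname meta_loss
#' @return `meta_loss_grad`: matrix of `d loss / d probs` (code-level).
#' @export
meta_loss_grad <- function(probs, labels, ontology) {
  probs <- rbind(probs); labels <- rbind(labels)
  q <- meta_probs(probs, ontology)
  Y <- meta_labels(labels, ontology)
  qc <- clamp_probs(q)
  dLdq <- (qc - Y) / (qc * (1 - qc)) / length(q)
  dLdq[q < PROB_EPS | q > 1 - PROB_EPS] <- 0
  groups <- meta_groups(ontology)
  G <- matrix(0, nrow(probs), ncol(probs))
  for (gi in seq_along(groups)) {
    d <- groups[[gi]] + 1L
    # dq/dp_d = prod_{d' != d} (1 - p_{d'})
    for (j in d) {
      others <- setdiff(d, j)
      pr <- if (length(others)) {
        apply(1 - probs[, others, drop = FALSE], 1, prod)
      } else rep(1, nrow(probs))
      G[, j] <- G[, j] + dLdq[, gi] * pr
    }
  }
  G
}

#' Combined training objective
#'
#' `L = L_bce + lambda_cluster * L_cluster + beta_meta * L_meta`. With both
#' weights at zero this is exactly the joint BCE baseline; the two
#' hierarchical terms are independently switchable, giving the
#' cluster-penalty variant, the meta-loss variant, or both at once.
#'
#' @inheritParams bce_loss
#' @param embeddings Disease-code embedding matrix (final-layer weights).
#' @param ontology A [code_ontology()].
#' @param lambda_cluster Cluster-penalty weight (>= 0).
#' @param beta_meta Meta-loss weight (>= 0).
#' @param margin Cluster-penalty margin.
#' @return Scalar total loss, with components as attribute `"components"`.
#' @export
total_loss <- function(probs, labels, embeddings, ontology,
                       lambda_cluster = 0, beta_meta = 0, margin = 1) {
  if (lambda_cluster < 0 || beta_meta < 0) abort("loss weights must be non-negative")
  l_bce <- bce_loss(probs, labels)
  l_cp <- if (lambda_cluster > 0) cluster_penalty(embeddings, ontology, margin) else 0
  l_meta <- if (beta_meta > 0) meta_loss(probs, labels, ontology) else 0
  total <- l_bce + lambda_cluster * l_cp + beta_meta * l_meta
  attr(total, "components") <- c(bce = l_bce, cluster = l_cp, meta = l_meta)
  total
}
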