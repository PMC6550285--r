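# codetag

Multilabel diagnosis-code tagging for clinical free text, with
hierarchical label-similarity training objectives, a learned abstention
wrapper, a full multilabel evaluation protocol, and a synthetic corpus
generator for cross-hospital domain-shift experiments.

## Who this is for

Clinical NLP researchers and informatics teams who want to (a) train and
evaluate an automated coder that assigns top-level diagnosis codes (e.g. a
SNOMED-CT rollup) to free-text notes, (b) study how hierarchical structure
among the labels can regularize such a model, (c) let the system defer
low-confidence notes to human coders, and (d) do all of this reproducibly
on synthetic corpora when the real coded corpora are restricted.

## The model

Notes are tokenized, embedded, and encoded by a bidirectional LSTM; the
document representation `h` is the concatenation of the two final hidden
states. Each of the D disease codes has an independent logistic head

```
p_d = sigmoid(e_d · h + b_d)
```

whose weight row `e_d` is the code's embedding. Training minimizes

```
L = L_BCE + lambda · L_cluster + beta · L_meta
```

* `L_BCE` — joint binary cross-entropy over documents and codes;
* `L_cluster` — an L2 objective on the code embeddings:
  `mean_intra ‖e_i − e_j‖² + mean_inter max(0, m − ‖e_i − e_j‖)²`,
  pulling codes of the same meta-disease together and pushing codes of
  different meta-diseases at least a margin `m` apart;
* `L_meta` — noisy-OR meta-disease prediction:
  `q_g = 1 − Π_{d∈g}(1 − p_d)` scored by cross-entropy against the OR of
  the member labels.

`lambda = beta = 0` is the plain BLSTM baseline; `bidirectional = FALSE`
gives the unidirectional LSTM baseline. The recurrent encoder (forward and
backward passes plus full backpropagation through time) is implemented in
RcppArmadillo; losses, gradients, and the training loop are R.

Evaluation follows the standard multilabel protocol: per-code precision,
recall, F1 and midrank AUC; the exact-match ratio; unweighted and
positive-count-weighted aggregates; and an OLS regression of per-code F1 on
log training count and subtype diversity. Abstention compares a
no-learning confidence-margin priority against a learned estimator (an
ensemble of small perceptrons regressing per-document error on the
confidence vector) via retention curves over dropped fractions 0–0.9.

## Worked example

A complete run on a reduced synthetic task — 10 codes in 4 meta groups,
2,000 notes, no label noise:

```r
library(codetag)

cfg <- generator_config(n_codes = 10, n_meta = 4, subtypes_per_code = c(2, 6),
                        background_vocab = 800, doc_len_mean = 40,
                        doc_len_sd = 10, mean_labels = 3, kw_injections = 8,
                        seed = 1)
synth <- generate_ontology(cfg)
#> <synthetic_ontology> 10 codes / 4 metas, 37 subtypes, seed 1

notes <- generate_corpus(synth, 2000, seed = 2)
splits <- split_corpus(notes, c(0.9, 0.05, 0.05), seed = 3)

fit <- train_tagger(splits$train, splits$validation, synth$ontology,
                    tagger_config(embedding_dim = 32, hidden_dim = 48,
                                  dropout = 0, lambda_cluster = 0.1,
                                  learning_rate = 3e-3, max_epochs = 45,
                                  patience = 12, seed = 4))
fit
#> <code_tagger> 10 codes, bidirectional LSTM encoder (emb 32, hidden 48), lambda_cluster = 0.1, beta_meta = 0
#>   trained 45 epochs (best 39), best val weighted F1 0.993

evaluate_tagger(fit, splits$test)
#> <tag_eval> 100 documents, 10 codes, threshold 0.50
#>   exact match 0.940 | weighted F1 0.990 | unweighted F1 0.989
```

The exact-match ratio is the fraction of notes whose predicted code set
equals the true set exactly; weighted/unweighted F1 average the per-code F1
with and without positive-count weights. Applying the cross-hospital shift
transform (15.4% out-of-vocabulary injection, 30% of subtypes swapped for
novel ones) to the same test notes shows the expected degradation:

```r
shifted <- apply_domain_shift(splits$test,
                              shift_config(oov_prob = 0.154,
                                           subtype_swap = 0.3, seed = 5),
                              synth)
glance(evaluate_tagger(fit, shifted))[, c("exact_match", "f1_weighted")]
#> # A tibble: 1 × 2
#>   exact_match f1_weighted
#>         <dbl>       <dbl>
#> 1        0.44       0.848
```

Abstention: fit the learned estimator on the validation split and compare
retention curves against the confidence-margin baseline:

```r
curves <- compare_abstention(fit, splits$validation, splits$test, seed = 6)
head(dplyr::filter(curves, method == "learned"), 3)
#> # A tibble: 3 × 5
#>   fraction n_retained weighted_f1 exact_match method
#>      <dbl>      <int>       <dbl>       <dbl> <chr>
#> 1      0          100       0.990       0.94  learned
#> 2      0.1         90       0.992       0.956 learned
#> 3      0.2         80       0.991       0.95  learned
autoplot(curves)
```

`tidy()`, `glance()` and `autoplot()` methods are provided for fitted
taggers, evaluation reports and retention curves. A thin command-line
front-end with `simulate`, `train`, `predict` and `abstain` subcommands is
installed at `inst/cli/codetag.R`.

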