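#' Tokenize clinical text
#'
#' Deterministic whitespace-and-punctuation tokenizer: lowercases, splits on
#' any run of characters that is neither alphanumeric, and drops the
#' punctuation itself. Intentionally simple so that vocabulary overlap
#' between domains is a pure function of token identity, which is what the
#' cross-hospital shift analysis measures.
#'
#' @param text Character vector of raw note texts.
#' @return For a single string, a character vector of tokens; for a vector,
#'   a list of token vectors.
#' @export
tokenize <- function(text) {
  split_one <- function(x) {
    toks <- stringr::str_split_1(stringr::str_to_lower(x), "[^a-z0-9]+")
    toks[nzchar(toks)]
  }
  if (length(text) == 1L) split_one(text) else lapply(text, split_one)
}

#' Build a vocabulary from training notes
#'
#' Assigns contiguous integer ids to every token whose corpus frequency
#' meets `min_freq`. Ids 0 and 1 are reserved for padding and unknown
#' tokens; real tokens start at id 2, ordered by descending frequency then
#' alphabetically (deterministic). The vocabulary must be built from the
#' training split only, so that out-of-vocabulary rates on other domains
#' are meaningful.
#'
#' @param notes Notes tibble with a `tokens` list-column, or a list of
#'   token vectors.
#' @param min_freq Minimum corpus frequency for a token to receive an id.
#' @return A `vocabulary` object: tibble of `token`, `id`, `freq` with
#'   attributes `pad_id` (0), `unk_id` (1) and `min_freq`.
#' @export
build_vocabulary <- function(notes, min_freq = 1L) {
  stopifnot(min_freq >= 1L)
  toks <- if (is.data.frame(notes)) notes$tokens else notes
  toks <- unlist(toks, use.names = FALSE)
  if (length(toks) == 0L) abort("cannot build a vocabulary from an empty corpus")
  freq <- table(toks)
  keep <- freq[freq >= min_freq]
  ord <- order(-as.integer(keep), names(keep), method = "radix")
  tbl <- tibble::tibble(
    token = names(keep)[ord],
    id = seq_along(keep) + 1L,
    freq = as.integer(keep)[ord])
  structure(tbl, class = c("vocabulary", class(tbl)),
            pad_id = 0L, unk_id = 1L, min_freq = as.integer(min_freq))
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d tokens (+ pad, unk), min_freq = %d\n",
              nrow(x), attr(x, "min_freq")))
  invisible(x)
}

#' Vocabulary size including the reserved pad and unknown ids
#' @param vocabulary A [build_vocabulary()] object.
#' @export
vocab_size <- function(vocabulary) nrow(vocabulary) + 2L

#' Map token sequences to integer id sequences
#'
#' Unknown tokens map to the reserved unknown id; sequences longer than
#' `max_len` are truncated from the tail.
#'
#' @param tokens A token vector or list of token vectors.
#' @param vocabulary A [build_vocabulary()] object.
#' @param max_len Maximum sequence length (default 512).
#' @return Integer vector or list of integer vectors (0-based external ids:
#'   unknown = 1, known tokens >= 2).
#' @export
token_ids <- function(tokens, vocabulary, max_len = 512L) {
  lut <- setNames(vocabulary$id, vocabulary$token)
  unk <- attr(vocabulary, "unk_id")
  map_one <- function(tk) {
    ids <- unname(lut[tk])
    ids[is.na(ids)] <- unk
    head(as.integer(ids), max_len)
  }
  if (is.list(tokens)) lapply(tokens, map_one) else map_one(tokens)
}

#' Save / load a vocabulary as token TAB id
#' @inheritParams token_ids
#' @param path File path.
#' @return `path` invisibly; `read_vocabulary` returns a `vocabulary`.
#' @export
write_vocabulary <- function(vocabulary, path) {
  readr::write_tsv(tibble::tibble(token = vocabulary$token, id = vocabulary$id,
                                  freq = vocabulary$freq), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = "cii")
  structure(tibble::as_tibble(tbl), class = c("vocabulary", class(tibble::tibble())),
            pad_id = 0L, unk_id = 1L, min_freq = NA_integer_)
}

#' Split a corpus into train / validation / test
#'
#' Deterministic seeded shuffle followed by a disjoint, exhaustive
#' partition. Validation and test sizes are the fractions rounded to
#' nearest; the remainder goes to train, so 100 notes under the default
#' 0.9/0.05/0.05 split give 90/5/5.
#'
#' @param notes Notes tibble.
#' @param fractions Numeric length-3 vector `(train, validation, test)`
#'   summing to 1; default `c(0.9, 0.05, 0.05)`.
#' @param seed Integer seed for the shuffle.
#' @return Named list of three tibbles: `train`, `validation`, `test`.
#' @export
split_corpus <- function(notes, fractions = c(0.9, 0.05, 0.05), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0)) {
    abort("fractions must be three non-negative numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) abort("fractions must sum to 1")
  n <- nrow(notes)
  if (n < 3L) abort("need at least 3 notes to split")
  ord <- withr::with_seed(seed, sample.int(n))
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1L) abort("train fraction leaves no training notes")
  idx <- list(train = ord[seq_len(n_train)],
              validation = ord[n_train + seq_len(n_val)],
              test = ord[n_train + n_val + seq_len(n_test)])
  lapply(idx, function(i) notes[sort(i), , drop = FALSE])
}

#' Out-of-vocabulary rate of a target corpus
#'
#' Measures how much of a target domain's text is invisible to a model
#' whose word embeddings were trained on a source domain: the fraction of
#' target token occurrences absent from the source vocabulary. Numeric
#' tokens (digits, optionally with `.,:/-` separators) are removed first
#' when `drop_numeric` is set, since numbers are unbounded and carry no
#' embedding signal. The distinct-token (type-level) rate is reported
#' alongside.
#'
#' @param notes Target-domain notes tibble (needs a `tokens` list-column).
#' @param vocabulary Source-domain [build_vocabulary()] object.
#' @param drop_numeric Drop numeric tokens before measuring (default TRUE).
#' @return One-row tibble: `occurrence_rate`, `type_rate`, `n_occurrences`,
#'   `n_types`.
#' @export
oov_rate <- function(notes, vocabulary, drop_numeric = TRUE) {
  toks <- unlist(if (is.data.frame(notes)) notes$tokens else notes, use.names = FALSE)
  if (drop_numeric) {
    toks <- toks[!stringr::str_detect(toks, "^[0-9]+([.,:/-][0-9]+)*$")]
  }
  if (length(toks) == 0L) abort("no target tokens left after filtering")
  known <- toks %in% vocabulary$token
  types <- !duplicated(toks)
  tibble::tibble(
    occurrence_rate = mean(!known),
    type_rate = mean(!known[types]),
    n_occurrences = length(toks),
    n_types = sum(types))
}

#' Read and write notes as JSON-lines
#'
#' One JSON object per line with keys `id`, `text`, `domain`, and either
#' `subtypes` (list of subtype code strings) or `labels` (0/1 vector over
#' the disease codes), or both. Reading re-tokenizes the text.
#'
#' @param path File path.
#' @param notes Notes tibble.
#' @return `read_notes` returns a notes tibble; `write_notes` returns
#'   `path` invisibly.
#' @export
read_notes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    id = purrr::map_chr(recs, "id"),
    text = purrr::map_chr(recs, "text"),
    tokens = lapply(purrr::map_chr(recs, "text"), tokenize),
    subtypes = lapply(recs, function(r) as.character(r$subtypes %||% character())),
    labels = lapply(recs, function(r) if (is.null(r$labels)) NULL else as.integer(r$labels)),
    domain = purrr::map_chr(recs, function(r) r$domain %||% NA_character_))
}

#' @rdname read_notes
#' @export
write_notes <- function(notes, path) {
  lines <- purrr::pmap_chr(
    list(notes$id, notes$text, notes$subtypes, notes$labels, notes$domain),
    function(id, text, subtypes, labels, domain) {
      jsonlite::toJSON(
        list(id = jsonlite::unbox(id), text = jsonlite::unbox(text),
             subtypes = as.character(subtypes), labels = as.integer(labels),
             domain = jsonlite::unbox(domain)))
    })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Stack the labels list-column into a binary matrix
#' @param notes Notes tibble with a `labels` list-column.
#' @return Integer matrix, one row per note.
#' @export
labels_matrix <- function(notes) {
  do.call(rbind, notes$labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
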