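#' Construct a code ontology
#'
#' A code ontology is the three-level map used throughout the package:
#' fine-grained subtype codes roll up to one of `n_codes` top-level disease
#' codes, and each disease code belongs to exactly one meta-disease group.
#' The canonical label space has 42 disease codes (41 disorder categories
#' plus one bucket for non-disease codes) partitioned into 18 meta-diseases;
#' smaller ontologies are allowed for toy and simulation work by relaxing
#' the cardinality check.
#'
#' @param subtype_to_disease Named integer vector: names are subtype code
#'   identifiers, values are 0-based disease-code indices.
#' @param disease_to_meta Integer vector of length `n_codes` giving the
#'   0-based meta-disease index of each disease code.
#' @param disease_names Character vector of display names, one per disease
#'   code. Defaults to `code_00`, `code_01`, ...
#' @param meta_names Character vector of display names, one per meta group.
#' @param other_index 0-based index of the non-disease bucket code.
#' @param strict If `TRUE` (default), enforce the canonical 42-code /
#'   18-meta cardinality.
#' @return An object of class `code_ontology`.
#' @seealso [read_ontology()], [rollup()], [count_subtypes()]
#' @export
code_ontology <- function(subtype_to_disease, disease_to_meta,
                          disease_names = NULL, meta_names = NULL,
                          other_index = length(disease_to_meta) - 1L,
                          strict = TRUE) {
  n_codes <- length(disease_to_meta)
  n_meta <- length(unique(disease_to_meta))
  if (strict && (n_codes != 42L || n_meta != 18L)) {
    abort(sprintf(
      "canonical ontology requires 42 disease codes and 18 meta groups, got %d/%d (use strict = FALSE for reduced label spaces)",
      n_codes, n_meta))
  }
  if (is.null(disease_names)) disease_names <- sprintf("code_%02d", seq_len(n_codes) - 1L)
  if (is.null(meta_names)) meta_names <- sprintf("meta_%02d", seq_len(n_meta) - 1L)
  std <- as.integer(subtype_to_disease)
  names(std) <- names(subtype_to_disease)
  dtm <- as.integer(disease_to_meta)
  if (anyDuplicated(names(std))) {
    dup <- names(std)[duplicated(names(std))][1]
    first <- std[names(std) == dup]
    if (length(unique(first)) > 1L) {
      abort(sprintf("subtype '%s' maps to more than one disease code", dup))
    }
    std <- std[!duplicated(names(std))]
  }
  if (any(std < 0L | std >= n_codes)) abort("subtype maps to an out-of-range disease index")
  if (any(dtm < 0L) || length(unique(dtm)) != max(dtm) + 1L) {
    abort("meta indices must be 0-based and contiguous")
  }
  if (length(disease_names) != n_codes) abort("need one disease name per code")
  if (length(meta_names) != n_meta) abort("need one meta name per meta group")
  if (other_index < 0L || other_index >= n_codes) abort("other_index out of range")
  structure(
    list(subtype_to_disease = std, disease_to_meta = dtm,
         disease_names = disease_names, meta_names = meta_names,
         other_index = as.integer(other_index),
         n_codes = n_codes, n_meta = n_meta),
    class = "code_ontology")
}

#' @export
print.code_ontology <- function(x, ...) {
  cat(sprintf("<code_ontology> %d disease codes in %d meta groups, %d subtypes\n",
              x$n_codes, x$n_meta, length(x$subtype_to_disease)))
  invisible(x)
}

#' Meta-group membership as a list of 0-based disease indices
#' @param ontology A [code_ontology()].
#' @return List of length `n_meta`; element g holds the disease indices in meta g.
#' @export
meta_groups <- function(ontology) {
  lapply(seq_len(ontology$n_meta) - 1L,
         function(g) which(ontology$disease_to_meta == g) - 1L)
}

#' Read a code ontology from a rollup TSV
#'
#' The file format is a flat rollup table with header
#' `subtype_id  disease_index  disease_name  meta_index  meta_name`
#' (tab-separated, UTF-8, `#` comments allowed). Each subtype row pins the
#' subtype to exactly one disease code, and the disease/meta columns must
#' be mutually consistent: a disease index appearing with two different
#' meta indices or names is rejected.
#'
#' @param path Path to the TSV file.
#' @inheritParams code_ontology
#' @return A `code_ontology`.
#' @export
read_ontology <- function(path, strict = TRUE) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           subtype_id = readr::col_character(),
                           disease_index = readr::col_integer(),
                           disease_name = readr::col_character(),
                           meta_index = readr::col_integer(),
                           meta_name = readr::col_character()))
  need <- c("subtype_id", "disease_index", "disease_name", "meta_index", "meta_name")
  if (!all(need %in% names(tbl))) {
    abort(paste0("rollup table must have columns: ", paste(need, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(tbl[need]))
  if (length(bad)) abort(sprintf("malformed rollup row at data line %d", bad[1]))
  amb <- tbl |>
    dplyr::distinct(.data$subtype_id, .data$disease_index) |>
    dplyr::count(.data$subtype_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(amb)) {
    abort(sprintf("subtype '%s' maps to more than one disease code", amb$subtype_id[1]))
  }
  dmap <- tbl |>
    dplyr::distinct(.data$disease_index, .data$disease_name, .data$meta_index, .data$meta_name)
  if (anyDuplicated(dmap$disease_index)) {
    d <- dmap$disease_index[duplicated(dmap$disease_index)][1]
    abort(sprintf("disease index %d is mapped to more than one meta group or name", d))
  }
  dmap <- dplyr::arrange(dmap, .data$disease_index)
  if (!identical(dmap$disease_index, seq_len(nrow(dmap)) - 1L)) {
    abort("disease indices must be 0-based and contiguous")
  }
  meta_tbl <- dmap |>
    dplyr::distinct(.data$meta_index, .data$meta_name) |>
    dplyr::arrange(.data$meta_index)
  if (anyDuplicated(meta_tbl$meta_index) ||
      !identical(meta_tbl$meta_index, seq_len(nrow(meta_tbl)) - 1L)) {
    abort("meta indices must be 0-based, contiguous, and uniquely named")
  }
  std <- tbl |> dplyr::distinct(.data$subtype_id, .data$disease_index)
  other <- grep("^(other|non.?disease)", dmap$disease_name, ignore.case = TRUE)
  code_ontology(
    subtype_to_disease = setNames(std$disease_index, std$subtype_id),
    disease_to_meta = dmap$meta_index,
    disease_names = dmap$disease_name,
    meta_names = meta_tbl$meta_name,
    other_index = if (length(other)) other[1] - 1L else nrow(dmap) - 1L,
    strict = strict)
}

#' Write a code ontology as a rollup TSV
#' @param ontology A [code_ontology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  tbl <- tibble::tibble(
    subtype_id = names(ontology$subtype_to_disease),
    disease_index = unname(ontology$subtype_to_disease)) |>
    dplyr::mutate(
      disease_name = ontology$disease_names[.data$disease_index + 1L],
      meta_index = ontology$disease_to_meta[.data$disease_index + 1L],
      meta_name = ontology$meta_names[.data$meta_index + 1L])
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Roll up subtype codes to a top-level label vector
#'
#' Maps a set of fine-grained subtype codes onto the binary disease-code
#' label vector: position d is 1 iff some subtype in the set rolls up to
#' disease code d. Notes are annotated at the subtype level; the tagger's
#' label space is the rolled-up top level.
#'
#' @param subtypes Character vector (a set) of subtype identifiers.
#' @param ontology A [code_ontology()].
#' @param unknown Policy for subtypes absent from the ontology:
#'   `"lenient"` (default) maps them to the ontology's non-disease bucket
#'   with a warning, `"strict"` raises an error. The lenient default
#'   reflects that a target-domain corpus may carry subtypes never seen in
#'   the ontology's source data.
#' @return Integer 0/1 vector of length `ontology$n_codes`.
#' @export
rollup <- function(subtypes, ontology, unknown = c("lenient", "strict")) {
  unknown <- match.arg(unknown)
  out <- integer(ontology$n_codes)
  if (length(subtypes) == 0L) {
    warn("empty subtype set rolls up to an all-zero label vector")
    return(out)
  }
  idx <- ontology$subtype_to_disease[subtypes]
  miss <- is.na(idx)
  if (any(miss)) {
    if (unknown == "strict") {
      abort(sprintf("unknown subtype '%s'", subtypes[miss][1]))
    }
    warn(sprintf("%d unknown subtype(s) mapped to the non-disease bucket", sum(miss)))
    idx[miss] <- ontology$other_index
  }
  out[unique(idx) + 1L] <- 1L
  out
}

#' Count distinct observed subtypes per disease code
#'
#' For each disease code, counts the number of distinct subtype codes
#' observed in a note collection that roll up to it. The subtype count is
#' the package's proxy for the textual diversity of a disease code: codes
#' realized by many distinct subtypes subsume more heterogeneous
#' descriptions and are harder to tag. Optionally also counts, per code,
#' how many of those subtypes are shared with a second collection.
#'
#' @param notes A notes tibble with a `subtypes` list-column.
#' @param ontology A [code_ontology()].
#' @param other_notes Optional second notes tibble for the shared count.
#' @inheritParams rollup
#' @return Tibble with columns `disease_index`, `disease_name`,
#'   `n_subtypes`, and `n_shared` when `other_notes` is given.
#' @export
count_subtypes <- function(notes, ontology, other_notes = NULL,
                           unknown = c("lenient", "strict")) {
  unknown <- match.arg(unknown)
  observed <- function(nts) {
    subs <- unique(unlist(nts$subtypes, use.names = FALSE))
    if (is.null(subs)) subs <- character()
    idx <- ontology$subtype_to_disease[subs]
    miss <- is.na(idx)
    if (any(miss)) {
      if (unknown == "strict") abort(sprintf("unknown subtype '%s'", subs[miss][1]))
      idx[miss] <- ontology$other_index
    }
    tibble::tibble(subtype_id = subs, disease_index = unname(idx))
  }
  obs <- observed(notes)
  out <- tibble::tibble(
    disease_index = seq_len(ontology$n_codes) - 1L,
    disease_name = ontology$disease_names) |>
    dplyr::left_join(dplyr::count(obs, .data$disease_index, name = "n_subtypes"),
                     by = "disease_index") |>
    dplyr::mutate(n_subtypes = dplyr::coalesce(.data$n_subtypes, 0L))
  if (!is.null(other_notes)) {
    obs2 <- observed(other_notes)
    shared <- obs |>
      dplyr::semi_join(obs2, by = "subtype_id") |>
      dplyr::count(.data$disease_index, name = "n_shared")
    out <- out |>
      dplyr::left_join(shared, by = "disease_index") |>
      dplyr::mutate(n_shared = dplyr::coalesce(.data$n_shared, 0L))
  }
  out
}
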