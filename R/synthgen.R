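#' Generator configuration for synthetic note corpora
#'
#' Defines the statistical structure of the synthetic source domain, chosen
#' to mirror the structure of a large university-hospital coding corpus:
#' multilabel notes with at least one and on average `mean_labels` (default
#' 8) top-level codes, long-tailed code frequencies, per-code subtype
#' diversity (each code realized by several keyword-bearing subtypes), and
#' documents of on average `doc_len_mean` words (default 325).
#'
#' Each subtype owns a small keyword set mixing three token namespaces:
#' tokens unique to the subtype, tokens shared by all subtypes of the same
#' code, and "theme" tokens shared across the codes of one meta-disease.
#' The meta-level sharing makes the meta structure learnable from text,
#' which is what the hierarchical training objectives exploit.
#'
#' @param n_codes Number of top-level disease codes (default 42: 41 disease
#'   categories plus one non-disease bucket).
#' @param n_meta Number of meta-disease groups (default 18).
#' @param subtypes_per_code Either a length-2 range from which each code's
#'   subtype count is drawn uniformly, or an explicit length-`n_codes`
#'   integer vector of planted subtype counts.
#' @param background_vocab Number of background (non-keyword) token types.
#' @param keywords_per_subtype Size of each subtype's keyword set.
#' @param meta_share,code_share How many of those keywords come from the
#'   meta-level theme pool and the code-level pool; the rest are unique to
#'   the subtype.
#' @param doc_len_mean,doc_len_sd Document length distribution (words).
#' @param mean_labels Mean number of codes per note (>= 1; a note draws
#'   `1 + Poisson(mean_labels - 1)` codes).
#' @param freq_exponent Exponent of the truncated power law over code
#'   frequencies (rank^-exponent), giving the long tail.
#' @param meta_cooccur Within-meta label co-occurrence: the probability
#'   that each code after the first is drawn as a sibling (same meta
#'   group) of an already-drawn code rather than from the frequency law
#'   (default 0.5). Related diseases co-occur in real notes; this is what
#'   makes the meta level informative.
#' @param kw_injections Keywords injected per selected subtype.
#' @param label_noise Probability of flipping each label bit (default 0).
#'   Either a scalar or a length-`n_codes` vector of per-code flip rates;
#'   per-code rates model diseases whose coding is inconsistent.
#' @param seed Integer seed; every generator call is fully seeded.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_codes = 42L, n_meta = 18L,
                             subtypes_per_code = c(2L, 20L),
                             background_vocab = 5000L,
                             keywords_per_subtype = 8L,
                             meta_share = 3L, code_share = 3L,
                             doc_len_mean = 325, doc_len_sd = 80,
                             mean_labels = 8, freq_exponent = 1,
                             meta_cooccur = 0.5,
                             kw_injections = 3L, label_noise = 0,
                             seed = 1L) {
  stopifnot(n_codes >= 2L, n_meta >= 1L, n_meta <= n_codes,
            mean_labels >= 1, all(label_noise >= 0), all(label_noise <= 1),
            length(label_noise) %in% c(1L, n_codes),
            meta_cooccur >= 0, meta_cooccur <= 1,
            meta_share + code_share < keywords_per_subtype)
  if (length(subtypes_per_code) == 2L && n_codes != 2L) {
    stopifnot(subtypes_per_code[1] >= 1L)
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a synthetic code ontology with keyword inventory
#'
#' Partitions `n_codes` disease codes into `n_meta` meta groups (each meta
#' gets at least one code), assigns each code its planted subtype count,
#' and equips every subtype with a keyword set drawn from the three token
#' namespaces described in [generator_config()].
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_ontology`: `ontology` (a
#'   [code_ontology()], strict iff the canonical 42/18 shape), `inventory`
#'   (tibble `subtype_id`, `disease_index`, `keywords` list-column), and
#'   the `config`.
#' @export
generate_ontology <- function(config) {
  withr::with_seed(config$seed, {
    D <- config$n_codes; G <- config$n_meta
    # every meta gets one code, remaining codes spread at random
    d2m <- integer(D)
    d2m[seq_len(G)] <- seq_len(G) - 1L
    if (D > G) d2m[(G + 1L):D] <- sample(G, D - G, replace = TRUE) - 1L
    d2m <- sort(d2m)
    spc <- config$subtypes_per_code
    n_sub <- if (length(spc) == D && D != 2L) {
      as.integer(spc)
    } else if (length(spc) == 2L) {
      vals <- seq.int(spc[1], spc[2])
      vals[sample.int(length(vals), D, replace = TRUE)]
    } else as.integer(spc)
    stopifnot(length(n_sub) == D, all(n_sub >= 1L))
    meta_pool <- lapply(seq_len(G), function(g) sprintf("mt%02dk%02d", g - 1L, 1:6))
    code_pool <- lapply(seq_len(D), function(d) sprintf("cd%02dk%02d", d - 1L, 1:6))
    inv <- purrr::map_dfr(seq_len(D), function(d) {
      purrr::map_dfr(seq_len(n_sub[d]), function(k) {
        kw <- c(sample(meta_pool[[d2m[d] + 1L]], config$meta_share),
                sample(code_pool[[d]], config$code_share),
                sprintf("su%02dx%03du%02d", d - 1L, k,
                        seq_len(config$keywords_per_subtype -
                                  config$meta_share - config$code_share)))
        tibble::tibble(subtype_id = sprintf("SUB_%02d_%03d", d - 1L, k),
                       disease_index = d - 1L, keywords = list(kw))
      })
    })
    ont <- code_ontology(
      subtype_to_disease = setNames(inv$disease_index, inv$subtype_id),
      disease_to_meta = d2m,
      disease_names = c(sprintf("disease_%02d", seq_len(D - 1L) - 1L), "other_nondisease"),
      meta_names = sprintf("metagroup_%02d", seq_len(G) - 1L),
      other_index = D - 1L,
      strict = (D == 42L && G == 18L))
    structure(list(ontology = ont, inventory = inv, config = config),
              class = "synthetic_ontology")
  })
}

#' @export
print.synthetic_ontology <- function(x, ...) {
  cat(sprintf("<synthetic_ontology> %d codes / %d metas, %d subtypes, seed %d\n",
              x$ontology$n_codes, x$ontology$n_meta, nrow(x$inventory),
              x$config$seed))
  invisible(x)
}

#' Generate a synthetic multilabel note corpus
#'
#' Per note: draws a code set of size `1 + Poisson(mean_labels - 1)`
#' (without replacement, weighted by the long-tailed code frequency law),
#' picks one subtype per code, fills the document with background tokens,
#' and injects `kw_injections` keywords per selected subtype at random
#' positions. Labels are the rollup of the planted subtypes; optional
#' label-flip noise is applied afterwards, so at noise 0 the labels equal
#' the rollup by construction.
#'
#' @param synth A [generate_ontology()] result.
#' @param n Number of notes.
#' @param seed Seed for this corpus draw (defaults to the config seed + 1).
#' @param domain Domain tag stored on each note (default `"synthA"`).
#' @return Notes tibble: `id`, `text`, `tokens`, `subtypes`, `labels`,
#'   `domain`.
#' @export
generate_corpus <- function(synth, n, seed = synth$config$seed + 1L,
                            domain = "synthA") {
  stopifnot(inherits(synth, "synthetic_ontology"), n >= 1L)
  cfg <- synth$config
  ont <- synth$ontology
  D <- ont$n_codes
  code_w <- (seq_len(D))^(-cfg$freq_exponent)
  code_w <- code_w / sum(code_w)
  bg <- sprintf("bg%05d", seq_len(cfg$background_vocab))
  bg_w <- (seq_len(cfg$background_vocab))^(-1)
  bg_w <- bg_w / sum(bg_w)
  inv_by_code <- split(synth$inventory, synth$inventory$disease_index)
  kw_lut <- setNames(synth$inventory$keywords, synth$inventory$subtype_id)
  d2m_lut <- ont$disease_to_meta
  withr::with_seed(seed, {
    notes <- purrr::map_dfr(seq_len(n), function(i) {
      k <- min(1L + rpois(1L, cfg$mean_labels - 1), D)
      codes <- integer(k)
      codes[1] <- sample.int(D, 1L, prob = code_w)
      for (j in seq_len(k - 1L) + 1L) {
        chosen <- codes[seq_len(j - 1L)]
        sibs <- setdiff(which(d2m_lut %in% d2m_lut[chosen]), chosen)
        if (length(sibs) && runif(1L) < cfg$meta_cooccur) {
          codes[j] <- sibs[sample.int(length(sibs), 1L)]
        } else {
          rest <- setdiff(seq_len(D), chosen)
          codes[j] <- rest[sample.int(length(rest), 1L,
                                      prob = code_w[rest])]
        }
      }
      subs <- vapply(codes, function(d) {
        pool <- inv_by_code[[as.character(d - 1L)]]$subtype_id
        pool[sample.int(length(pool), 1L)]
      }, character(1))
      len <- max(10L, round(rnorm(1L, cfg$doc_len_mean, cfg$doc_len_sd)))
      toks <- sample(bg, len, replace = TRUE, prob = bg_w)
      # distinct injection positions, cycled over subtypes so every planted
      # subtype keeps its share of keyword evidence
      total <- min(len, cfg$kw_injections * length(subs))
      pos <- sample.int(len, total)
      owner <- rep(seq_along(subs), length.out = total)
      for (si in seq_along(subs)) {
        p_i <- pos[owner == si]
        if (length(p_i)) {
          toks[p_i] <- sample(kw_lut[[subs[si]]], length(p_i), replace = TRUE)
        }
      }
      tibble::tibble(id = sprintf("%s_%06d", domain, i),
                     text = paste(toks, collapse = " "),
                     tokens = list(toks),
                     subtypes = list(subs),
                     labels = list(suppressWarnings(rollup(subs, ont))),
                     domain = domain)
    })
    if (any(cfg$label_noise > 0)) {
      rate <- rep(cfg$label_noise, length.out = D)
      notes$labels <- lapply(notes$labels, function(y) {
        flip <- rbinom(length(y), 1L, rate) == 1L
        y[flip] <- 1L - y[flip]
        y
      })
    }
    notes
  })
}

#' Domain-shift configuration
#'
#' Parameterizes the transform from the synthetic source domain to a
#' shifted target domain mimicking a cross-hospital gap: shorter notes,
#' unfamiliar abbreviations (out-of-vocabulary injection at rate 0.154 by
#' default, matching an observed cross-hospital OOV share of 15.4% after
#' number filtering), and subtypes unique to the target domain.
#'
#' @param oov_prob Probability that a token occurrence is replaced by its
#'   unseen abbreviated form (default 0.154).
#' @param length_scale Target/source document length ratio (default
#'   191/325, the shifted domain averaging 191 words against 325).
#' @param subtype_swap Fraction of the ontology's subtypes replaced in the
#'   shifted domain by novel subtypes that roll up to the same codes
#'   (their unique keywords are rewritten to unseen tokens).
#' @param code_vocab_swap Probability that an occurrence of a code-level
#'   keyword is also rewritten in notes carrying a swapped subtype: a novel
#'   subtype brings novel code-specific terminology, leaving mainly the
#'   meta-level themes intact (default 0.5).
#' @param code_reweight Optional length-`n_codes` multiplicative weight
#'   vector; when given, the shifted corpus is resampled with per-note
#'   weights proportional to the mean reweight of its codes, changing the
#'   code frequency distribution.
#' @param seed Seed for the shift transform.
#' @return A `shift_config` list.
#' @export
shift_config <- function(oov_prob = 0.154, length_scale = 191 / 325,
                         subtype_swap = 0.1, code_vocab_swap = 0.5,
                         code_reweight = NULL, seed = 99L) {
  stopifnot(oov_prob >= 0, oov_prob <= 1, length_scale > 0,
            subtype_swap >= 0, subtype_swap <= 1,
            code_vocab_swap >= 0, code_vocab_swap <= 1)
  structure(as.list(environment()), class = "shift_config")
}

#' Apply a cross-hospital domain shift to a note corpus
#'
#' Transforms source-domain notes into shifted-domain notes: truncates each
#' document to `length_scale` of its length, replaces a `subtype_swap`
#' fraction of subtypes with novel same-code subtypes (rewriting their
#' subtype-unique keywords to novel tokens), and replaces each remaining
#' token occurrence with an unseen "abbreviation" token with probability
#' `oov_prob`. Label vectors are carried over unchanged: every transform
#' preserves which top-level codes a note is tagged with.
#'
#' @param notes Source notes tibble from [generate_corpus()].
#' @param shift A [shift_config()].
#' @param synth The [generate_ontology()] result the notes came from.
#' @return Shifted notes tibble with `domain` suffixed by `"_shift"`.
#' @export
apply_domain_shift <- function(notes, shift, synth) {
  stopifnot(inherits(shift, "shift_config"), inherits(synth, "synthetic_ontology"))
  withr::with_seed(shift$seed, {
    inv <- synth$inventory
    swap_ids <- character()
    if (shift$subtype_swap > 0) {
      n_swap <- round(shift$subtype_swap * nrow(inv))
      swap_ids <- sample(inv$subtype_id, n_swap)
    }
    # unique keywords of swapped subtypes get rewritten to novel tokens
    swap_kw <- character()
    if (length(swap_ids)) {
      uniq <- unlist(lapply(swap_ids, function(s) {
        kw <- inv$keywords[[match(s, inv$subtype_id)]]
        kw[stringr::str_detect(kw, "^su[0-9]")]
      }))
      swap_kw <- unique(uniq)
    }
    out <- notes
    out$domain <- paste0(notes$domain, "_shift")
    new_note <- function(toks, subs) {
      len <- max(5L, round(length(toks) * shift$length_scale))
      toks <- toks[seq_len(min(len, length(toks)))]
      if (length(swap_kw)) {
        hit <- toks %in% swap_kw
        toks[hit] <- paste0("nv", toks[hit])
      }
      # a novel subtype also brings novel code-specific terminology: half of
      # the code-level keyword occurrences in its notes are rewritten, so
      # only the meta-level themes survive intact for swapped subtypes
      sw <- subs %in% swap_ids
      if (any(sw)) {
        d_sw <- inv$disease_index[match(subs[sw], inv$subtype_id)]
        cp <- sprintf("cd%02dk%02d", rep(d_sw, each = 6L), 1:6)
        hit <- toks %in% cp & runif(length(toks)) < shift$code_vocab_swap
        toks[hit] <- paste0("nv", toks[hit])
      }
      if (shift$oov_prob > 0) {
        abbr <- runif(length(toks)) < shift$oov_prob
        toks[abbr] <- paste0("ab", toks[abbr])
      }
      subs[subs %in% swap_ids] <- paste0(subs[subs %in% swap_ids], "NOVEL")
      list(tokens = toks, subtypes = subs)
    }
    shifted <- purrr::map2(notes$tokens, notes$subtypes, new_note)
    out$tokens <- purrr::map(shifted, "tokens")
    out$subtypes <- purrr::map(shifted, "subtypes")
    out$text <- purrr::map_chr(out$tokens, paste, collapse = " ")
    if (!is.null(shift$code_reweight)) {
      w <- vapply(notes$labels, function(y) {
        mean(shift$code_reweight[which(y == 1L)])
      }, numeric(1))
      idx <- sample.int(nrow(out), nrow(out), replace = TRUE, prob = w)
      out <- out[idx, , drop = FALSE]
      out$id <- sprintf("%s_%06d", out$domain, seq_len(nrow(out)))
    }
    out
  })
}
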