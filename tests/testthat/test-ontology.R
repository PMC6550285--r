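test_that("ontology constructor enforces the canonical cardinality and map consistency", {
  expect_error(code_ontology(c(S1 = 0L), disease_to_meta = c(0L, 1L)),
               "42 disease codes")
  ont <- toy_ontology()
  expect_s3_class(ont, "code_ontology")
  expect_equal(ont$n_codes, 6L)
  expect_equal(ont$n_meta, 3L)
  # a subtype pinned to two different codes is rejected
  expect_error(code_ontology(
    subtype_to_disease = c(S1 = 0L, S1 = 1L),
    disease_to_meta = c(0L, 1L), strict = FALSE),
    "more than one disease code")
  # meta indices must be contiguous
  expect_error(code_ontology(c(S1 = 0L), disease_to_meta = c(0L, 2L),
                             strict = FALSE),
               "contiguous")
})

test_that("rollup TSV round-trips through write and read", {
  synth <- generate_ontology(small_gen_config(seed = 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ontology(synth$ontology, path)
  back <- read_ontology(path, strict = FALSE)
  expect_equal(back$subtype_to_disease, synth$ontology$subtype_to_disease)
  expect_equal(back$disease_to_meta, synth$ontology$disease_to_meta)
  expect_equal(back$disease_names, synth$ontology$disease_names)
  expect_equal(back$meta_names, synth$ontology$meta_names)
  expect_equal(back$other_index, synth$ontology$other_index)
  # a second round trip is identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_ontology(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed rollup tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "subtype_id\tdisease_index\tdisease_name\tmeta_index\tmeta_name"
  # same subtype under two disease codes
  writeLines(c(hdr,
               "S1\t0\tcode a\t0\tmeta a",
               "S1\t1\tcode b\t0\tmeta a"), path)
  expect_error(read_ontology(path, strict = FALSE), "more than one disease code")
  # one disease index mapped to two meta groups
  writeLines(c(hdr,
               "S1\t0\tcode a\t0\tmeta a",
               "S2\t0\tcode a\t1\tmeta b"), path)
  expect_error(read_ontology(path, strict = FALSE), "more than one meta")
  # malformed row (missing field)
  writeLines(c(hdr,
               "S1\t0\tcode a\t0\tmeta a",
               "S2\t\tcode b\t0\tmeta a"), path)
  expect_error(read_ontology(path, strict = FALSE), "malformed")
  # comments and a valid toy table are fine
  writeLines(c("# rollup fixture", hdr,
               "S1\t0\tcode a\t0\tmeta a",
               "S2\t0\tcode a\t0\tmeta a",
               "S3\t1\tcode b\t0\tmeta a"), path)
  ont <- read_ontology(path, strict = FALSE)
  expect_equal(ont$n_codes, 2L)
  expect_equal(ont$n_meta, 1L)
})

test_that("rollup maps subtype sets onto binary label vectors", {
  ont <- toy_ontology()
  # idempotent union: two subtypes of the same code give a single 1
  expect_equal(rollup(c("S1", "S2"), ont), c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_warning(z <- rollup(character(), ont), "all-zero")
  expect_equal(z, integer(6))
  expect_error(rollup("nope", ont, unknown = "strict"), "unknown subtype")
  expect_warning(v <- rollup("nope", ont, unknown = "lenient"), "non-disease bucket")
  expect_equal(which(v == 1L) - 1L, ont$other_index)
})

test_that("rollup agrees with a brute-force loop and is monotone under union", {
  ont <- toy_ontology()
  subs <- names(ont$subtype_to_disease)
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- sample(subs, 5, replace = TRUE)
      b <- sample(subs, 3, replace = TRUE)
      # brute force: loop over the map
      brute <- integer(ont$n_codes)
      for (s in unique(a)) brute[ont$subtype_to_disease[[s]] + 1L] <- 1L
      expect_equal(rollup(a, ont), brute)
      # rollup(union) = elementwise OR; adding subtypes never clears a bit
      u <- rollup(union(a, b), ont)
      expect_equal(u, pmax(rollup(a, ont), rollup(b, ont)))
      expect_true(all(u >= rollup(a, ont)))
    }
  })
})

test_that("count_subtypes counts distinct observed subtypes per code", {
  ont <- toy_ontology()
  notes <- tibble::tibble(
    id = c("a", "b"),
    subtypes = list("S1", c("S1", "S2")))
  cnt <- count_subtypes(notes, ont)
  expect_equal(cnt$n_subtypes[1], 2L)     # S1 and S2 both roll to code 0
  expect_equal(cnt$n_subtypes[2:6], rep(0L, 5))
  # shared counts against a second collection
  other <- tibble::tibble(id = "c", subtypes = list(c("S2", "S3")))
  cnt2 <- count_subtypes(notes, ont, other)
  expect_equal(cnt2$n_shared[1], 1L)      # only S2 is shared
})

test_that("count_subtypes over a union is bounded by per-collection counts and their sum", {
  ont <- toy_ontology()
  subs <- names(ont$subtype_to_disease)
  withr::with_seed(9, {
    mk <- function(n) tibble::tibble(
      id = as.character(seq_len(n)),
      subtypes = lapply(seq_len(n), function(i) sample(subs, 2)))
    a <- mk(8); b <- mk(8)
    u <- dplyr::bind_rows(a, b)
    ca <- count_subtypes(a, ont)$n_subtypes
    cb <- count_subtypes(b, ont)$n_subtypes
    cu <- count_subtypes(u, ont)$n_subtypes
    expect_true(all(cu >= pmax(ca, cb)))
    expect_true(all(cu <= ca + cb))
  })
})

test_that("count_subtypes recovers the planted subtype inventory on a large corpus", {
  synth <- generate_ontology(small_gen_config(seed = 5L))
  notes <- generate_corpus(synth, 1500, seed = 6L)
  cnt <- count_subtypes(notes, synth$ontology)
  planted <- dplyr::count(synth$inventory, disease_index, name = "n_planted")
  expect_true(all(cnt$n_subtypes <= planted$n_planted))
  # at n = 1500 every subtype of this small inventory has been drawn
  expect_equal(cnt$n_subtypes, planted$n_planted)
})
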