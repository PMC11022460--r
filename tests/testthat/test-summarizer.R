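make_scored_doc <- function(seed = 3, spt = 4, duplicates = 0,
                            connective_rate = 0.15) {
  spec <- toy_spec(seed = seed)
  mod <- make_toy_embedding_model(spec)
  art <- make_synthetic_article(spec, sentences_per_topic = spt,
                                duplicates = duplicates, seed = seed + 50,
                                connective_rate = connective_rate)
  doc <- prepare_document(art$text)
  list(spec = spec, mod = mod, art = art, doc = doc)
}

test_that("budget follows max(1, round(ratio * n))", {
  f <- make_scored_doc(seed = 2, spt = 5, connective_rate = 0)
  expect_identical(f$doc$n, 15L)
  s15 <- summarize_document(f$doc, f$mod, summary_config(ratio = 0.15))
  expect_identical(s15$budget, 2L)       # round(2.25)
  expect_identical(length(s15$selected), 2L)
  s25 <- summarize_document(f$doc, f$mod, summary_config(ratio = 0.25))
  expect_identical(s25$budget, 4L)       # round(3.75)
  expect_identical(length(s25$selected), 4L)
  # the spec-level arithmetic case: n = 20, ratio 0.15 -> 3
  expect_identical(max(1L, as.integer(floor(0.15 * 20 + 0.5))), 3L)
})

test_that("summary is emitted in ascending document order, extractively", {
  f <- make_scored_doc(seed = 6)
  s <- summarize_document(f$doc, f$mod, summary_config(ratio = 0.25))
  expect_true(all(diff(s$selected) > 0))
  surfaces <- vapply(f$doc$sentences, `[[`, character(1), "surface")
  for (i in s$selected) {
    expect_true(grepl(surfaces[i], s$text, fixed = TRUE))
  }
  expect_identical(s$text,
                   paste(surfaces[s$selected], collapse = " "))
})

test_that("identical inputs and seed give byte-identical summaries", {
  f <- make_scored_doc(seed = 9, duplicates = 1)
  cfg <- summary_config(ratio = 0.25, seed = 17)
  a <- summarize_document(f$doc, f$mod, cfg)
  b <- summarize_document(f$doc, f$mod, cfg)
  expect_identical(a$text, b$text)
  expect_identical(a$selected, b$selected)
})

test_that("degenerate documents are returned whole with a warning", {
  mod <- toy_abc_model()
  doc <- annotate_document("Only one sentence here.")
  expect_warning(
    s <- summarize_document(doc, mod),
    "fewer than 2"
  )
  expect_identical(s$selected, 1L)
  expect_identical(s$text, "Only one sentence here.")
})

test_that("verbatim duplicates never co-occur in a summary", {
  for (seed in 1:8) {
    f <- make_scored_doc(seed = seed, duplicates = 2)
    s <- summarize_document(f$doc, f$mod,
                            summary_config(ratio = 0.3, seed = seed))
    chosen <- vapply(f$doc$sentences[s$selected], `[[`, character(1),
                     "surface")
    expect_identical(anyDuplicated(chosen), 0L)
  }
})

test_that("selection at a smaller ratio is a subset of a larger one", {
  f <- make_scored_doc(seed = 12, connective_rate = 0)
  lo <- summarize_document(f$doc, f$mod,
                           summary_config(ratio = 0.15, seed = 2))
  hi <- summarize_document(f$doc, f$mod,
                           summary_config(ratio = 0.4, seed = 2))
  expect_true(all(lo$selected %in% hi$selected))
})

test_that("a selected connective opener drags its predecessor in", {
  # hand-built document: sentence 4 opens with a connective and is made
  # to dominate the ranking through sheer length and proper nouns
  surfaces <- c(
    "Filler alpha beta.",
    "Filler gamma delta.",
    "Short note.",
    "However, Avastin and Herceptin strongly inhibit t1w1 t1w2 t1w3 t1w4 growth in many trials."
  )
  doc <- annotate_document(surfaces)
  mod <- make_toy_embedding_model(toy_spec(seed = 1))
  s <- summarize_document(doc, mod,
                          summary_config(ratio = 0.25, k = 2, seed = 1))
  expect_identical(s$budget, 1L)
  expect_true(4L %in% s$selected)
  expect_true(3L %in% s$selected)     # forced antecedent, beyond budget
  expect_lte(length(s$selected), s$budget + 1L)
})

test_that("summaries and manifests write to disk deterministically", {
  f <- make_scored_doc(seed = 20)
  s <- summarize_document(f$doc, f$mod, summary_config(seed = 3))
  out1 <- tempfile(); man1 <- tempfile()
  out2 <- tempfile(); man2 <- tempfile()
  write_summary(s, out1, man1)
  write_summary(summarize_document(f$doc, f$mod, summary_config(seed = 3)),
                out2, man2)
  expect_identical(readLines(out1), readLines(out2))
  expect_identical(readLines(man1), readLines(man2))
  man <- jsonlite::read_json(man1)
  expect_identical(unlist(man$selected), as.integer(s$selected))
  expect_identical(man$config$policy, "mean")
})
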