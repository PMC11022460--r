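test_that("strip_structure removes title, abstract, captions, references", {
  art <- raw_article("T\n\nAbstract\nA.\n\nIntroduction\nB. C.\n\nReferences\n1. X.")
  expect_identical(strip_structure(art), "B. C.")

  with_caps <- paste("Study title", "", "Introduction",
                     "Body sentence one.", "Figure 1: pipeline overview",
                     "Body sentence two.", sep = "\n")
  out <- strip_structure(with_caps)
  expect_false(grepl("pipeline overview", out))
  expect_true(grepl("Body sentence one", out))
  expect_true(grepl("Body sentence two", out))
})

test_that("strip_structure passes unrecognized text through with a warning", {
  txt <- "Just prose with no headings. More prose."
  expect_warning(out <- strip_structure(txt), "unchanged")
  expect_identical(out, txt)
})

test_that("strip_structure preserves retained order and rejects empty input", {
  txt <- paste("Title", "", "Introduction", "First point.",
               "Second point.", "Third point.", "", "References",
               "1. x", sep = "\n")
  out <- strip_structure(txt)
  expect_lt(regexpr("First", out), regexpr("Second", out))
  expect_lt(regexpr("Second", out), regexpr("Third", out))
  expect_error(strip_structure("   "), class = "biosumm_empty_input")
  expect_error(raw_article("  "), class = "biosumm_empty_input")
})

test_that("segment_sentences handles terminators, fragments, decimals", {
  expect_identical(segment_sentences("A cat sat. A dog ran."),
                   c("A cat sat.", "A dog ran."))
  expect_identical(segment_sentences("One sentence without terminator"),
                   "One sentence without terminator")
  got <- segment_sentences("pH 7.4 was used. Next.")
  expect_length(got, 2)
  expect_identical(got[1], "pH 7.4 was used.")
  expect_length(segment_sentences("   \n \n"), 0)
})

test_that("segment_sentences keeps abbreviations intact", {
  got <- segment_sentences("Samples were fixed, e.g. in ethanol. Results follow.")
  expect_length(got, 2)
  got2 <- segment_sentences("As shown by Smith et al. the effect is large. It persists.")
  expect_length(got2, 2)
  expect_match(got2[1], "et al\\. the effect")
})

test_that("segmentation covers all non-whitespace body content", {
  body <- "Alpha beta. Gamma delta! Epsilon? Trailing bit"
  got <- segment_sentences(body)
  expect_identical(gsub("\\s+", "", paste(got, collapse = "")),
                   gsub("\\s+", "", body))
})

test_that("preprocess_sentence lowercases, lemmatizes, filters tokens", {
  expect_identical(preprocess_sentence("better")$tokens, "good")
  expect_identical(preprocess_sentence("123 45 ?!")$tokens, character(0))
  s <- preprocess_sentence("Dogs, running fast!",
                           annotator = fixture_annotator())
  expect_identical(s$tokens, c("dog", "run", "fast"))
})

test_that("tokens and tags stay parallel and preprocessing is idempotent", {
  ann <- builtin_annotator()
  sentences <- c("The HER2 receptor regulates growth, clearly.",
                 "Values of 3.5 and 7 were recorded!",
                 "However, T1prot binds t1w2 strongly.")
  for (srf in sentences) {
    s <- preprocess_sentence(srf, annotator = ann)
    expect_length(s$pos_tags, length(s$tokens))
    # re-running the pipeline on the normalized token stream is a no-op
    s2 <- preprocess_sentence(paste(s$tokens, collapse = " "),
                              annotator = ann)
    expect_identical(s2$tokens, s$tokens)
  }
})

test_that("hyphenated words survive as single tokens", {
  s <- preprocess_sentence("The beta-blocker dose was low.")
  expect_true("beta-blocker" %in% s$tokens)
})

test_that("proper nouns are tagged mid-sentence, not at sentence start", {
  s <- preprocess_sentence("The drug Avastin inhibits growth.")
  expect_identical(s$pos_tags[s$tokens == "avastin"], "PROPN")
  s2 <- preprocess_sentence("Avastin inhibits growth.")
  expect_false("PROPN" %in% s2$pos_tags[1])
})

test_that("annotate_document assigns gapless 1-based indices", {
  doc <- annotate_document(c("A cat sat.", "?!", "A dog ran."))
  expect_identical(doc$n, 3L)
  expect_identical(vapply(doc$sentences, `[[`, integer(1), "index"),
                   1:3)
  # all-punctuation sentence retained with empty tokens
  expect_length(doc$sentences[[2]]$tokens, 0)
})
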