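test_that("position score endpoints and interior values are exact", {
  expect_identical(position_score(1, 7), 1)
  expect_equal(position_score(5, 5), 0.2, tolerance = 1e-12)
  expect_equal(position_score(3, 5), 0.6, tolerance = 1e-12)
  for (n in c(1, 2, 13, 400)) {
    expect_equal(position_score(1, n), 1, tolerance = 1e-12)
    expect_equal(position_score(n, n), 1 / n, tolerance = 1e-12)
  }
  # strictly decreasing in index
  expect_true(all(diff(position_score(1:20, 20)) < 0))
  expect_error(position_score(0, 5), class = "biosumm_invalid_parameter")
})

test_that("tfidf sentence score matches the hand oracle", {
  doc <- annotate_document(c("a b", "a c", "a d"))
  st <- tfidf_stats(doc)
  # "a" occurs in all 3 sentences -> idf 0; "b" in 1 -> ln 3
  expect_equal(tfidf_sentence_score(doc$sentences[[1]], st), log(3),
               tolerance = 1e-9)
  expect_identical(tfidf_sentence_score(character(0), st), 0)
  # a token present in every sentence contributes nothing anywhere
  uniform <- annotate_document(c("x y", "x z", "x w"))
  stu <- tfidf_stats(uniform)
  expect_equal(tfidf_sentence_score("x", stu), 0, tolerance = 1e-12)
})

test_that("length, phrase and proper-noun scores follow their definitions", {
  expect_equal(length_score(c("a", "b", "c", "d", "e"), 10), 0.5)
  expect_equal(length_score(character(0), 10), 0)
  expect_error(length_score("a", 0), class = "biosumm_invalid_parameter")

  expect_equal(phrase_score(c("NOUN", "VERB", "OTHER")), 1)
  expect_equal(phrase_score(c("NOUN", "NOUN")), 0.5)
  expect_equal(phrase_score("OTHER"), 0)
  expect_equal(phrase_score(c("PROPN", "VERB")), 1)

  expect_equal(proper_noun_score(c("NOUN", "OTHER"), 4), 0)
  expect_equal(proper_noun_score(c("PROPN", "PROPN"), 2), 1)
  expect_equal(proper_noun_score("PROPN", 4), 0.25)
  expect_equal(proper_noun_score(character(0), 0), 0)
})

test_that("avg_cosine matches hand arithmetic and its bound", {
  same <- matrix(1, 4, 3)
  expect_equal(avg_cosine(2, same), 3 / 4, tolerance = 1e-12)
  ortho <- diag(3)
  expect_equal(avg_cosine(1, ortho), 0, tolerance = 1e-12)
  v <- rbind(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))
  expect_equal(avg_cosine(3, v), (2 * cos(pi / 4)) / 3, tolerance = 1e-9)
  # invariant to reordering of the other sentences; |value| <= (n-1)/n
  set.seed(3)
  x <- matrix(rnorm(18), 6, 3)
  perm <- rbind(x[1, , drop = FALSE], x[sample(2:6), ])
  expect_equal(avg_cosine(1, x), avg_cosine(1, perm), tolerance = 1e-12)
  for (i in 1:6) expect_lte(abs(avg_cosine(i, x)), 5 / 6 + 1e-12)
})

test_that("min-max normalization rescales columns and zeroes constants", {
  out <- normalize_features(data.frame(a = c(2, 4, 6), b = c(3, 3, 3),
                                       c = c(0, 1, 0.5)))
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, c(0, 0, 0))
  expect_equal(out$c, c(0, 1, 0.5))
})

test_that("total is the sum of the six normalized features", {
  spec <- toy_spec(seed = 8)
  mod <- make_toy_embedding_model(spec)
  art <- make_synthetic_article(spec, sentences_per_topic = 4, seed = 4)
  doc <- prepare_document(art$text)
  vec <- document_big_vectors(doc, mod)
  sc <- score_sentences(doc, vec)
  norm_cols <- grep("^norm_", names(sc), value = TRUE)
  expect_length(norm_cols, 6)
  expect_equal(sc$total, rowSums(sc[norm_cols]), tolerance = 1e-12)
  expect_true(all(sc$total >= 0 & sc$total <= 6))
  expect_true(all(vapply(sc[norm_cols], function(col)
    all(col >= 0 & col <= 1), logical(1))))
})

test_that("redundancy filter drops the lower-position near-duplicate", {
  fake_cluster <- structure(list(assignment = c(1L, 1L), k = 1L),
                            class = "biosumm_clustering")
  scores <- data.frame(index = 1:2, total = c(0.80, 0.81),
                       position = c(0.9, 0.5))
  keep <- redundancy_filter(fake_cluster, scores, epsilon = 0.02)
  expect_identical(keep, c(TRUE, FALSE))
  # gap wider than epsilon: both survive
  scores$total <- c(0.80, 0.95)
  expect_identical(redundancy_filter(fake_cluster, scores, 0.02),
                   c(TRUE, TRUE))
  # same totals but different clusters: rule is intra-cluster only
  two_cl <- structure(list(assignment = c(1L, 2L), k = 2L),
                      class = "biosumm_clustering")
  scores$total <- c(0.80, 0.81)
  expect_identical(redundancy_filter(two_cl, scores, 0.02),
                   c(TRUE, TRUE))
})

test_that("redundancy filter never empties a cluster", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    assignment <- sample(1:3, n, replace = TRUE)
    scores <- data.frame(index = 1:n,
                         total = round(runif(n), 1),  # force many ties
                         position = 1 - (1:n - 1) / n)
    cl <- structure(list(assignment = assignment, k = 3L),
                    class = "biosumm_clustering")
    keep <- redundancy_filter(cl, scores, epsilon = 0.1)
    for (lbl in unique(assignment)) {
      members <- which(assignment == lbl)
      expect_true(any(keep[members]))
      # the member with the highest position score survives
      expect_true(keep[members[which.max(scores$position[members])]])
    }
  }
})

test_that("connecting rule pulls in predecessors of connective openers", {
  doc <- annotate_document(c("First fact here.", "Second fact here.",
                             "Third fact here.", "Fourth fact here.",
                             "However, the effect reversed."))
  expect_identical(apply_connecting_rule(5L, doc), c(4L, 5L))
  doc2 <- annotate_document(c("But this opens the document.",
                              "Another sentence."))
  expect_identical(apply_connecting_rule(1L, doc2), 1L)
  expect_identical(apply_connecting_rule(c(2L, 3L), doc), c(2L, 3L))
})
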