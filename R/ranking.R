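# Sentence ranking: six surface/semantic features per sentence, min-max
# normalization, an unweighted total, plus the two selection rules —
# intra-cluster redundancy elimination and forced inclusion of a
# connective opener's preceding sentence.

#' Sentence position score
#'
#' `1 - (i - 1) / n`: the first sentence scores 1, the last `1/n`;
#' strictly decreasing in position.
#'
#' @param i 1-based sentence index.
#' @param n number of sentences in the document.
#' @return score in `(0, 1]`.
#' @export
position_score <- function(i, n) {
  if (any(i < 1 | i > n)) bs_invalid("i must be in [1, n]")
  1 - (i - 1) / n
}

#' Per-sentence TF-IDF statistics for one document
#'
#' Each sentence is treated as one "document" for IDF:
#' `idf(w) = ln(n / df(w))` with `df(w)` the number of sentences
#' containing `w`.
#'
#' @param document a `biosumm_document`.
#' @return list with `n` and named `idf` vector, class `tfidf_stats`.
#' @export
tfidf_stats <- function(document) {
  n <- document$n
  df <- table(unlist(lapply(document$sentences,
                            function(s) unique(s$tokens))))
  idf <- log(n / as.numeric(df))
  names(idf) <- names(df)
  structure(list(n = n, idf = idf), class = "tfidf_stats")
}

#' TF-IDF sentence score
#'
#' Sum over the sentence's tokens of `tf(w, sentence) * idf(w)` — the
#' sentence score is the sum of its words' TF-IDF scores.
#'
#' @param sentence a `biosumm_sentence` (or character token vector).
#' @param stats a `tfidf_stats` built from the same document.
#' @return non-negative score (0 for an empty sentence).
#' @export
tfidf_sentence_score <- function(sentence, stats) {
  tokens <- if (inherits(sentence, "biosumm_sentence")) {
    sentence$tokens
  } else {
    as.character(sentence)
  }
  if (length(tokens) == 0) return(0)
  tf <- table(tokens)
  idf <- stats$idf[names(tf)]
  idf[is.na(idf)] <- 0
  sum(as.numeric(tf) * idf)
}

#' Length score: token count relative to the document's longest sentence
#'
#' @param sentence a `biosumm_sentence` or token vector.
#' @param doc_max_len token count of the longest sentence (>= 1).
#' @return score in `[0, 1]`.
#' @export
length_score <- function(sentence, doc_max_len) {
  if (doc_max_len < 1) bs_invalid("doc_max_len must be >= 1")
  tokens <- if (inherits(sentence, "biosumm_sentence")) {
    sentence$tokens
  } else {
    as.character(sentence)
  }
  length(tokens) / doc_max_len
}

#' Noun/verb phrase score
#'
#' 1 if the sentence contains both a noun (NOUN or PROPN) and a verb,
#' 0.5 if exactly one of the two, 0 otherwise.
#'
#' @param pos_tags coarse tag vector (NOUN/VERB/PROPN/OTHER).
#' @return 0, 0.5 or 1.
#' @export
phrase_score <- function(pos_tags) {
  has_noun <- any(pos_tags %in% c("NOUN", "PROPN"))
  has_verb <- any(pos_tags == "VERB")
  if (has_noun && has_verb) 1 else if (has_noun || has_verb) 0.5 else 0
}

#' Proper-noun score
#'
#' PROPN count relative to the document maximum.
#'
#' @param pos_tags coarse tag vector.
#' @param doc_max_propn maximum PROPN count over the document's
#'   sentences.
#' @return score in `[0, 1]`.
#' @export
proper_noun_score <- function(pos_tags, doc_max_propn) {
  sum(pos_tags == "PROPN") / max(1, doc_max_propn)
}

#' Average cosine similarity of one sentence to all others
#'
#' `sum over j != i of cos(v_i, v_j), divided by n`. Zero vectors
#' contribute 0 to every pairwise term.
#'
#' @param i sentence index (row of `vectors`).
#' @param vectors matrix of big-vectors, one row per sentence.
#' @return the averaged similarity.
#' @export
avg_cosine <- function(i, vectors) {
  n <- nrow(vectors)
  if (i < 1 || i > n) bs_invalid("i must be in [1, n]")
  if (n == 1) return(0)
  s <- 0
  for (j in seq_len(n)) {
    if (j == i) next
    s <- s + cosine_sim(vectors[i, ], vectors[j, ])
  }
  s / n
}

#' Min-max normalize feature columns to [0, 1]
#'
#' A constant column maps to all zeros.
#'
#' @param raw data.frame or matrix of raw feature values (rows =
#'   sentences).
#' @return data.frame of normalized values.
#' @export
normalize_features <- function(raw) {
  raw <- as.data.frame(raw)
  if (nrow(raw) == 0) bs_empty("empty feature table")
  as.data.frame(lapply(raw, function(col) {
    rng <- range(col)
    if (rng[1] == rng[2]) return(rep(0, length(col)))
    (col - rng[1]) / (rng[2] - rng[1])
  }))
}

#' Score every sentence of a document
#'
#' Computes the six features (TF-IDF, position, length, phrase, proper
#' noun, average cosine), min-max normalizes each across the document,
#' and totals them (unweighted sum, range `[0, 6]`). The layout mirrors
#' a per-sentence feature table with one row per sentence.
#'
#' @param document a `biosumm_document`.
#' @param vectors big-vector matrix from [document_big_vectors()].
#' @param weights optional named numeric weights for the six features
#'   (default all 1).
#' @return data.frame with columns `index`, raw features
#'   (`tfidf`, `position`, `length`, `phrase`, `proper_noun`,
#'   `avg_cosine`), their normalized counterparts (`norm_` prefix) and
#'   `total`.
#' @export
score_sentences <- function(document, vectors, weights = NULL) {
  n <- document$n
  if (n == 0) bs_empty("document has no sentences")
  stopifnot(nrow(vectors) == n)
  stats <- tfidf_stats(document)
  max_len <- max(1, max(vapply(document$sentences,
                               function(s) length(s$tokens), integer(1))))
  max_propn <- max(vapply(document$sentences,
                          function(s) sum(s$pos_tags == "PROPN"),
                          integer(1)))
  raw <- data.frame(
    tfidf = vapply(document$sentences,
                   function(s) tfidf_sentence_score(s, stats), numeric(1)),
    position = position_score(seq_len(n), n),
    length = vapply(document$sentences,
                    function(s) length_score(s, max_len), numeric(1)),
    phrase = vapply(document$sentences,
                    function(s) phrase_score(s$pos_tags), numeric(1)),
    proper_noun = vapply(document$sentences,
                         function(s) proper_noun_score(s$pos_tags,
                                                       max_propn),
                         numeric(1)),
    avg_cosine = vapply(seq_len(n),
                        function(i) avg_cosine(i, vectors), numeric(1))
  )
  norm <- normalize_features(raw)
  names(norm) <- paste0("norm_", names(raw))
  w <- c(tfidf = 1, position = 1, length = 1, phrase = 1,
         proper_noun = 1, avg_cosine = 1)
  if (!is.null(weights)) w[names(weights)] <- weights
  total <- as.numeric(as.matrix(norm) %*%
                        w[sub("^norm_", "", names(norm))])
  cbind(data.frame(index = seq_len(n)), raw, norm,
        data.frame(total = total))
}

#' Intra-cluster redundancy filter
#'
#' Within each cluster, any pair of sentences whose total scores differ
#' by at most `epsilon` is treated as saying the same thing: the member
#' with the lower position score is marked ineligible (position ties
#' keep the lower index). Verbatim repeats — identical token sequences —
#' are redundant regardless of `epsilon`, since their totals differ only
#' through position, which is exactly the tie the rule resolves. The
#' cluster member with the highest position score always survives.
#'
#' @param clustering a `biosumm_clustering`.
#' @param scores feature table from [score_sentences()].
#' @param epsilon non-negative total-score closeness threshold.
#' @param document optional `biosumm_document`; when supplied, the
#'   verbatim-duplicate rule above is applied.
#' @return logical vector: `TRUE` where the sentence remains eligible.
#' @export
redundancy_filter <- function(clustering, scores, epsilon = 0.05,
                              document = NULL) {
  if (epsilon < 0) bs_invalid("epsilon must be >= 0")
  n <- nrow(scores)
  token_key <- if (!is.null(document)) {
    vapply(document$sentences,
           function(s) paste(s$tokens, collapse = "\u001f"), character(1))
  } else NULL
  eligible <- rep(TRUE, n)
  for (cl in unique(clustering$assignment)) {
    members <- which(clustering$assignment == cl)
    if (length(members) < 2) next
    for (a in seq_along(members)) {
      for (b in seq_along(members)) {
        if (b <= a) next
        i <- members[a]; j <- members[b]
        dup <- !is.null(token_key) && nzchar(token_key[i]) &&
          token_key[i] == token_key[j]
        if (dup || abs(scores$total[i] - scores$total[j]) <= epsilon) {
          pi <- scores$position[i]; pj <- scores$position[j]
          loser <- if (pi < pj) i else if (pj < pi) j else max(i, j)
          eligible[loser] <- FALSE
        }
      }
    }
  }
  eligible
}

#' Default connecting-word lexicon
#'
#' Discourse connectives whose appearance at a sentence's start makes
#' the preceding sentence necessary context.
#'
#' @return lowercase character vector.
#' @export
default_connecting_words <- function() {
  c("however", "moreover", "but", "because", "therefore", "thus",
    "hence", "furthermore", "additionally", "consequently")
}

first_surface_word <- function(sentence) {
  toks <- surface_tokens(sentence$surface)
  if (length(toks) == 0) return("")
  tolower(toks[1])
}

#' Force inclusion of sentences preceding connective openers
#'
#' For every selected sentence whose first surface word is a connecting
#' word, its immediate predecessor is added to the selection regardless
#' of rank. Applied to a fixed point: a forced antecedent that itself
#' opens with a connective pulls in its own predecessor, so every
#' connective in the final selection has its antecedent.
#'
#' @param selected integer vector of selected sentence indices.
#' @param document a `biosumm_document`.
#' @param lexicon connecting-word set.
#' @return augmented, sorted index vector.
#' @export
apply_connecting_rule <- function(selected, document,
                                  lexicon = default_connecting_words()) {
  current <- sort(unique(as.integer(selected)))
  repeat {
    add <- integer(0)
    for (i in current) {
      if (i <= 1 || (i - 1L) %in% current) next
      if (first_surface_word(document$sentences[[i]]) %in% lexicon) {
        add <- c(add, i - 1L)
      }
    }
    if (length(add) == 0) break
    current <- sort(unique(c(current, add)))
  }
  current
}
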