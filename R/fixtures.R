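# Synthetic-data generators: toy embedding models with planted topic
# neighbourhoods and multi-topic articles with known reference summaries.
# They exist so the whole pipeline — neighbourhood expansion, clustering,
# ranking, selection, ROUGE — is exercisable offline, with ground truth
# (topic labels, key sentences) known by construction.

#' Specification of a planted-topic toy embedding
#'
#' Each topic gets an anchor vector; every word of the topic is its
#' anchor plus isotropic Gaussian noise. Topic vocabularies are disjoint
#' by construction so topic recovery has a well-defined ground truth.
#'
#' @param n_topics number of topics (>= 1).
#' @param words_per_topic vocabulary size per topic.
#' @param dim embedding dimensionality (>= n_topics, so anchors can sit
#'   on distinct axes).
#' @param noise_scale standard deviation of the per-word noise (>= 0).
#' @param separation Euclidean distance between distinct topic anchors
#'   (> 0).
#' @param seed RNG seed.
#' @return a `toy_spec` list.
#' @export
toy_spec <- function(n_topics = 3L, words_per_topic = 8L, dim = 8L,
                     noise_scale = 0.1, separation = 1,
                     seed = 42L) {
  if (n_topics < 1) bs_invalid("n_topics must be >= 1")
  if (separation <= 0) bs_invalid("separation must be > 0")
  if (noise_scale < 0) bs_invalid("noise_scale must be >= 0")
  if (dim < n_topics) bs_invalid("dim must be >= n_topics")
  structure(list(n_topics = as.integer(n_topics),
                 words_per_topic = as.integer(words_per_topic),
                 dim = as.integer(dim), noise_scale = noise_scale,
                 separation = separation, seed = as.integer(seed)),
            class = "toy_spec")
}

topic_words <- function(spec, topic) {
  sprintf("t%dw%d", topic, seq_len(spec$words_per_topic))
}

#' Build a toy embedding model with planted topic neighbourhoods
#'
#' Anchors are placed at `separation / sqrt(2)` along distinct
#' coordinate axes, so any two anchors are exactly `separation` apart;
#' word vectors are anchor + N(0, noise_scale^2) noise. Deterministic
#' per `spec$seed`.
#'
#' @param spec a [toy_spec()].
#' @return an `embedding_model` over the words `t<topic>w<j>`.
#' @export
make_toy_embedding_model <- function(spec) {
  if (!inherits(spec, "toy_spec")) bs_invalid("spec must be a toy_spec")
  with_seed(spec$seed, {
    words <- unlist(lapply(seq_len(spec$n_topics),
                           function(t) topic_words(spec, t)))
    mat <- matrix(0, length(words), spec$dim)
    row <- 1L
    for (t in seq_len(spec$n_topics)) {
      anchor <- numeric(spec$dim)
      anchor[t] <- spec$separation / sqrt(2)
      for (j in seq_len(spec$words_per_topic)) {
        mat[row, ] <- anchor +
          stats::rnorm(spec$dim, sd = spec$noise_scale)
        row <- row + 1L
      }
    }
    rownames(mat) <- words
    embedding_model(mat)
  })
}

.fixture_verbs <- c("regulates", "inhibits", "activates", "modulates",
                    "mediates", "promotes", "suppresses", "induces")

# One designated key sentence per topic: longer and proper-noun-richer
# than filler so the ranking features have planted signal.
make_key_sentence <- function(spec, topic, verb) {
  w <- topic_words(spec, topic)
  pick <- function(i) w[((i - 1) %% length(w)) + 1]
  sprintf(
    "The %s complex of T%dgene and T%dprot strongly %s %s %s and %s signaling in the %s pathway.",
    pick(1), topic, topic, verb, pick(2), pick(3), pick(4), pick(5))
}

make_filler_sentence <- function(spec, topic, verb, j,
                                 connective = FALSE) {
  w <- topic_words(spec, topic)
  pick <- function(i) w[((i - 1) %% length(w)) + 1]
  core <- sprintf("the %s %s %s activity.", pick(j), verb, pick(j + 1))
  if (connective) {
    paste("However,", core)
  } else {
    paste0(toupper(substr(core, 1, 1)), substr(core, 2, nchar(core)))
  }
}

#' Generate a synthetic multi-topic article with a known reference
#'
#' The body holds `sentences_per_topic` sentences per topic — one
#' designated key sentence (longer, proper-noun-rich) plus filler — in
#' shuffled order, optionally with `duplicates` verbatim repeats of
#' randomly chosen body sentences. A fraction of filler sentences opens
#' with a connective ("However,") to exercise the predecessor rule;
#' repeated sentences are never placed immediately before a connective
#' opener, and connective openers are never themselves duplicated, so a
#' repeat is never the forced antecedent of a connective. The article
#' text carries a title, an abstract and a references block so the
#' structural stripper is exercised too; the reference summary is the
#' key sentences in body order.
#'
#' @param spec a [toy_spec()] (vocabulary and topic count).
#' @param sentences_per_topic body sentences per topic (>= 1).
#' @param duplicates how many verbatim repeats to plant.
#' @param seed RNG seed (independent of `spec$seed`).
#' @param connective_rate fraction of filler sentences opening with a
#'   connective.
#' @return a `synthetic_article`: list with `text`, `body` (surface
#'   sentences), `topic_label`, `reference`, `key_sentences`.
#' @export
make_synthetic_article <- function(spec, sentences_per_topic = 4L,
                                   duplicates = 0L, seed = 1L,
                                   connective_rate = 0.15) {
  if (sentences_per_topic < 1) {
    bs_invalid("sentences_per_topic must be >= 1")
  }
  with_seed(seed, {
    body <- character(0)
    labels <- integer(0)
    is_key <- logical(0)
    for (t in seq_len(spec$n_topics)) {
      verb <- .fixture_verbs[((t - 1) %% length(.fixture_verbs)) + 1]
      body <- c(body, make_key_sentence(spec, t, verb))
      labels <- c(labels, t)
      is_key <- c(is_key, TRUE)
      if (sentences_per_topic > 1) {
        for (j in seq_len(sentences_per_topic - 1)) {
          verb_j <- .fixture_verbs[((t + j - 1) %% length(.fixture_verbs)) + 1]
          conn <- stats::runif(1) < connective_rate
          body <- c(body,
                    make_filler_sentence(spec, t, verb_j, j,
                                         connective = conn))
          labels <- c(labels, t)
          is_key <- c(is_key, FALSE)
        }
      }
    }
    ord <- sample.int(length(body))
    body <- body[ord]
    labels <- labels[ord]
    is_key <- is_key[ord]

    if (duplicates > 0) {
      connective_initial <- grepl("^however", tolower(body))
      for (d in seq_len(duplicates)) {
        n_b <- length(body)
        # neither copy of a repeated sentence may ever be the antecedent
        # of a connective opener, so exclude connective-initial sources,
        # sources already followed by a connective, and insertion slots
        # followed by one
        follower_conn <- c(connective_initial[-1], FALSE)
        src_ok <- which(!connective_initial & !follower_conn)
        src <- src_ok[sample.int(length(src_ok), 1)]
        pos_ok <- which(!follower_conn)
        pos <- pos_ok[sample.int(length(pos_ok), 1)]
        body <- append(body, body[src], after = pos)
        labels <- append(labels, labels[src], after = pos)
        is_key <- append(is_key, FALSE, after = pos)
        connective_initial <- append(connective_initial,
                                     connective_initial[src], after = pos)
      }
    }

    reference <- paste(body[is_key], collapse = " ")
    text <- paste(
      c("Planted-topic synthetic study",
        "",
        "Abstract",
        "This synthetic abstract is discarded by the structural stripper.",
        "",
        "Introduction",
        "",
        paste(body, collapse = " "),
        "",
        "References",
        "1. Synthetic reference entry."),
      collapse = "\n")
    structure(list(text = text, body = body, topic_label = labels,
                   reference = reference,
                   key_sentences = body[is_key]),
              class = "synthetic_article")
  })
}

#' Write a paired input/reference fixture batch to disk
#'
#' Emits the two-directory layout `out/input/<id>.txt` +
#' `out/reference/<id>.txt` consumed by batch evaluation.
#'
#' @param out_dir output directory (created if needed).
#' @param n_articles how many articles.
#' @param spec a [toy_spec()].
#' @param sentences_per_topic,duplicates,connective_rate passed to
#'   [make_synthetic_article()].
#' @param seed base seed; article `i` uses `seed + i`.
#' @return data.frame with columns `id`, `input`, `reference`
#'   (paths), invisibly.
#' @export
write_fixture_batch <- function(out_dir, n_articles = 10L,
                                spec = toy_spec(),
                                sentences_per_topic = 4L,
                                duplicates = 0L,
                                connective_rate = 0.15,
                                seed = 1L) {
  input_dir <- file.path(out_dir, "input")
  ref_dir <- file.path(out_dir, "reference")
  dir.create(input_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(ref_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n_articles), function(i) {
    art <- make_synthetic_article(spec, sentences_per_topic,
                                  duplicates = duplicates,
                                  seed = seed + i,
                                  connective_rate = connective_rate)
    id <- sprintf("doc%03d", i)
    input <- file.path(input_dir, paste0(id, ".txt"))
    reference <- file.path(ref_dir, paste0(id, ".txt"))
    writeLines(art$text, input, useBytes = TRUE)
    writeLines(art$reference, reference, useBytes = TRUE)
    data.frame(id = id, input = input, reference = reference)
  })
  invisible(do.call(rbind, rows))
}
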