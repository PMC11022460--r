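# Embedding backend and semantic sentence representation. A sentence's
# big-vector is built by expanding each in-vocabulary word with its top-m
# nearest neighbours in embedding space and combining the expansion set's
# vectors into one fixed-length vector.

#' Construct an in-memory embedding model
#'
#' The query interface every backend satisfies: vocabulary membership,
#' per-word vector lookup, and top-m most-similar words under cosine
#' similarity (ties broken lexicographically, the query word excluded).
#'
#' @param vectors numeric matrix, one row per word, rownames = vocabulary.
#' @return an `embedding_model`.
#' @export
embedding_model <- function(vectors) {
  if (!is.matrix(vectors) || !is.numeric(vectors) ||
      is.null(rownames(vectors)) || nrow(vectors) == 0) {
    bs_invalid("`vectors` must be a numeric matrix with word rownames")
  }
  if (anyDuplicated(rownames(vectors))) {
    bs_invalid("duplicate words in vocabulary")
  }
  norms <- sqrt(rowSums(vectors^2))
  structure(
    list(vectors = vectors, norms = norms, dim = ncol(vectors)),
    class = "embedding_model"
  )
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %d words, dim %d\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' @rdname embedding_model
#' @param model an `embedding_model`.
#' @param word a word (character scalar).
#' @export
emb_contains <- function(model, word) {
  word %in% rownames(model$vectors)
}

#' @rdname embedding_model
#' @export
emb_vector <- function(model, word) {
  if (!emb_contains(model, word)) {
    bs_invalid(sprintf("word not in vocabulary: %s", word))
  }
  model$vectors[word, ]
}

#' @rdname embedding_model
#' @export
emb_vocabulary <- function(model) rownames(model$vectors)

#' Top-m most-similar words (the neighbourhood expansion function)
#'
#' Returns up to `m` in-vocabulary words ranked by descending cosine
#' similarity to `word`, excluding `word` itself; ties are broken by
#' lexicographic word order so the ranking is deterministic. An
#' out-of-vocabulary query returns an empty list (a message is emitted).
#'
#' @param word query word.
#' @param m non-negative neighbour count.
#' @param model an `embedding_model`.
#' @return character vector of length <= m.
#' @export
beta_neighbors <- function(word, m, model) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0) {
    bs_invalid("`m` must be a non-negative integer")
  }
  m <- as.integer(m)
  if (m == 0L) return(character(0))
  if (!emb_contains(model, word)) {
    message(sprintf("out-of-vocabulary word skipped: %s", word))
    return(character(0))
  }
  v <- model$vectors[word, ]
  nv <- model$norms[word]
  vocab <- rownames(model$vectors)
  if (nv == 0) return(character(0))
  sims <- as.vector(model$vectors %*% v) / (model$norms * nv)
  sims[model$norms == 0] <- -Inf
  sims[vocab == word] <- -Inf
  ord <- order(-sims, vocab)
  picked <- ord[seq_len(min(m, sum(is.finite(sims[ord]))))]
  vocab[picked]
}

#' Build a sentence big-vector
#'
#' Each in-vocabulary token contributes its own vector plus the vectors
#' of its top-`m` neighbours, in sentence order. Two combination
#' policies produce a fixed-length vector:
#' \describe{
#'   \item{`mean`}{arithmetic mean of the expansion set's vectors;
#'     length equals the embedding dimension and token order is
#'     irrelevant (default).}
#'   \item{`pad_concat`}{vectors concatenated in order and zero-padded
#'     or truncated to `L_max * (m + 1) * dim`, the literal
#'     concatenation reading; token order matters.}
#' }
#' A sentence with no in-vocabulary token yields an all-zero vector.
#'
#' @param sentence a `biosumm_sentence` (or a character token vector).
#' @param model an `embedding_model`.
#' @param m neighbours per word.
#' @param policy `"mean"` or `"pad_concat"`.
#' @param L_max maximum token count assumed under `pad_concat`.
#' @return a `big_vector`: numeric vector with attributes
#'   `sentence_index` and `policy`.
#' @export
build_big_vector <- function(sentence, model, m = 3L,
                             policy = c("mean", "pad_concat"),
                             L_max = 30L) {
  policy <- match.arg(policy)
  tokens <- if (inherits(sentence, "biosumm_sentence")) {
    sentence$tokens
  } else {
    as.character(sentence)
  }
  idx <- if (inherits(sentence, "biosumm_sentence")) sentence$index else 1L
  if (policy == "pad_concat" && L_max < 1) {
    bs_invalid("`L_max` must be >= 1 for pad_concat")
  }
  d <- model$dim
  expansion <- list()
  for (tok in tokens) {
    if (!emb_contains(model, tok)) next
    words <- c(tok, beta_neighbors(tok, m, model))
    for (w in words) expansion[[length(expansion) + 1L]] <- emb_vector(model, w)
  }
  if (policy == "mean") {
    if (length(expansion) == 0) {
      values <- numeric(d)
    } else {
      values <- Reduce(`+`, expansion) / length(expansion)
    }
  } else {
    D <- as.integer(L_max) * (as.integer(m) + 1L) * d
    values <- numeric(D)
    if (length(expansion) > 0) {
      flat <- unlist(expansion, use.names = FALSE)
      take <- min(length(flat), D)
      values[seq_len(take)] <- flat[seq_len(take)]
    }
  }
  structure(values, sentence_index = idx, policy = policy,
            class = "big_vector")
}

#' Big-vectors for a whole document
#'
#' @param document a `biosumm_document`.
#' @inheritParams build_big_vector
#' @return numeric matrix, one row per sentence (rows in sentence order).
#' @export
document_big_vectors <- function(document, model, m = 3L,
                                 policy = c("mean", "pad_concat"),
                                 L_max = NULL) {
  policy <- match.arg(policy)
  if (is.null(L_max)) {
    lens <- vapply(document$sentences, function(s) length(s$tokens),
                   integer(1))
    L_max <- max(1, ceiling(stats::quantile(lens, 0.95, names = FALSE)))
  }
  rows <- lapply(document$sentences, function(s) {
    as.numeric(build_big_vector(s, model, m = m, policy = policy,
                                L_max = L_max))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- NULL
  mat
}

#' Read word vectors in word2vec text format
#'
#' First line `"<count> <dim>"`, then one `"word v1 ... vdim"` line per
#' word.
#'
#' @param path path to the vector file.
#' @return an `embedding_model`.
#' @export
read_word2vec <- function(path) {
  if (!file.exists(path)) bs_invalid(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 2) bs_empty("vector file has no entries")
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(header) != 2 || anyNA(header)) {
    bs_invalid("malformed word2vec header (expected 'count dim')")
  }
  n <- header[1]; d <- header[2]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    warning(sprintf("header count %d but %d entries found", n,
                    length(body)), call. = FALSE)
  }
  parts <- strsplit(trimws(body), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(mat) <- words
  embedding_model(mat)
}
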