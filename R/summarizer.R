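# Pipeline orchestration: preprocess -> big-vectors -> cluster -> rank ->
# redundancy filter -> ratio-bounded selection, emitted in document order.

#' Summarization configuration
#'
#' @param ratio summary length as a fraction of the document's sentence
#'   count, in `(0, 1]`. The two conventional settings are 0.15 (short)
#'   and 0.25 (long).
#' @param m neighbours per word in the big-vector expansion.
#' @param k cluster count; `NULL` selects `max(2, round(sqrt(n/2)))`.
#' @param seed RNG seed (clustering initialization).
#' @param epsilon intra-cluster redundancy threshold on the total-score
#'   scale.
#' @param policy big-vector combination policy (`"mean"` or
#'   `"pad_concat"`).
#' @param connecting_words connective lexicon for the predecessor rule.
#' @param n_init k-means restarts.
#' @param weights optional named feature weights.
#' @return a `summary_config` list.
#' @export
summary_config <- function(ratio = 0.25, m = 3L, k = NULL, seed = 42L,
                           epsilon = 0.05,
                           policy = c("mean", "pad_concat"),
                           connecting_words = default_connecting_words(),
                           n_init = 10L, weights = NULL) {
  policy <- match.arg(policy)
  if (!is.numeric(ratio) || ratio <= 0 || ratio > 1) {
    bs_invalid("ratio must be in (0, 1]")
  }
  if (!is.numeric(m) || m < 0) bs_invalid("m must be >= 0")
  structure(
    list(ratio = ratio, m = as.integer(m), k = k,
         seed = as.integer(seed), epsilon = epsilon, policy = policy,
         connecting_words = connecting_words,
         n_init = as.integer(n_init), weights = weights),
    class = "summary_config"
  )
}

#' Select a ratio-bounded summary from ranked eligible sentences
#'
#' Budget is `max(1, round(ratio * n))` sentences. The highest-total
#' eligible sentences fill the budget (ties broken by higher position
#' score, then lower index); the connecting-word rule may then add
#' predecessors beyond the budget. Output order is document order.
#'
#' @param scores feature table from [score_sentences()].
#' @param eligible logical eligibility vector (from
#'   [redundancy_filter()]; empty-token sentences should already be
#'   `FALSE`).
#' @param document the `biosumm_document`.
#' @param ratio fraction of `document$n` to keep.
#' @param connecting_words connective lexicon.
#' @return a `biosumm_summary`: list with `selected` (ascending
#'   indices), `text`, `budget`, `n`.
#' @export
select_summary <- function(scores, eligible, document, ratio,
                           connecting_words = default_connecting_words()) {
  if (!any(eligible)) bs_error("biosumm_empty_summary",
                               "no eligible sentence to select")
  n <- document$n
  budget <- max(1L, as.integer(round_half_up(ratio * n)))
  pool <- scores[eligible, , drop = FALSE]
  ord <- order(-pool$total, -pool$position, pool$index)
  take <- pool$index[ord][seq_len(min(budget, nrow(pool)))]
  selected <- apply_connecting_rule(sort(take), document,
                                    lexicon = connecting_words)
  text <- paste(vapply(selected,
                       function(i) document$sentences[[i]]$surface,
                       character(1)),
                collapse = " ")
  structure(list(selected = as.integer(selected), text = text,
                 budget = budget, n = n),
            class = "biosumm_summary")
}

#' @export
print.biosumm_summary <- function(x, ...) {
  cat(sprintf("<biosumm_summary> %d of %d sentences (budget %d)\n",
              length(x$selected), x$n, x$budget))
  cat(sprintf("  indices: %s\n", paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Summarize one article end to end
#'
#' Runs the full pipeline: structural stripping and sentence
#' segmentation, token normalization, big-vector construction, seeded
#' k-means clustering, six-feature scoring with normalization,
#' intra-cluster redundancy elimination, and ratio-bounded selection
#' with the connecting-word rule. Deterministic given the article, the
#' embedding model and the configuration (including seed).
#'
#' @param article a `raw_article`, a `biosumm_document`, or a character
#'   string of article text.
#' @param model an `embedding_model`.
#' @param config a [summary_config()].
#' @param annotator annotator for preprocessing (ignored when `article`
#'   is already a `biosumm_document`).
#' @return a `biosumm_summary`; the run manifest (config, k, feature
#'   table, eligibility, clustering) is attached as attribute
#'   `manifest`.
#' @export
summarize_document <- function(article, model,
                               config = summary_config(),
                               annotator = builtin_annotator()) {
  document <- if (inherits(article, "biosumm_document")) {
    article
  } else {
    prepare_document(article, annotator = annotator)
  }
  n <- document$n
  usable <- vapply(document$sentences,
                   function(s) length(s$tokens) > 0, logical(1))
  if (n == 0 || sum(usable) < 2) {
    warning("document has fewer than 2 usable sentences; returning it whole",
            call. = FALSE)
    sel <- seq_len(n)
    text <- paste(vapply(document$sentences, function(s) s$surface,
                         character(1)), collapse = " ")
    return(structure(list(selected = as.integer(sel), text = text,
                          budget = max(1L, n), n = n),
                     class = "biosumm_summary"))
  }

  vectors <- document_big_vectors(document, model, m = config$m,
                                  policy = config$policy)
  k <- choose_k(n, override = config$k)
  clustering <- kmeans_cluster(vectors, k, seed = config$seed,
                               n_init = config$n_init)
  scores <- score_sentences(document, vectors, weights = config$weights)
  eligible <- redundancy_filter(clustering, scores,
                                epsilon = config$epsilon,
                                document = document) & usable
  if (!any(eligible)) eligible <- usable  # degenerate: everything collided
  summary <- select_summary(scores, eligible, document,
                            ratio = config$ratio,
                            connecting_words = config$connecting_words)
  attr(summary, "manifest") <- list(
    config = config, k = k, clustering = clustering, scores = scores,
    eligible = eligible
  )
  summary
}

#' Write a summary and its run manifest
#'
#' @param summary a `biosumm_summary`.
#' @param out path for the UTF-8 plain-text summary.
#' @param manifest_out optional path for a JSON run manifest (config,
#'   k, budget, selected indices).
#' @return `out`, invisibly.
#' @export
write_summary <- function(summary, out, manifest_out = NULL) {
  writeLines(summary$text, out, useBytes = TRUE)
  if (!is.null(manifest_out)) {
    man <- attr(summary, "manifest")
    cfg <- if (is.null(man)) NULL else man$config
    jsonlite::write_json(
      list(
        selected = summary$selected, budget = summary$budget,
        n = summary$n,
        k = if (is.null(man)) NULL else man$k,
        config = if (is.null(cfg)) NULL else {
          cfg[c("ratio", "m", "seed", "epsilon", "policy", "n_init")]
        }
      ),
      manifest_out, auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(out)
}
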