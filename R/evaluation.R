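# ROUGE-1/2/L scoring of system summaries against references, plus batch
# macro-averaging over document pairs.

#' Tokenize text for ROUGE scoring
#'
#' Lowercases and splits on non-alphanumeric characters; the same
#' pipeline is applied to both system and reference sides. No stemming,
#' no stop-word removal.
#'
#' @param text character scalar.
#' @return character vector of tokens.
#' @export
rouge_tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

rouge_result <- function(variant, precision, recall) {
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(variant = variant, precision = precision,
                 recall = recall, f_score = f),
            class = "rouge_result")
}

#' @export
print.rouge_result <- function(x, ...) {
  cat(sprintf("ROUGE-%s  Pr=%.4f  Rc=%.4f  Fs=%.4f\n",
              x$variant, x$precision, x$recall, x$f_score))
  invisible(x)
}

ngrams <- function(tokens, n) {
  k <- length(tokens) - n + 1
  if (k < 1) return(character(0))
  vapply(seq_len(k), function(i) {
    paste(tokens[i:(i + n - 1)], collapse = " ")
  }, character(1))
}

#' ROUGE-N (unigram/bigram co-occurrence)
#'
#' Overlap is the clipped multiset intersection of n-grams; recall is
#' overlap over the reference n-gram count, precision over the system
#' n-gram count. Empty denominators give 0.
#'
#' @param system system summary: text or pre-tokenized character vector.
#' @param reference reference summary, same convention.
#' @param n n-gram order, 1 or 2.
#' @return a `rouge_result`.
#' @export
rouge_n <- function(system, reference, n = 1L) {
  if (!n %in% c(1L, 2L)) bs_invalid("n must be 1 or 2")
  sys_tok <- if (length(system) == 1L) rouge_tokenize(system) else system
  ref_tok <- if (length(reference) == 1L) rouge_tokenize(reference) else reference
  sg <- ngrams(sys_tok, n)
  rg <- ngrams(ref_tok, n)
  if (length(sg) == 0 || length(rg) == 0) {
    return(rouge_result(paste0("R", n), 0, 0))
  }
  st <- table(sg)
  rt <- table(rg)
  shared <- intersect(names(st), names(rt))
  overlap <- sum(pmin(st[shared], rt[shared]))
  rouge_result(paste0("R", n), overlap / length(sg), overlap / length(rg))
}

lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  prev <- integer(nb + 1)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1)
    for (j in seq_len(nb)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L
                    else max(cur[j], prev[j + 1])
    }
    prev <- cur
  }
  prev[nb + 1]
}

#' ROUGE-L (longest common subsequence)
#'
#' Recall is LCS length over the reference length, precision over the
#' system length.
#'
#' @inheritParams rouge_n
#' @return a `rouge_result`.
#' @export
rouge_l <- function(system, reference) {
  sys_tok <- if (length(system) == 1L) rouge_tokenize(system) else system
  ref_tok <- if (length(reference) == 1L) rouge_tokenize(reference) else reference
  if (length(sys_tok) == 0 || length(ref_tok) == 0) {
    return(rouge_result("RL", 0, 0))
  }
  L <- lcs_length(sys_tok, ref_tok)
  rouge_result("RL", L / length(sys_tok), L / length(ref_tok))
}

#' All three ROUGE variants for one pair
#'
#' @inheritParams rouge_n
#' @return data.frame with one row per variant (R1, R2, RL) and columns
#'   `variant`, `precision`, `recall`, `f_score`.
#' @export
rouge_all <- function(system, reference) {
  rows <- list(rouge_n(system, reference, 1L),
               rouge_n(system, reference, 2L),
               rouge_l(system, reference))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(variant = r$variant, precision = r$precision,
               recall = r$recall, f_score = r$f_score)
  }))
}

#' Batch ROUGE evaluation with macro-averaging
#'
#' Scores each (system, reference) pair and reports the unweighted mean
#' of precision/recall/F per variant over documents. Pairs whose files
#' cannot be read are skipped and counted.
#'
#' @param pairs data.frame with columns `system` and `reference`; each
#'   entry is either a file path or literal text (controlled by
#'   `as_files`).
#' @param as_files if `TRUE` (default) entries are paths read from disk.
#' @return list with `per_document` (long data.frame with a `doc`
#'   column), `averages` (one row per variant) and `skipped` (count).
#' @export
batch_evaluate <- function(pairs, as_files = TRUE) {
  if (nrow(pairs) == 0) bs_empty("no pairs to evaluate")
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    sys_src <- pairs$system[i]
    ref_src <- pairs$reference[i]
    if (as_files) {
      if (!file.exists(sys_src) || !file.exists(ref_src)) {
        warning(sprintf("pair %d skipped: missing file", i),
                call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      sys_src <- paste(readLines(sys_src, warn = FALSE), collapse = " ")
      ref_src <- paste(readLines(ref_src, warn = FALSE), collapse = " ")
    }
    tab <- rouge_all(sys_src, ref_src)
    tab$doc <- i
    rows[[length(rows) + 1L]] <- tab
  }
  if (length(rows) == 0) bs_empty("every pair was skipped")
  per_doc <- do.call(rbind, rows)
  averages <- do.call(rbind, lapply(split(per_doc, per_doc$variant),
    function(d) {
      data.frame(variant = d$variant[1],
                 precision = mean(d$precision),
                 recall = mean(d$recall),
                 f_score = mean(d$f_score))
    }))
  rownames(averages) <- NULL
  averages <- averages[match(c("R1", "R2", "RL"), averages$variant), ]
  list(per_document = per_doc, averages = averages, skipped = skipped)
}
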