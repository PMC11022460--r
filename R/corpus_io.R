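# Corpus input: raw article handling, structural stripping, sentence
# segmentation, and token-level normalization (lowercasing, lemmatization,
# punctuation/number removal) behind a pluggable annotator interface.

#' Construct a raw article
#'
#' @param text full UTF-8 article text.
#' @param source_id opaque identifier (defaults to `"article"`).
#' @return an object of class `raw_article`.
#' @export
raw_article <- function(text, source_id = "article") {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    bs_invalid("`text` must be a single character string")
  }
  if (!nzchar(trimws(text))) bs_empty("article text is empty")
  structure(list(source_id = source_id, text = text), class = "raw_article")
}

#' Read a plain-text article from disk
#'
#' @param path path to a UTF-8 `.txt` file, one article per file.
#' @param source_id identifier; defaults to the file name without extension.
#' @return a `raw_article`.
#' @export
read_article <- function(path, source_id = NULL) {
  if (!file.exists(path)) bs_invalid(sprintf("no such file: %s", path))
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw_article(txt, source_id)
}

#' Default section-header lexicon
#'
#' Section labels whose content is dropped before summarization: front
#' matter (abstract), back matter (references, bibliography,
#' acknowledgements) and float captions (figure, table).
#'
#' @return character vector of lowercase section keywords.
#' @export
default_section_lexicon <- function() {
  c("abstract", "references", "bibliography", "acknowledgements",
    "acknowledgments", "figure", "table", "fig.")
}

# A standalone line that looks like a section heading: short, starts with
# an uppercase letter (or is all-caps), and carries no sentence terminator.
is_heading_line <- function(line) {
  s <- trimws(line)
  if (!nzchar(s) || nchar(s) > 80) return(FALSE)
  if (grepl("[.!?;,]$", s)) return(FALSE)
  words <- strsplit(s, "\\s+")[[1]]
  if (length(words) > 8) return(FALSE)
  grepl("^[A-Z0-9]", s)
}

# Lowercased first word of a heading-like line, trailing colon stripped.
heading_keyword <- function(line) {
  s <- tolower(trimws(line))
  s <- sub(":$", "", s)
  strsplit(s, "\\s+")[[1]][1]
}

is_caption_line <- function(line) {
  grepl("^\\s*(figure|fig\\.?|table)\\s*([0-9]|:)", line,
        ignore.case = TRUE)
}

#' Strip non-body structure from an article
#'
#' Removes the title block, the abstract section, figure/table caption
#' lines, and everything from a references (or bibliography) heading
#' onward. Standalone section-heading lines are dropped as well, since
#' they are not sentences. If no recognized heading is found the text is
#' returned unchanged with a warning. Retained text keeps its original
#' order.
#'
#' @param article a `raw_article` or a single character string.
#' @param lexicon lowercase section keywords (see
#'   [default_section_lexicon()]).
#' @return the body text as a single string.
#' @export
strip_structure <- function(article, lexicon = default_section_lexicon()) {
  text <- if (inherits(article, "raw_article")) article$text else article
  if (!is.character(text) || length(text) != 1L ||
      !nzchar(trimws(text))) {
    bs_empty("article text is empty")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]

  kw <- vapply(lines, function(l) {
    if (is_heading_line(l)) heading_keyword(l) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  recognized <- any(kw %in% lexicon, na.rm = TRUE) |
    any(vapply(lines, is_caption_line, logical(1)))
  if (!recognized) {
    warning("no recognized section headings; article returned unchanged",
            call. = FALSE)
    return(text)
  }

  # Title block: leading heading-like lines up to the first blank line.
  start <- 1L
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) > 0 && is_heading_line(lines[nonblank[1]]) &&
      !(kw[nonblank[1]] %in% lexicon)) {
    blank_after <- which(!nzchar(trimws(lines)) &
                           seq_along(lines) > nonblank[1])
    if (length(blank_after) > 0) start <- blank_after[1] + 1L
  }

  kept <- character(0)
  skipping <- FALSE
  for (i in seq(start, length(lines))) {
    if (i > length(lines)) break
    line <- lines[i]
    blank <- !nzchar(trimws(line))
    if (blank) {
      if (skipping) skipping <- FALSE else kept <- c(kept, line)
      next
    }
    k <- kw[i]
    if (!is.na(k) && k %in% c("references", "bibliography")) break
    if (is_caption_line(line)) next            # drops that line only
    if (!is.na(k) && k %in% lexicon) {         # abstract, acknowledgements
      skipping <- TRUE
      next
    }
    if (skipping) next
    if (!is.na(k)) next                        # other standalone headings
    kept <- c(kept, line)
  }
  trimws(paste(kept, collapse = "\n"))
}

# Abbreviations that end with a period but do not end a sentence.
.abbreviations <- c(
  "e.g.", "i.e.", "et al.", "al.", "fig.", "figs.", "eq.", "eqs.",
  "dr.", "mr.", "mrs.", "ms.", "prof.", "vs.", "cf.", "ca.", "approx.",
  "no.", "nos.", "ref.", "refs.", "resp.", "spp.", "sp.", "etc."
)

#' Segment body text into sentences
#'
#' Splits on `.`, `!` or `?` followed by whitespace and an
#' uppercase/digit/quote sentence opener; decimal numbers (`pH 7.4`) are
#' never split points and a hand list of common abbreviations (`e.g.`,
#' `et al.`, `Fig.`) suppresses false breaks. Blank lines are hard
#' paragraph boundaries. A trailing fragment without a terminator is kept
#' as a sentence.
#'
#' @param body body text (single string).
#' @return character vector of surface sentences (possibly empty).
#' @export
segment_sentences <- function(body) {
  if (!is.character(body) || length(body) != 1L) {
    bs_invalid("`body` must be a single character string")
  }
  paragraphs <- strsplit(body, "\n\\s*\n")[[1]]
  out <- character(0)
  for (par in paragraphs) {
    flat <- gsub("\\s+", " ", trimws(par))
    if (!nzchar(flat)) next
    pieces <- strsplit(flat, "(?<=[.!?])\\s+(?=[A-Z0-9\"'(])",
                       perl = TRUE)[[1]]
    # Re-merge splits caused by abbreviations or single-letter initials.
    merged <- character(0)
    for (p in pieces) {
      last <- tolower(sub("^.*\\s", "", p))
      if (length(merged) > 0) {
        prev_last <- tolower(sub("^.*\\s", "", merged[length(merged)]))
        if (prev_last %in% .abbreviations ||
            grepl("^[a-z]\\.$", prev_last) ||
            grepl("\\s(et al\\.)$", tolower(merged[length(merged)]))) {
          merged[length(merged)] <- paste(merged[length(merged)], p)
          next
        }
      }
      merged <- c(merged, p)
    }
    out <- c(out, merged)
  }
  out[nzchar(trimws(out))]
}

#' Built-in rule-based annotator
#'
#' A dependency-free lemmatizer (irregular-form exception table plus
#' suffix rules) and lexicon-driven coarse POS tagger
#' (NOUN/VERB/PROPN/OTHER), sufficient for controlled vocabularies; an
#' external NLP toolkit can be substituted through the same interface.
#'
#' @param extra_lemmas optional named character vector of extra
#'   `word -> lemma` entries (keys lowercase).
#' @param extra_verbs optional character vector of extra verb lemmas.
#' @return a list with functions `lemma(word)` and `tag(tokens)`; class
#'   `biosumm_annotator`.
#' @export
builtin_annotator <- function(extra_lemmas = NULL, extra_verbs = NULL) {
  exceptions <- c(
    better = "good", best = "good", worse = "bad", worst = "bad",
    mice = "mouse", men = "man", women = "woman", children = "child",
    feet = "foot", teeth = "tooth", data = "datum",
    was = "be", were = "be", is = "be", are = "be", am = "be",
    been = "be", being = "be",
    has = "have", had = "have", having = "have",
    did = "do", does = "do", done = "do",
    ran = "run", running = "run", went = "go", gone = "go",
    made = "make", found = "find", shown = "show", showed = "show",
    given = "give", gave = "give", taken = "take", took = "take",
    higher = "high", highest = "high", lower = "low", lowest = "low",
    larger = "large", largest = "large", smaller = "small",
    smallest = "small", greater = "great", greatest = "great"
  )
  if (!is.null(extra_lemmas)) exceptions <- c(extra_lemmas, exceptions)

  verb_lemmas <- c(
    "be", "have", "do", "run", "go", "make", "find", "show", "give",
    "take", "use", "regulate", "inhibit", "activate", "involve",
    "encode", "bind", "mediate", "modulate", "affect", "increase",
    "decrease", "suggest", "indicate", "promote", "suppress", "induce",
    "express", "measure", "observe", "report", "describe", "analyze",
    "require", "reduce", "produce", "contain", "cause", "control",
    "associate", "correlate", "target", "interact", "phosphorylate",
    "sat", "sit", "say", "see", "get", "come", "know", "think", "work"
  )
  if (!is.null(extra_verbs)) verb_lemmas <- c(verb_lemmas, extra_verbs)

  closed_class <- c(
    "the", "a", "an", "of", "in", "on", "at", "to", "for", "with",
    "by", "from", "and", "or", "but", "nor", "so", "yet", "as", "if",
    "than", "that", "this", "these", "those", "it", "its", "their",
    "his", "her", "our", "your", "my", "we", "they", "he", "she", "i",
    "you", "not", "no", "both", "all", "each", "which", "who", "whom",
    "however", "moreover", "because", "therefore", "thus", "hence",
    "furthermore", "additionally", "consequently", "also", "while",
    "when", "where", "between", "among", "during", "after", "before",
    "via", "per", "using", "such", "other", "same", "more", "most",
    "very", "then", "there", "here", "into", "onto", "over", "under"
  )

  lemma_fun <- function(word) {
    w <- tolower(word)
    if (w %in% names(exceptions)) return(unname(exceptions[w]))
    n <- nchar(w)
    if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n > 4 && endsWith(w, "sses")) return(substr(w, 1, n - 2))
    if (n > 4 && grepl("(x|ch|sh|z)es$", w)) return(substr(w, 1, n - 2))
    if (n > 3 && endsWith(w, "s") && !grepl("(ss|us|is)$", w)) {
      return(substr(w, 1, n - 1))
    }
    if (n > 5 && endsWith(w, "ing")) {
      stem <- substr(w, 1, n - 3)
      ns <- nchar(stem)
      if (ns > 2 && substr(stem, ns, ns) == substr(stem, ns - 1, ns - 1)) {
        stem <- substr(stem, 1, ns - 1)                # stopping -> stop
      } else if (paste0(stem, "e") %in% verb_lemmas) {
        stem <- paste0(stem, "e")                      # encoding -> encode
      }
      return(stem)
    }
    if (n > 4 && endsWith(w, "ed")) {
      stem <- substr(w, 1, n - 2)
      ns <- nchar(stem)
      if (ns > 2 && substr(stem, ns, ns) == substr(stem, ns - 1, ns - 1)) {
        stem <- substr(stem, 1, ns - 1)
      } else if (paste0(stem, "e") %in% verb_lemmas) {
        stem <- paste0(stem, "e")
      }
      return(stem)
    }
    w
  }

  tag_fun <- function(tokens) {
    n <- length(tokens)
    if (n == 0) return(character(0))
    tags <- character(n)
    for (j in seq_len(n)) {
      tok <- tokens[j]
      low <- tolower(tok)
      if (!grepl("[A-Za-z]", tok)) {
        tags[j] <- "OTHER"
      } else if (low %in% closed_class) {
        tags[j] <- "OTHER"
      } else if (lemma_fun(low) %in% verb_lemmas) {
        tags[j] <- "VERB"
      } else if (j > 1 && grepl("^[A-Z]", tok)) {
        tags[j] <- "PROPN"
      } else {
        tags[j] <- "NOUN"
      }
    }
    tags
  }

  structure(list(lemma = lemma_fun, tag = tag_fun),
            class = "biosumm_annotator")
}

# Surface tokens: whitespace-delimited pieces with surrounding (but not
# internal) punctuation stripped, so hyphenated terms stay whole.
surface_tokens <- function(surface) {
  raw <- strsplit(trimws(surface), "\\s+")[[1]]
  cleaned <- gsub("^[^A-Za-z0-9]+|[^A-Za-z0-9]+$", "", raw)
  cleaned[nzchar(raw)]
}

is_droppable_token <- function(tok) {
  !nzchar(tok) ||
    !grepl("[A-Za-z0-9]", tok) ||                  # punctuation-only
    grepl("^[0-9]+([.,][0-9]+)*$", tok)            # digit-only
}

#' Preprocess one surface sentence into tokens and tags
#'
#' Tags are computed on the surface tokens (case intact, so proper nouns
#' are detectable), then tokens are lowercased and lemmatized, and
#' punctuation-only or digit-only tokens are removed with their tags
#' filtered in parallel.
#'
#' @param surface the original sentence text.
#' @param index 1-based position of the sentence in its document.
#' @param annotator an annotator, e.g. [builtin_annotator()].
#' @return a `biosumm_sentence`: list with `index`, `surface`, `tokens`,
#'   `pos_tags`.
#' @export
preprocess_sentence <- function(surface, index = 1L,
                                annotator = builtin_annotator()) {
  if (!is.character(surface) || length(surface) != 1L ||
      !nzchar(surface)) {
    bs_invalid("`surface` must be a non-empty string")
  }
  toks <- surface_tokens(surface)
  tags <- annotator$tag(toks)
  stopifnot(length(tags) == length(toks))
  keep <- !vapply(toks, is_droppable_token, logical(1))
  toks <- toks[keep]
  tags <- tags[keep]
  lemmas <- vapply(toks, function(t) tolower(annotator$lemma(tolower(t))),
                   character(1), USE.NAMES = FALSE)
  structure(
    list(index = as.integer(index), surface = surface,
         tokens = lemmas, pos_tags = unname(tags)),
    class = "biosumm_sentence"
  )
}

#' Assemble a document from surface sentences
#'
#' @param surfaces character vector of surface sentences, in order.
#' @param annotator an annotator.
#' @return a `biosumm_document`: list with `sentences` (list of
#'   `biosumm_sentence`, indices 1..n) and `n`.
#' @export
annotate_document <- function(surfaces,
                              annotator = builtin_annotator()) {
  sentences <- lapply(seq_along(surfaces), function(i) {
    preprocess_sentence(surfaces[i], index = i, annotator = annotator)
  })
  structure(list(sentences = sentences, n = length(sentences)),
            class = "biosumm_document")
}

#' Full front-end: article text to annotated document
#'
#' Strips structure, segments sentences and annotates them.
#'
#' @param article a `raw_article` or character string.
#' @param annotator an annotator.
#' @param lexicon section-header lexicon for [strip_structure()].
#' @return a `biosumm_document`.
#' @export
prepare_document <- function(article,
                             annotator = builtin_annotator(),
                             lexicon = default_section_lexicon()) {
  body <- strip_structure(article, lexicon = lexicon)
  annotate_document(segment_sentences(body), annotator = annotator)
}

#' @export
print.biosumm_document <- function(x, ...) {
  cat(sprintf("<biosumm_document> %d sentences\n", x$n))
  for (s in utils::head(x$sentences, 5)) {
    cat(sprintf("  [%d] %s\n", s$index,
                substr(s$surface, 1, 70)))
  }
  if (x$n > 5) cat(sprintf("  ... %d more\n", x$n - 5))
  invisible(x)
}
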