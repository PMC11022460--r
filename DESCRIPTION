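Package: biosumm
Title: Extractive Biomedical Text Summarization with Semantic Big-Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-document extractive summarization for biomedical
    articles. Sentences are expanded into semantic "big-vectors" by
    augmenting each word with its nearest neighbours in a word-embedding
    space, the big-vectors are partitioned with seeded k-means, and
    sentences are ranked by six surface and semantic features (TF-IDF,
    position, length, noun/verb phrase presence, proper nouns, average
    cosine similarity). Near-duplicate sentences within a cluster are
    removed, discourse-connective openers pull in their preceding
    sentence, and the summary is cut to a sentence-count ratio of the
    document. Includes ROUGE-1/2/L evaluation, a reader for word2vec
    text-format vector files, and synthetic fixture generators (toy
    embedding models with planted topic neighbourhoods, multi-topic
    articles with known reference summaries) so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
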