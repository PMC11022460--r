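---
title: "Big-vector extractive summarization: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Big-vector extractive summarization: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosumm)
```

## The model

`biosumm` performs single-document extractive summarization: the
summary is a subset of the document's own sentences, unmodified, in
document order. The pipeline is

preprocess → big-vectors → k-means clustering → six-feature ranking →
redundancy filter → ratio-bounded selection.

The working hypothesis is distributional: words used in similar
contexts have similar meanings, so a sentence can be represented by the
embedding-space neighbourhood of its words rather than by its surface
forms alone. Each word `w` of a sentence is expanded with `β(w)`, its
top-*m* most-similar in-vocabulary words under cosine similarity, and
the union of word and neighbour vectors forms the sentence's
*big-vector*. Clustering big-vectors groups sentences that talk about
the same thing even when they share few literal words; the redundancy
filter then exploits exactly this property to drop restatements.

### Big-vector combination policies

A literal concatenation of per-word expansions yields vectors whose
length varies with sentence length, which no standard clusterer
accepts. Two policies are provided:

- **`mean`** (default): the arithmetic mean of all expansion-set
  vectors. Fixed dimension (the embedding dimension), invariant to
  token order, robust to sentence-length variation. This is the
  centroid-of-neighbourhood reading of the representation.
- **`pad_concat`**: vectors concatenated in sentence order, zero-padded
  or truncated to `L_max · (m+1) · dim`, where `L_max` defaults to the
  95th percentile of the document's sentence lengths. This preserves
  word order at the cost of a high-dimensional, padding-dominated
  geometry.

Both satisfy the k-means precondition of dimensional homogeneity; the
test suite asserts the order-invariance of `mean` and the
order-sensitivity of `pad_concat`. Out-of-vocabulary tokens are
skipped rather than given random vectors — random vectors would inject
noise into the cluster geometry, and skipping keeps the representation
a function of the model's actual knowledge. A sentence with no
in-vocabulary token gets an all-zero big-vector, contributes zero to
every cosine, and is ineligible for selection.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `m` | 3 | neighbours per word in `β`. Small values limit topic drift: each additional neighbour is farther from the word and more likely to blur topics. |
| `ratio` | 0.25 | summary budget as a fraction of document sentences; 0.15 and 0.25 are the conventional short/long settings. The budget unit is sentences (selection is sentence-atomic): `max(1, round(ratio · n))`. |
| `k` | `max(2, round(sqrt(n/2)))`, capped at `n` | cluster count. The square-root heuristic is a standard default when no domain value is known; an override is accepted. |
| `epsilon` | 0.05 | redundancy threshold on the total-score scale (`[0, 6]`). Two same-cluster sentences within `epsilon` are considered restatements; the one with the higher position score survives. |
| `seed` | 42 | drives k-means++ initialization; fixed seed makes the whole pipeline deterministic. |
| `n_init` | 10 | k-means restarts, best inertia kept. |
| `policy` | `mean` | big-vector combination policy (above). |
| `connecting_words` | however, moreover, but, because, therefore, thus, hence, furthermore, additionally, consequently | connective lexicon for the predecessor rule — a superset of the four canonical examples, configurable. |

Feature weights default to 1 (an unweighted sum of the six normalized
features); `summary_config(weights = …)` can re-weight them.

## Ranking details

- **TF-IDF corpus definition.** The summarizer is single-document, so
  the IDF corpus is the document's own sentences: each sentence is one
  "document", `idf(w) = ln(n / df(w))`. A word present in every
  sentence carries zero weight, which is the behaviour wanted from a
  discriminative feature.
- **Normalization.** Each feature column is min-max rescaled to
  `[0, 1]` across the document; a constant column maps to all zeros
  (it cannot discriminate, so it contributes nothing).
- **Cosine feature.** The average-cosine feature uses the big-vectors
  themselves (consistent with the semantic representation); the sum
  over the `n − 1` other sentences is divided by `n`, bounding the
  value by `(n−1)/n`.
- **Phrase feature.** Coarse POS presence (≥ 1 noun and ≥ 1 verb → 1,
  exactly one category → 0.5, neither → 0) rather than parser-derived
  constituents, keeping the default pipeline dependency-free.
- **Redundancy rule.** Applied within clusters only. Verbatim repeats
  (identical token sequences) are additionally treated as redundant
  regardless of `epsilon`: two identical sentences differ in total
  score only through position, which is precisely the tie the rule
  resolves by position — so an `epsilon` on totals alone cannot be
  relied on to catch them.
- **Connecting-word rule.** Applied to a fixed point after selection: a
  forced-in antecedent that itself opens with a connective pulls in its
  own predecessor. Insertions may exceed the budget; the budget
  contract `|selected| = max(1, round(ratio·n))` holds exactly when no
  insertion fires.

## Preprocessing choices

Structural stripping is lexicon-driven (abstract, references,
bibliography, acknowledgements, figure/table captions), with headings
matched case-insensitively at line starts; caption lines are dropped
individually, reference sections to the end of the document, and the
abstract to the end of its paragraph. Standalone heading lines are
removed — they are labels, not sentences. An article with no
recognized structure passes through unchanged with a warning.
Stop-words are **not** removed, hyphenated terms stay single tokens
(splitting "beta-blocker" destroys the term), and sentences whose
token list empties out (all punctuation/digits) are kept in the
document to preserve 1-based index arithmetic but are never selectable.

The default annotator is a bundled rule-based lemmatizer (exception
table plus suffix rules) and a lexicon POS tagger; both are
deterministic and adequate for controlled vocabularies. On real
biomedical prose a proper NLP toolkit should be substituted through the
`lemma()`/`tag()` interface — the rule-based tagger's proper-noun
heuristic (capitalized, non-sentence-initial) and small verb lexicon
are the crudest parts of the default pipeline.

## Numerical and determinism choices

- k-means: k-means++ initialization, Lloyd iteration, convergence when
  the maximum squared centroid shift drops below `1e-6` or assignments
  stabilize; `max_iter = 300`. Empty clusters are repaired by donating
  the point farthest from its current centroid. Distance is Euclidean;
  a cosine-like geometry is available by pre-normalizing rows
  (`normalize = TRUE`), off by default.
- Neighbour ranking ties are broken lexicographically, point-assignment
  ties by lowest cluster index, selection ties by higher position score
  then lower sentence index. Every tie-break is deterministic, which
  is what makes byte-identical reruns possible.
- Budgets use half-up rounding (`floor(x + 0.5)`) rather than the
  platform's round-half-even, so `round(2.5) = 3` on every machine.
- ROUGE tokenization lowercases and splits on non-alphanumerics, with
  stemming and stop-word removal off, applied identically to system
  and reference sides; empty denominators yield 0.

## What the synthetic fixtures do and do not show

`make_toy_embedding_model()` plants topic structure: each topic has an
anchor vector (anchors pairwise `separation` apart) and each word is
its anchor plus isotropic Gaussian noise (`noise_scale`). The default
study condition is `separation = 6 × noise_scale`, where topics are
well separated and big-vector cluster purity is expected ≥ 0.9.
`make_synthetic_article()` writes articles whose body mixes one
designated key sentence per topic (longer, proper-noun-richer — planted
ranking signal) with filler, optional verbatim repeats, connective
openers, and the title/abstract/references scaffolding the stripper
removes. The reference summary is the set of key sentences, mirroring
the article/abstract pairing used in biomedical summarization corpora.
Test problem sizes — 3 topics × 8 words, 12–15 sentences per article,
10–20 articles or seeds per property — were chosen as the smallest
sizes at which the planted structure is unambiguous.

What passing on these fixtures shows: the pipeline's machinery is
correct — representations separate separable topics, ranking responds
to the planted features, contracts (budgets, determinism, redundancy,
connectives) hold. What it does not show: performance on real
biomedical prose, whose topics overlap, whose vocabulary is mostly
out-of-vocabulary for any fixed model, and whose reference abstracts
are abstractive rather than extracts. Published-corpus scores require
real articles and pretrained biomedical embeddings, both outside the
package's test scope by design.

## Known limitations

- The rule-based annotator under-lemmatizes irregular forms outside its
  exception table and over-triggers PROPN on mid-sentence capitalized
  acronyms.
- `pad_concat` big-vectors are dominated by zero padding for short
  sentences; `mean` is the recommended policy.
- k-means with few restarts can land in local optima on hard
  geometries; the exhaustive-partition oracle in the tests bounds this
  only at small n.
- Sentence segmentation is regex-based with a finite abbreviation
  list; exotic abbreviation patterns can over-split.
- ROUGE is implemented without stemming/stop-list options' many
  historical variants; scores are comparable within the package, not
  byte-compatible with every external ROUGE configuration.
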