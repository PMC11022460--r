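# Independent oracles: deliberately naive implementations used to check
# the package's code paths. They share no code with the package.

# Brute-force cosine nearest neighbours over a small vocabulary.
oracle_neighbors <- function(word, m, vectors) {
  if (m == 0 || !(word %in% rownames(vectors))) return(character(0))
  v <- vectors[word, ]
  others <- setdiff(rownames(vectors), word)
  sims <- sapply(others, function(w) {
    u <- vectors[w, ]
    sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  })
  ord <- order(-sims, others)
  others[ord][seq_len(min(m, length(others)))]
}

# Exhaustive minimum within-cluster SSE over all assignments of n points
# into k non-empty clusters (feasible for n <= 8, k <= 3).
oracle_min_inertia <- function(x, k) {
  n <- nrow(x)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < k) next
    sse <- 0
    for (cl in seq_len(k)) {
      pts <- x[a == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      sse <- sse + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, sse)
  }
  best
}

# Recursive memoized LCS length (top-down, unlike the package's
# bottom-up DP).
oracle_lcs <- function(a, b) {
  memo <- new.env()
  rec <- function(i, j) {
    if (i == 0 || j == 0) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a[i] == b[j]) {
      rec(i - 1L, j - 1L) + 1L
    } else {
      max(rec(i - 1L, j), rec(i, j - 1L))
    }
    memo[[key]] <- val
    val
  }
  rec(length(a), length(b))
}

# Clipped n-gram overlap ROUGE computed with plain loops.
oracle_rouge_n <- function(sys_tok, ref_tok, n) {
  grams <- function(t) {
    if (length(t) < n) return(character(0))
    sapply(seq_len(length(t) - n + 1),
           function(i) paste(t[i:(i + n - 1)], collapse = "|"))
  }
  sg <- grams(sys_tok); rg <- grams(ref_tok)
  if (length(sg) == 0 || length(rg) == 0) return(c(0, 0, 0))
  ov <- 0
  rg_left <- rg
  for (g in sg) {
    hit <- match(g, rg_left)
    if (!is.na(hit)) {
      ov <- ov + 1
      rg_left <- rg_left[-hit]
    }
  }
  pr <- ov / length(sg); rc <- ov / length(rg)
  fs <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  c(pr, rc, fs)
}

# Shared small fixtures.
toy_abc_model <- function() {
  embedding_model(matrix(c(1, 0, 0.9, 0.1, 0, 1), ncol = 2,
                         byrow = TRUE,
                         dimnames = list(c("a", "b", "c"), NULL)))
}

fixture_annotator <- function() {
  builtin_annotator(extra_lemmas = c(dogs = "dog", running = "run",
                                     fast = "fast"))
}
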