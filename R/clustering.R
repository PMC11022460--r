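# Seeded, deterministic k-means over big-vectors. Lloyd iteration from
# k-means++ starts; clusters are guaranteed non-empty by reassigning the
# point farthest from its centroid into any cluster that empties out.
# stats::kmeans is not used directly because it offers neither an
# empty-cluster repair nor a k-means++ start; it serves as an independent
# cross-check in the test suite instead.

sq_dist_to <- function(x, center) {
  colSums((t(x) - center)^2)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1)
  centers[1, ] <- x[first, ]
  if (k == 1) return(centers)
  d2 <- sq_dist_to(x, centers[1, ])
  for (j in 2:k) {
    if (sum(d2) == 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, sq_dist_to(x, centers[j, ]))
  }
  centers
}

lloyd_once <- function(x, k, max_iter, tol) {
  n <- nrow(x)
  centers <- kmeanspp_init(x, k)
  assign_prev <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d2 <- vapply(seq_len(k), function(j) sq_dist_to(x, centers[j, ]),
                 numeric(n))
    d2 <- matrix(d2, nrow = n)
    assignment <- max.col(-d2, ties.method = "first")
    # Empty-cluster repair: move the globally farthest point into each
    # empty cluster.
    repeat {
      empties <- setdiff(seq_len(k), unique(assignment))
      if (length(empties) == 0) break
      cur <- d2[cbind(seq_len(n), assignment)]
      donors <- order(-cur)
      for (e in empties) {
        for (cand in donors) {
          lbl <- assignment[cand]
          if (sum(assignment == lbl) > 1) {
            assignment[cand] <- e
            d2[cand, ] <- 0  # pin: its own (new) centroid will sit on it
            break
          }
        }
      }
    }
    new_centers <- t(vapply(seq_len(k), function(j) {
      colMeans(x[assignment == j, , drop = FALSE])
    }, numeric(ncol(x))))
    shift <- max(rowSums((new_centers - centers)^2))
    centers <- new_centers
    if (all(assignment == assign_prev) || shift < tol) break
    assign_prev <- assignment
  }
  d2 <- vapply(seq_len(k), function(j) sq_dist_to(x, centers[j, ]),
               numeric(n))
  d2 <- matrix(d2, nrow = n)
  inertia <- sum(d2[cbind(seq_len(n), assignment)])
  list(assignment = assignment, centers = centers, inertia = inertia)
}

#' Cluster big-vectors with seeded k-means
#'
#' Lloyd iteration from a k-means++ start, repeated `n_init` times with
#' the lowest-inertia solution kept. Identical inputs and seed give
#' identical output; every cluster has at least one member.
#'
#' @param vectors numeric matrix, one row per sentence big-vector.
#' @param k number of clusters, `1 <= k <= nrow(vectors)`.
#' @param seed RNG seed for initialization.
#' @param max_iter maximum Lloyd iterations per start.
#' @param tol convergence threshold on the maximum squared centroid
#'   shift.
#' @param n_init number of k-means++ restarts.
#' @param normalize if `TRUE`, rows are L2-normalized first (cosine-like
#'   geometry); off by default.
#' @return a `biosumm_clustering`: list with `assignment` (1-based
#'   labels per row), `centroids` (k x D matrix), `inertia`, `k`.
#' @export
kmeans_cluster <- function(vectors, k, seed = 42L, max_iter = 300L,
                           tol = 1e-6, n_init = 10L,
                           normalize = FALSE) {
  if (!is.matrix(vectors)) vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n == 0) bs_empty("no vectors to cluster")
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k > n) {
    bs_invalid(sprintf("k must be in [1, %d]", n))
  }
  k <- as.integer(k)
  x <- vectors
  if (normalize) {
    nrm <- sqrt(rowSums(x^2))
    nz <- nrm > 0
    x[nz, ] <- x[nz, , drop = FALSE] / nrm[nz]
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- lloyd_once(x, k, max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia - 1e-12) {
        best <- fit
      }
    }
  })
  structure(
    list(assignment = best$assignment, centroids = best$centers,
         inertia = best$inertia, k = k),
    class = "biosumm_clustering"
  )
}

#' @export
print.biosumm_clustering <- function(x, ...) {
  cat(sprintf("<biosumm_clustering> k=%d, n=%d, inertia=%.4g\n",
              x$k, length(x$assignment), x$inertia))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Choose the number of clusters for a document
#'
#' `max(2, round(sqrt(n/2)))`, capped at `n`; an explicit override wins.
#'
#' @param n document sentence count.
#' @param override optional integer in `[1, n]`.
#' @return integer k.
#' @export
choose_k <- function(n, override = NULL) {
  if (!is.numeric(n) || n < 1) bs_invalid("n must be >= 1")
  if (!is.null(override)) {
    if (!is.numeric(override) || override < 1 || override > n) {
      bs_invalid(sprintf("k override must be in [1, %d]", n))
    }
    return(as.integer(override))
  }
  as.integer(min(n, max(2, round_half_up(sqrt(n / 2)))))
}

#' Cluster purity against ground-truth labels
#'
#' Fraction of items whose cluster's majority label equals their own
#' label.
#'
#' @param assignment cluster labels.
#' @param truth ground-truth labels (same length).
#' @return purity in `[0, 1]`.
#' @export
cluster_purity <- function(assignment, truth) {
  stopifnot(length(assignment) == length(truth))
  tab <- table(assignment, truth)
  sum(apply(tab, 1, max)) / length(assignment)
}
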