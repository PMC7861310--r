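#' K-means++ clustering
#'
#' D^2-weighted seeding followed by Lloyd iterations (convergence when the
#' largest centroid shift drops below 1e-6, cap 300 iterations); the best
#' of `n_restarts` runs by within-cluster sum of squares is returned.
#' Fully deterministic for a fixed seed; the caller's RNG stream is left
#' untouched.
#'
#' @param points numeric matrix P x n.
#' @param k number of clusters, 1 <= k <= P.
#' @param seed RNG seed for seeding and restarts.
#' @param n_restarts independent restarts.
#' @return A `clustering_result`: labels (1-based), k, method, seed,
#'   centers, wss.
#' @export
kmeans_pp <- function(points, k, seed = 1L, n_restarts = 10L) {
  stopifnot(is.matrix(points))
  P <- nrow(points); k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > P) stop(sprintf("k = %d exceeds the number of points (%d)", k, P))

  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kpp_seed(points, k)
    fit <- lloyd(points, centers)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  structure(list(labels = best$labels, k = k, method = "kmeans++",
                 seed = as.integer(seed), centers = best$centers,
                 wss = best$wss),
            class = "clustering_result")
}

# squared Euclidean distances from every point to every center
sqdist_to <- function(points, centers) {
  p2 <- rowSums(points^2)
  c2 <- rowSums(centers^2)
  pmax(outer(p2, c2, "+") - 2 * points %*% t(centers), 0)
}

kpp_seed <- function(points, k) {
  P <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1, ] <- points[sample.int(P, 1L), ]
  if (k > 1L) {
    d2 <- sqdist_to(points, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      tot <- sum(d2)
      pick <- if (tot <= 0) sample.int(P, 1L)  # all mass on duplicates
              else sample.int(P, 1L, prob = d2 / tot)
      centers[j, ] <- points[pick, ]
      d2 <- pmin(d2, sqdist_to(points, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

lloyd <- function(points, centers, tol = 1e-6, max_iter = 300L) {
  k <- nrow(centers)
  labels <- integer(nrow(points))
  for (it in seq_len(max_iter)) {
    d2 <- sqdist_to(points, centers)
    labels <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      in_j <- labels == j
      if (any(in_j)) {
        new_centers[j, ] <- colMeans(points[in_j, , drop = FALSE])
      } else {
        # empty cluster: re-seed at the point farthest from its center
        far <- which.max(d2[cbind(seq_len(nrow(points)), labels)])
        new_centers[j, ] <- points[far, ]
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- sqdist_to(points, centers)
  labels <- max.col(-d2, ties.method = "first")
  wss <- sum(d2[cbind(seq_len(nrow(points)), labels)])
  list(labels = labels, centers = centers, wss = wss)
}

#' Agglomerative clustering, single linkage, cosine distance
#'
#' Bottom-up merging under single linkage with distance
#' `1 - (u . v) / (|u| |v|)` until k clusters remain, computed as a
#' minimum-spanning-tree cut (identical partition, O(P) memory). Rows with
#' zero norm are rejected (cosine undefined).
#'
#' @param points numeric matrix P x n with no all-zero rows.
#' @param k number of clusters, 1 <= k <= P.
#' @return A `clustering_result` with 1-based labels numbered by first
#'   occurrence.
#' @export
agglomerative_cosine_single <- function(points, k) {
  stopifnot(is.matrix(points))
  P <- nrow(points); k <- as.integer(k)
  if (k < 1L || k > P)
    stop(sprintf("k = %d out of range for %d points", k, P))
  nrm <- sqrt(rowSums(points^2))
  bad <- which(nrm == 0)
  if (length(bad) > 0)
    stop(sprintf("cosine distance undefined for zero-norm row(s): %s",
                 paste(head(bad, 5), collapse = ", ")))
  labels <- cpp_single_linkage_cosine(points, k) + 1L
  structure(list(labels = labels, k = k, method = "agglomerative/cosine/single",
                 seed = NA_integer_),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s, k = %d, %d points\n",
              x$method, x$k, length(x$labels)))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table:
#' `(sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`. Invariant to label
#' renaming; 1 iff the partitions are identical; 0 in expectation for
#' random labelings. Returns 1 for the degenerate case where both
#' expected and maximum index coincide (e.g., both partitions all-
#' singletons or all-one-cluster).
#'
#' @param labels_a,labels_b vectors of equal length >= 2.
#' @return A scalar <= 1.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("length mismatch between the two labelings")
  if (length(labels_a) < 2L) stop("need at least 2 items")
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Best-matching accuracy between predicted clusters and reference classes
#'
#' Cluster ids are arbitrary, so accuracy is taken as the maximum over
#' one-to-one assignments of clusters to classes of the fraction of
#' agreeing positions; the optimum is found exactly with a Hungarian
#' (augmenting-path) solver on the confusion matrix.
#'
#' @param pred_labels,true_labels vectors of equal length.
#' @return Fraction in \[0, 1\].
#' @export
matched_accuracy <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels))
    stop("length mismatch between predicted and reference labels")
  tab <- table(pred_labels, true_labels)
  # pad to square; assignment maximizes total matched count
  d <- max(dim(tab))
  cost <- matrix(0, d, d)
  cost[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  sum_matched <- hungarian_max(cost)
  sum_matched / length(pred_labels)
}

# Exact maximum-weight perfect matching on a square matrix via the
# Jonker-Volgenant style shortest augmenting path algorithm (on negated
# weights). O(d^3); d here is the number of clusters, always small.
hungarian_max <- function(w) {
  d <- nrow(w)
  cost <- max(w) - w  # minimize
  u <- numeric(d + 1); v <- numeric(d + 1)
  p <- integer(d + 1)  # p[j]: row assigned to column j (0 = none)
  for (i in seq_len(d)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, d + 1)
    used <- rep(FALSE, d + 1)
    way <- integer(d + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(d + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(d + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assigned <- integer(d)  # assigned[row] = column
  for (j in 2:(d + 1)) if (p[j] > 0L) assigned[p[j]] <- j - 1L
  sum(w[cbind(seq_len(d), assigned)])
}

#' Majority label per group
#'
#' Utility for turning per-row cluster labels into one label per sequence
#' or per frame: the most frequent label wins, ties broken toward the
#' smallest label id (deterministic).
#'
#' @param labels vector of labels.
#' @param groups parallel vector of group ids.
#' @return Named vector, one label per distinct group (in first-occurrence
#'   order).
#' @export
majority_vote <- function(labels, groups) {
  stopifnot(length(labels) == length(groups))
  gs <- unique(groups)
  out <- vapply(gs, function(g) {
    tab <- table(labels[groups == g])
    cand <- names(tab)[tab == max(tab)]
    # numeric-aware tie-break toward the smallest id
    suppressWarnings(num <- as.numeric(cand))
    if (!any(is.na(num))) cand[which.min(num)] else sort(cand)[1]
  }, character(1))
  names(out) <- as.character(gs)
  out
}
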