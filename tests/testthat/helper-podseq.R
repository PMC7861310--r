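# Shared fixtures and independent oracles. Everything is generated in code;
# oracle implementations deliberately use different algorithms from the
# package paths they check.

circle_pair <- function(Te = 50L, type_id = 0L, phase = 0) {
  sp <- trajectory_spec("circle", period_steps = Te, phase_offset = phase,
                        type_id = type_id)
  make_prediction_pair(make_circle(sp), type_id = type_id)
}

ellipse_pair <- function(Te = 50L, type_id = 1L, phase = 0) {
  sp <- trajectory_spec("ellipse", period_steps = Te, phase_offset = phase,
                        type_id = type_id)
  make_prediction_pair(make_ellipse(sp), type_id = type_id)
}

# tiny model + data so a full train/snapshot cycle runs in well under a second
tiny_pairs <- function() list(circle_pair(8L, 0L), ellipse_pair(8L, 1L))

tiny_model <- function(seed = 1L, M = 2L, share = FALSE)
  init_model(model_config(4L, M, share_weights = share, seed = seed))

# reference GRU Seq2Seq forward written independently in plain R,
# mirroring the documented gate equations
r_gru_forward <- function(model, X, Td) {
  cfg <- model$config
  N <- cfg$n_units; M <- cfg$n_features
  cell_len <- 3 * N * M + 3 * N * N + 6 * N
  unpack <- function(off) {
    W <- matrix(model$theta[off + seq_len(3 * N * M)], 3 * N, M)
    off <- off + 3 * N * M
    U <- matrix(model$theta[off + seq_len(3 * N * N)], 3 * N, N)
    off <- off + 3 * N * N
    bx <- model$theta[off + seq_len(3 * N)]
    bh <- model$theta[off + 3 * N + seq_len(3 * N)]
    list(W = W, U = U, bx = bx, bh = bh)
  }
  enc <- unpack(0)
  dec <- if (cfg$share_weights) enc else unpack(cell_len)
  off_out <- cell_len * (if (cfg$share_weights) 1 else 2)
  Wy <- matrix(model$theta[off_out + seq_len(M * N)], M, N)
  by <- model$theta[off_out + M * N + seq_len(M)]
  sig <- function(x) 1 / (1 + exp(-x))
  step <- function(cl, x, h) {
    ax <- cl$W %*% x + cl$bx
    ah <- cl$U %*% h + cl$bh
    r <- sig(ax[1:N] + ah[1:N])
    z <- sig(ax[N + 1:N] + ah[N + 1:N])
    n <- tanh(ax[2 * N + 1:N] + r * ah[2 * N + 1:N])
    (1 - z) * n + z * h
  }
  h <- numeric(N)
  E <- matrix(0, nrow(X), N)
  for (t in seq_len(nrow(X))) {
    h <- step(enc, X[t, ], h)
    E[t, ] <- h
  }
  D <- matrix(0, Td, N)
  Yhat <- matrix(0, Td, M)
  x <- X[nrow(X), ]
  for (t in seq_len(Td)) {
    h <- step(dec, x, h)
    D[t, ] <- h
    y <- as.numeric(Wy %*% h + by)
    Yhat[t, ] <- y
    x <- y
  }
  list(E = E, D = D, Yhat = Yhat)
}

# ARI oracle by direct pair counting over all item pairs (O(n^2)),
# independent of the contingency-table route
ari_pairs_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# all partitions of n items as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_id) {
    k <- length(labels)
    if (k == n) { out[[length(out) + 1]] <<- labels; return(invisible()) }
    for (id in 0:next_id) rec(c(labels, id), max(next_id, id + 1))
  }
  rec(integer(0), 0)
  out
}

# matched accuracy oracle: exhaustive search over assignments
matched_accuracy_oracle <- function(pred, truth) {
  pu <- unique(pred); tu <- unique(truth)
  if (length(pu) > length(tu)) { tmp <- pred; pred <- truth; truth <- tmp
                                 tmp <- pu; pu <- tu; tu <- tmp }
  best <- 0
  for (perm in asplit(perms_of(tu, length(pu)), 1)) {
    mapped <- perm[match(pred, pu)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

# all ordered selections of k elements from v
perms_of <- function(v, k) {
  if (k == 0) return(matrix(nrow = 1, ncol = 0))
  sub <- function(rem, acc) {
    if (length(acc) == k) return(matrix(acc, nrow = 1))
    do.call(rbind, lapply(seq_along(rem), function(i)
      sub(rem[-i], c(acc, rem[i]))))
  }
  sub(v, v[0])
}

# single-linkage/cosine oracle through stats::hclust on a dense dist
hclust_cosine_single_oracle <- function(P, k) {
  nrm <- sqrt(rowSums(P^2))
  d <- stats::as.dist(1 - tcrossprod(P / nrm))
  stats::cutree(stats::hclust(d, method = "single"), k)
}
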