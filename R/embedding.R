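#' Center the columns of a state matrix
#'
#' Subtracts each column's mean so every column of the result has mean
#' exactly zero (to machine precision); the removed means are returned and
#' later reused so that new matrices are projected into the same frame.
#'
#' @param A numeric matrix T x N with T >= 1.
#' @return list(Ac = centered matrix, mu = 1 x N row vector of means).
#' @export
center_columns <- function(A) {
  if (!is.matrix(A) || nrow(A) < 1L || ncol(A) < 1L)
    stop("A must be a non-empty numeric matrix")
  mu <- colMeans(A)
  list(Ac = sweep(A, 2L, mu, "-"), mu = matrix(mu, nrow = 1))
}

#' Proper orthogonal decomposition of a centered matrix
#'
#' Thin SVD `Ac = U diag(sigma) V'` with singular values in non-increasing
#' order and a deterministic sign convention: each right-singular column's
#' largest-magnitude entry is made positive (ties broken by the first such
#' entry). The columns of V are the PC modes of the embedding space.
#'
#' @param Ac centered matrix T x N (see [center_columns()]).
#' @param mu optional 1 x N means to carry along (stored in the basis so
#'   projections of new matrices share the same frame); defaults to zeros.
#' @return A `pod_basis`: mu, V, sigma, U, sve_total.
#' @export
pod <- function(Ac, mu = NULL) {
  if (!is.matrix(Ac)) stop("Ac must be a matrix")
  if (any(!is.finite(Ac))) stop("Ac contains non-finite entries")
  s <- svd(Ac)
  # sign convention: dominant entry of each V column positive
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$v[, j]))
    if (s$v[i, j] < 0) {
      s$v[, j] <- -s$v[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  if (is.null(mu)) mu <- matrix(0, nrow = 1, ncol = ncol(Ac))
  structure(list(mu = mu, V = s$v, sigma = s$d, U = s$u,
                 sve_total = sum(s$d^2)),
            class = "pod_basis")
}

#' Center and decompose in one call
#'
#' Convenience wrapper: [center_columns()] then [pod()], storing the means
#' in the returned basis.
#'
#' @param A raw (uncentered) matrix T x N.
#' @return A `pod_basis`.
#' @export
pod_basis <- function(A) {
  cc <- center_columns(A)
  pod(cc$Ac, mu = cc$mu)
}

#' @export
print.pod_basis <- function(x, ...) {
  cat(sprintf("<pod_basis> %d modes, SVE = %.4g; modes for 90%%/99%% energy: %d/%d\n",
              length(x$sigma), x$sve_total,
              sve_mode_count(x$sigma, 0.90), sve_mode_count(x$sigma, 0.99)))
  invisible(x)
}

#' Number of modes retaining a fraction of singular-value energy
#'
#' The singular-value energy is `SVE = sum(sigma^2)`; the mode count at
#' level p is the smallest k whose leading partial sum retains at least a
#' fraction p of it. Non-decreasing in p, so the count at 99% is never
#' below the count at 90%.
#'
#' @param sigma singular values, non-increasing, not all zero.
#' @param p energy fraction, 0 < p <= 1.
#' @return Integer k with 1 <= k <= length(sigma).
#' @export
sve_mode_count <- function(sigma, p) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    stop("p must be a single value in (0, 1]")
  e <- sigma^2
  tot <- sum(e)
  if (tot == 0) stop("all singular values are zero: mode count undefined")
  frac <- cumsum(e) / tot
  if (p == 1) return(max(which(e > 0)))
  as.integer(which(frac >= p)[1])
}

#' Stack state traces into the global states matrix
#'
#' Vertically stacks each trace's states matrix S = [E; D] in sequence
#' order, producing the global matrix whose POD defines the shared
#' embedding space, together with per-row bookkeeping (sequence id, phase,
#' time step, type id).
#'
#' @param traces list of `state_trace`s sharing the same N.
#' @param type_ids integer vector, one per trace.
#' @return A `global_states`: S (sum(Te+Td) x N) and row_index data frame
#'   with columns seq, phase ("encoder"/"decoder"), t (1-based within
#'   phase), type_id.
#' @export
stack_states <- function(traces, type_ids) {
  stopifnot(length(traces) >= 1, length(type_ids) == length(traces))
  ns <- vapply(traces, function(tr) ncol(tr$S), integer(1))
  if (length(unique(ns)) != 1L)
    stop("mismatched N across traces")
  blocks <- lapply(traces, function(tr) tr$S)
  idx <- do.call(rbind, lapply(seq_along(traces), function(k) {
    tr <- traces[[k]]
    data.frame(
      seq = k,
      phase = rep(c("encoder", "decoder"), c(nrow(tr$E), nrow(tr$D))),
      t = c(seq_len(nrow(tr$E)), seq_len(nrow(tr$D))),
      type_id = unname(type_ids[k]))
  }))
  structure(list(S = do.call(rbind, blocks), row_index = idx),
            class = "global_states")
}

#' @export
print.global_states <- function(x, ...) {
  cat(sprintf("<global_states> %d x %d (%d sequences, %d types)\n",
              nrow(x$S), ncol(x$S), max(x$row_index$seq),
              length(unique(x$row_index$type_id))))
  invisible(x)
}

#' Project a state matrix onto the leading PC modes
#'
#' Computes `(A - mu) V[, 1:n]` using the basis's own column means, so any
#' matrix (a single encoder trace, decoder rows from a scan, the global
#' matrix itself) lands in the one shared coordinate frame. At n = N the
#' projection is an isometry of the centered data.
#'
#' @param A matrix T x N in the basis's original coordinates.
#' @param basis a `pod_basis`.
#' @param n number of leading modes, 1 <= n <= ncol(basis$V).
#' @return Matrix T x n of embedding coordinates.
#' @export
project_states <- function(A, basis, n) {
  stopifnot(inherits(basis, "pod_basis"), is.matrix(A))
  n <- as.integer(n)
  if (n < 1L || n > ncol(basis$V))
    stop(sprintf("n out of range: need 1 <= n <= %d", ncol(basis$V)))
  if (ncol(A) != nrow(basis$V))
    stop("A's column count does not match the basis dimension")
  sweep(A, 2L, as.numeric(basis$mu), "-") %*% basis$V[, seq_len(n), drop = FALSE]
}

#' Write a POD basis to a JSON archive
#'
#' Stores mu, V, sigma and optional provenance (iteration, data hash) in a
#' single plain-text file; U is not archived (it is data-specific).
#'
#' @param basis a `pod_basis`.
#' @param path output file.
#' @param provenance optional named list carried through verbatim.
#' @export
save_basis <- function(basis, path, provenance = NULL) {
  jsonlite::write_json(
    list(mu = as.numeric(basis$mu), V = basis$V, sigma = basis$sigma,
         provenance = provenance),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a POD basis archived by [save_basis()]
#' @param path archive file.
#' @return A `pod_basis` (without U).
#' @export
load_basis <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mu = matrix(b$mu, nrow = 1), V = b$V, sigma = b$sigma,
                 U = NULL, sve_total = sum(b$sigma^2)),
            class = "pod_basis")
}
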