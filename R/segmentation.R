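#' Enumerate sliding windows over a long sequence
#'
#' Window starts are 0-based frame offsets 0, stride, 2*stride, ... while
#' the full encoder+decoder span fits (`start + Te + Td <= T`). Decoder
#' step t (0-based) of the window starting at s covers frame `s + Te + t`
#' (0-based), i.e. the frame the decoder is predicting.
#'
#' @param sequence numeric matrix T x M, or its row count.
#' @param Te encoder steps per window.
#' @param Td decoder steps per window.
#' @param stride hop between window starts, >= 1.
#' @return A `window_scan`: starts (0-based), Te, Td, stride, n_frames.
#' @export
sliding_windows <- function(sequence, Te, Td, stride = 1L) {
  n <- if (is.matrix(sequence)) nrow(sequence) else as.integer(sequence)
  Te <- as.integer(Te); Td <- as.integer(Td); stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (n < Te + Td)
    stop(sprintf("sequence too short: %d frames < Te + Td = %d", n, Te + Td))
  starts <- seq.int(0L, n - Te - Td, by = stride)
  structure(list(starts = starts, Te = Te, Td = Td, stride = stride,
                 n_frames = n),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("<window_scan> %d windows (Te = %d, Td = %d, stride = %d) over %d frames\n",
              length(x$starts), x$Te, x$Td, x$stride, x$n_frames))
  invisible(x)
}

#' Frames covered by the decoder rows of a scan
#'
#' @param scan a `window_scan`.
#' @return Integer vector of 0-based frame indices, window-major then
#'   decoder-step order — aligned with the rows of
#'   [collect_window_states()].
#' @export
covered_frames <- function(scan) {
  stopifnot(inherits(scan, "window_scan"))
  as.integer(outer(seq_len(scan$Td) - 1L, scan$starts + scan$Te, "+"))
}

#' Collect decoder states across all windows of a scan
#'
#' Forward-propagates every window (encoder over its Te frames, decoder
#' free-running for Td steps) and stacks the decoder state rows
#' window-major, with the 0-based covered frame of each row.
#'
#' @param model a `seq2seq_model`.
#' @param scan a `window_scan`.
#' @param sequence the matrix the scan was built over.
#' @return list(D = (n_windows*Td) x N matrix, frame_map = 0-based frames,
#'   window = window id per row).
#' @export
collect_window_states <- function(model, scan, sequence) {
  stopifnot(inherits(scan, "window_scan"), is.matrix(sequence))
  if (ncol(sequence) != model$config$n_features)
    stop("sequence feature width does not match the model")
  blocks <- lapply(scan$starts, function(s) {
    X <- sequence[(s + 1):(s + scan$Te), , drop = FALSE]
    forward_collect(model, X, scan$Td)$D
  })
  list(D = do.call(rbind, blocks),
       frame_map = covered_frames(scan),
       window = rep(seq_along(scan$starts), each = scan$Td))
}

#' Unsupervised temporal segmentation of a multi-activity sequence
#'
#' Scans the sequence with sliding windows, collects the decoder states,
#' builds a POD basis from the collected states themselves (self-contained
#' inference; no training-time basis required), projects to `n_pcs` modes,
#' clusters the projected rows with single-linkage/cosine agglomerative
#' clustering into k groups, and labels each frame by majority vote over
#' all decoder rows covering it (ties toward the lower cluster id). The
#' first Te frames and any tail frames no window reaches inherit the
#' nearest covered frame's label; this policy is reported in the result.
#'
#' @param model a trained `seq2seq_model`.
#' @param sequence numeric matrix T x M.
#' @param k number of activities (the only supervision-like input).
#' @param Te,Td window lengths; default to the training lengths used for
#'   the synthetic tasks (50/50).
#' @param stride window hop (default 1).
#' @param n_pcs embedding dimension for clustering (default 3).
#' @param reference_labels optional per-frame type ids (length T); when
#'   given, frame-level matched accuracy is computed.
#' @return A `segmentation_result`: frame_labels (length T, 1-based cluster
#'   ids), k, accuracy (or NA), uncovered_policy, segments table.
#' @export
segment_sequence <- function(model, sequence, k, Te = 50L, Td = 50L,
                             stride = 1L, n_pcs = 3L,
                             reference_labels = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  scan <- sliding_windows(sequence, Te, Td, stride)
  cw <- collect_window_states(model, scan, sequence)
  if (k > nrow(cw$D))
    stop("k exceeds the number of collected decoder state rows")

  basis <- pod_basis(cw$D)
  n_pcs <- min(as.integer(n_pcs), ncol(basis$V))
  Z <- project_states(cw$D, basis, n_pcs)
  cl <- agglomerative_cosine_single(Z, k)

  n <- nrow(sequence)
  frame_labels <- rep(NA_integer_, n)
  votes <- majority_vote(cl$labels, cw$frame_map)
  frame_labels[as.integer(names(votes)) + 1L] <- as.integer(votes)

  # uncovered frames inherit the nearest covered frame's label
  if (anyNA(frame_labels)) {
    cov_idx <- which(!is.na(frame_labels))
    for (i in which(is.na(frame_labels))) {
      nearest <- cov_idx[which.min(abs(cov_idx - i))]
      frame_labels[i] <- frame_labels[nearest]
    }
  }

  acc <- NA_real_
  if (!is.null(reference_labels)) {
    if (length(reference_labels) != n)
      stop("reference_labels length does not match the sequence")
    acc <- matched_accuracy(frame_labels, reference_labels)
  }

  runs <- rle(frame_labels)
  ends <- cumsum(runs$lengths)
  segments <- data.frame(start = c(0L, head(ends, -1L)),  # 0-based
                         end = ends - 1L, label = runs$values)

  structure(list(frame_labels = frame_labels, k = k, accuracy = acc,
                 uncovered_policy = "nearest-covered-frame",
                 segments = segments, scan = scan, n_pcs = n_pcs),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d frames, k = %d, %d segments%s\n",
              length(x$frame_labels), x$k, nrow(x$segments),
              if (is.finite(x$accuracy))
                sprintf(", matched accuracy %.3f", x$accuracy) else ""))
  invisible(x)
}

#' Frame-level accuracy of a segmentation against reference labels
#'
#' Matched accuracy over frames: the maximum, over one-to-one assignments
#' of cluster ids to reference classes, of the fraction of frames that
#' agree.
#'
#' @param result a `segmentation_result`.
#' @param reference_frame_labels per-frame reference type ids.
#' @return Fraction in \[0, 1\].
#' @export
evaluate_segmentation <- function(result, reference_frame_labels) {
  stopifnot(inherits(result, "segmentation_result"))
  matched_accuracy(result$frame_labels, reference_frame_labels)
}
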