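#' Options controlling training-snapshot construction
#'
#' @param n_pcs embedding dimension used for the low-dimensional clustering
#'   view (default 3, the visualization dimension used throughout).
#' @param cluster_seed seed for the snapshot's K-means++ runs (isolated
#'   from the training RNG stream).
#' @param n_restarts K-means++ restarts per snapshot.
#' @param energy_levels SVE fractions at which mode counts are recorded.
#' @return A `snapshot_config` list.
#' @export
snapshot_config <- function(n_pcs = 3L, cluster_seed = 1L, n_restarts = 10L,
                            energy_levels = c(0.90, 0.99)) {
  structure(list(n_pcs = as.integer(n_pcs),
                 cluster_seed = as.integer(cluster_seed),
                 n_restarts = as.integer(n_restarts),
                 energy_levels = energy_levels),
            class = "snapshot_config")
}

#' Observe the embedding state of a model at one training iteration
#'
#' Runs [forward_collect()] on every probe pair, stacks the traces into the
#' global states matrix, rebuilds the POD basis from scratch (bases are
#' never reused across iterations), and records: decoder-row clustering ARI
#' against the probe type ids (K-means++ with k = number of types, both in
#' the full N-dimensional state space and projected to `n_pcs`), the mode
#' counts at each energy level for the encoder-only, decoder-only and
#' stacked matrices, and train/validation losses.
#'
#' @param model a `seq2seq_model`.
#' @param probe_pairs list of `sequence_pair`s covering >= 2 types; labels
#'   are used for evaluation only.
#' @param iteration training iteration being observed.
#' @param config a [snapshot_config()].
#' @param train_loss optional training loss to record.
#' @return A `training_snapshot`.
#' @export
take_snapshot <- function(model, probe_pairs, iteration,
                          config = snapshot_config(), train_loss = NA_real_) {
  stopifnot(length(probe_pairs) >= 1)
  type_ids <- vapply(probe_pairs, function(p) p$type_id, integer(1))
  n_types <- length(unique(type_ids))
  if (n_types < 2L)
    stop("probe set must contain at least 2 sequence types (ARI undefined)")

  traces <- lapply(probe_pairs, function(p)
    forward_collect(model, p$X, nrow(p$Y)))
  gs <- stack_states(traces, type_ids)
  basis <- pod_basis(gs$S)

  dec <- gs$row_index$phase == "decoder"
  D_rows <- gs$S[dec, , drop = FALSE]
  d_types <- gs$row_index$type_id[dec]
  n_pcs <- min(config$n_pcs, ncol(basis$V))
  D_low <- project_states(D_rows, basis, n_pcs)
  D_full <- project_states(D_rows, basis, ncol(basis$V))

  cl_low <- kmeans_pp(D_low, k = n_types, seed = config$cluster_seed,
                      n_restarts = config$n_restarts)
  cl_full <- kmeans_pp(D_full, k = n_types, seed = config$cluster_seed,
                       n_restarts = config$n_restarts)
  ari_low <- ari(cl_low$labels, d_types)
  ari_full <- ari(cl_full$labels, d_types)
  # the agglomerative/cosine view: how the synthetic attractors are
  # verified to be separable (and the method the segmentation pipeline
  # uses); recorded alongside the K-means views
  ari_agglo <- tryCatch(
    ari(agglomerative_cosine_single(D_full, n_types)$labels, d_types),
    error = function(e) NA_real_)  # zero-norm row early in training

  E_all <- do.call(rbind, lapply(traces, function(tr) tr$E))
  D_all <- do.call(rbind, lapply(traces, function(tr) tr$D))
  counts <- function(A) {
    s <- pod_basis(A)$sigma
    vapply(config$energy_levels, function(p) sve_mode_count(s, p), integer(1))
  }
  mode_counts <- rbind(encoder = counts(E_all), decoder = counts(D_all),
                       stacked = counts(gs$S))
  colnames(mode_counts) <- sprintf("p%02d", round(100 * config$energy_levels))

  val_loss <- mean(vapply(probe_pairs, function(p)
    mse_loss(p$Y, forward_collect(model, p$X, nrow(p$Y))$Yhat), numeric(1)))

  structure(list(iteration = as.integer(iteration),
                 train_loss = train_loss, val_loss = val_loss,
                 ari = ari_low, ari_full = ari_full, ari_agglo = ari_agglo,
                 n_pcs = n_pcs, k = n_types,
                 mode_counts = mode_counts, basis = basis),
            class = "training_snapshot")
}

#' @export
print.training_snapshot <- function(x, ...) {
  cat(sprintf(
    "<training_snapshot> iter %d: train %.3g, val %.3g, ARI(PC%d) %.3f, ARI(full) %.3f\n",
    x$iteration, x$train_loss, x$val_loss, x$n_pcs, x$ari, x$ari_full))
  invisible(x)
}

#' Train while monitoring the embedding
#'
#' Wraps [train_seq2seq()] with a snapshot callback so the embedding is
#' rebuilt at iterations 1, interval, 2*interval, ..., final. Snapshots
#' are pure observations: the trained parameters are bitwise identical to
#' an unmonitored run with the same seeds.
#'
#' @param model a `seq2seq_model`.
#' @param pairs training `sequence_pair`s.
#' @param iterations optimizer steps.
#' @param interval snapshot spacing, >= 1.
#' @param probe_pairs sequences observed at each snapshot (>= 2 types);
#'   defaults to the training pairs.
#' @param config a [snapshot_config()].
#' @param ... further arguments to [train_seq2seq()] (lr, batch_size, ...).
#' @return list(model, log, snapshots) with snapshots ordered by iteration.
#' @export
run_monitoring <- function(model, pairs, iterations, interval,
                           probe_pairs = pairs, config = snapshot_config(),
                           ...) {
  interval <- as.integer(interval)
  if (interval < 1L) stop("interval must be >= 1")
  snaps <- new.env(parent = emptyenv())
  snaps$list <- list()
  cb <- function(m, it, loss) {
    s <- take_snapshot(m, probe_pairs, it, config, train_loss = loss)
    s$basis <- NULL  # keep the log light; bases are recomputable
    snaps$list[[length(snaps$list) + 1L]] <- s
  }
  fit <- train_seq2seq(model, pairs, iterations,
                       snapshot_every = interval, snapshot_callback = cb, ...)
  list(model = fit$model, log = fit$log, snapshots = snaps$list)
}

#' Turn a snapshot list into a data frame
#' @param snapshots list of `training_snapshot`s.
#' @return Data frame with one row per snapshot.
#' @export
snapshot_table <- function(snapshots) {
  do.call(rbind, lapply(snapshots, function(s) {
    mc <- s$mode_counts
    out <- data.frame(iteration = s$iteration, train_loss = s$train_loss,
                      val_loss = s$val_loss, ari = s$ari,
                      ari_full = s$ari_full, ari_agglo = s$ari_agglo)
    for (rn in rownames(mc)) for (cn in colnames(mc))
      out[[paste0("modes_", rn, "_", cn)]] <- mc[rn, cn]
    out
  }))
}

#' Locate the optimal-training point and flag overfitting
#'
#' The optimal iteration by clustering is the earliest iteration attaining
#' the maximum decoder ARI; the optimal iteration by validation is that of
#' the minimum validation loss (absent when no validation loss was
#' recorded). Overfitting is flagged when the final snapshot's ARI has
#' dropped below the peak by more than `margin` while (if available) the
#' final validation loss exceeds its minimum.
#'
#' @param snapshots list of `training_snapshot`s (>= 3), ordered.
#' @param margin ARI drop treated as meaningful (default 0.05, above
#'   clustering seed noise on the synthetic tasks).
#' @return list(i_star_ari, i_star_val, overfit_flag).
#' @export
detect_optimal_iteration <- function(snapshots, margin = 0.05) {
  if (length(snapshots) < 3L) stop("need at least 3 snapshots")
  its <- vapply(snapshots, function(s) s$iteration, integer(1))
  aris <- vapply(snapshots, function(s) s$ari, numeric(1))
  vals <- vapply(snapshots, function(s)
    if (is.null(s$val_loss)) NA_real_ else s$val_loss, numeric(1))

  i_star_ari <- its[which.max(aris)]  # which.max: earliest on ties
  have_val <- any(is.finite(vals))
  i_star_val <- if (have_val) its[which.min(vals)] else NA_integer_

  ari_drop <- max(aris) - aris[length(aris)]
  val_rise <- if (have_val) vals[length(vals)] > min(vals, na.rm = TRUE) else TRUE
  list(i_star_ari = i_star_ari, i_star_val = i_star_val,
       overfit_flag = (ari_drop > margin) && val_rise)
}
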