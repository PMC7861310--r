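#' Configure a Seq2Seq encoder-decoder model
#'
#' A single-layer GRU encoder hands its final hidden state to a GRU decoder
#' that runs free (teacher-forcing-free): the decoder's first input is the
#' last encoder input row, thereafter its own previous output, in both
#' training and testing. A trailing linear map sends the N-dimensional
#' decoder state to the M-dimensional output.
#'
#' @param n_units N, hidden units per cell.
#' @param n_features M, input/output dimension.
#' @param share_weights if TRUE the encoder and decoder use one parameter
#'   set (a single stored block, so "mutating one mutates the other").
#' @param cell_kind "GRU"; "LSTM" is part of the configuration surface but
#'   not implemented (errors at [init_model()]).
#' @param n_layers 1; deeper stacks are not implemented.
#' @param seed master seed for parameter initialization and batching.
#' @return A `model_config` list.
#' @export
model_config <- function(n_units, n_features, share_weights = FALSE,
                         cell_kind = c("GRU", "LSTM"), n_layers = 1L,
                         seed = 1L) {
  cell_kind <- match.arg(cell_kind)
  n_units <- as.integer(n_units); n_features <- as.integer(n_features)
  n_layers <- as.integer(n_layers)
  if (n_units < 1L || n_features < 1L || n_layers < 1L)
    stop("n_units, n_features and n_layers must be >= 1")
  structure(list(n_units = n_units, n_features = n_features,
                 share_weights = isTRUE(share_weights),
                 cell_kind = cell_kind, n_layers = n_layers,
                 seed = as.integer(seed)),
            class = "model_config")
}

# flat parameter vector layout: [enc cell | dec cell (unless shared) | Wy, by]
# cell block = W (3N x M) | U (3N x N) | bx (3N) | bh (3N), column-major
param_length <- function(config) {
  N <- config$n_units; M <- config$n_features
  cell <- 3L * N * M + 3L * N * N + 6L * N
  n_cells <- if (config$share_weights) 1L else 2L
  n_cells * cell + M * N + M
}

#' Initialize a Seq2Seq model
#'
#' Parameters are drawn uniformly from (-1/sqrt(N), 1/sqrt(N)), seeded by
#' the config's master seed, so identical configs yield identical models.
#'
#' @param config a [model_config()].
#' @return A `seq2seq_model`: the config plus a flat parameter vector.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  if (config$cell_kind != "GRU")
    stop("unsupported cell_kind: only GRU is implemented")
  if (config$n_layers != 1L)
    stop("unsupported n_layers: only single-layer models are implemented")
  bound <- 1 / sqrt(config$n_units)
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(config$seed)
  theta <- runif(param_length(config), -bound, bound)
  structure(list(config = config, theta = theta, iterations_trained = 0L),
            class = "seq2seq_model")
}

#' @export
print.seq2seq_model <- function(x, ...) {
  cat(sprintf(
    "<seq2seq_model> %s, N = %d, M = %d, %s weights, %d parameters, %d iterations trained\n",
    x$config$cell_kind, x$config$n_units, x$config$n_features,
    if (x$config$share_weights) "shared" else "separate",
    length(x$theta), x$iterations_trained))
  invisible(x)
}

# save/restore .Random.seed so observation code never perturbs training RNG
preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Forward pass with full internal-state capture
#'
#' Runs the encoder over X from an all-zero initial state, recording the
#' hidden state at every step, then the decoder for Td steps. Capture is
#' non-invasive: the returned outputs are those of a plain forward pass.
#'
#' @param model a `seq2seq_model`.
#' @param X input matrix Te x M.
#' @param Td decoder steps.
#' @return A `state_trace`: E (Te x N), D (Td x N), Yhat (Td x M) and their
#'   vertical stack S ((Te+Td) x N).
#' @export
forward_collect <- function(model, X, Td) {
  stopifnot(inherits(model, "seq2seq_model"), is.matrix(X))
  Td <- as.integer(Td)
  if (nrow(X) < 1L || Td < 1L) stop("Te and Td must be positive")
  if (ncol(X) != model$config$n_features)
    stop(sprintf("X has %d columns but the model expects M = %d",
                 ncol(X), model$config$n_features))
  res <- cpp_seq2seq_forward(model$theta, model$config$n_units,
                             model$config$n_features,
                             model$config$share_weights, X, Td)
  structure(list(E = res$E, D = res$D, Yhat = res$Yhat,
                 S = rbind(res$E, res$D)),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("<state_trace> E %d x %d, D %d x %d, S %d x %d\n",
              nrow(x$E), ncol(x$E), nrow(x$D), ncol(x$D),
              nrow(x$S), ncol(x$S)))
  invisible(x)
}

#' Mean squared prediction error
#'
#' Per-step squared deviation averaged over the Td time steps and the M
#' features (so the value is scale-invariant to M).
#'
#' @param Y,Yhat matrices of identical shape Td x M.
#' @return A non-negative scalar.
#' @export
mse_loss <- function(Y, Yhat) {
  if (!identical(dim(Y), dim(Yhat)))
    stop("shape mismatch between Y and Yhat")
  mean((Y - Yhat)^2)
}

#' Train a Seq2Seq model with Adam
#'
#' Minimizes [mse_loss()] over the dataset by backpropagation through time,
#' including through the decoder's output-feedback path. Batches of size
#' `batch_size` are sampled without replacement each iteration (the full
#' dataset is used deterministically when `batch_size >= length(pairs)`).
#' All randomness flows from the model's master seed.
#'
#' @param model a `seq2seq_model`.
#' @param pairs non-empty list of `sequence_pair`s.
#' @param iterations optimizer steps, >= 1.
#' @param batch_size sequences per gradient estimate.
#' @param lr Adam learning rate.
#' @param clip gradient clipping threshold on the global L2 norm.
#' @param betas,eps Adam moment decay rates and stabilizer.
#' @param snapshot_every invoke `snapshot_callback` at iterations
#'   1, snapshot_every, 2*snapshot_every, ..., iterations (0 = never).
#' @param snapshot_callback function(model, iteration, train_loss) run as a
#'   pure observation; its RNG use is isolated from the training stream.
#'   Validation-style losses are computed by the snapshot itself on its
#'   probe pairs (see [take_snapshot()]).
#' @return list(model, log) where log is a `train_log` data frame with one
#'   row per iteration (iteration, loss).
#' @export
train_seq2seq <- function(model, pairs, iterations, batch_size = length(pairs),
                          lr = 1e-3, clip = 5, betas = c(0.9, 0.999),
                          eps = 1e-8, snapshot_every = 0L,
                          snapshot_callback = NULL) {
  stopifnot(inherits(model, "seq2seq_model"))
  if (length(pairs) == 0L) stop("empty dataset")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  cfg <- model$config
  for (p in pairs)
    if (ncol(p$X) != cfg$n_features)
      stop("sequence feature width does not match model n_features")

  theta <- model$theta
  m <- v <- numeric(length(theta))
  loss_hist <- numeric(iterations)
  snap_at <- if (snapshot_every > 0L)
    unique(sort(c(1L, seq(snapshot_every, iterations, by = snapshot_every),
                  iterations)))
  else integer(0)

  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(cfg$seed + 1L)  # offset: init consumed cfg$seed itself

  full_batch <- batch_size >= length(pairs)
  for (it in seq_len(iterations)) {
    idx <- if (full_batch) seq_along(pairs)
           else sample.int(length(pairs), batch_size)
    grad <- numeric(length(theta))
    loss <- 0
    for (j in idx) {
      g <- cpp_seq2seq_grad(theta, cfg$n_units, cfg$n_features,
                            cfg$share_weights, pairs[[j]]$X, pairs[[j]]$Y)
      grad <- grad + as.numeric(g$grad)
      loss <- loss + g$loss
    }
    grad <- grad / length(idx)
    loss <- loss / length(idx)
    gn <- sqrt(sum(grad^2))
    if (is.finite(clip) && gn > clip) grad <- grad * (clip / gn)
    m <- betas[1] * m + (1 - betas[1]) * grad
    v <- betas[2] * v + (1 - betas[2]) * grad^2
    mhat <- m / (1 - betas[1]^it)
    vhat <- v / (1 - betas[2]^it)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    loss_hist[it] <- loss

    if (it %in% snap_at && !is.null(snapshot_callback)) {
      cur <- structure(list(config = cfg, theta = theta,
                            iterations_trained = model$iterations_trained + it),
                       class = "seq2seq_model")
      rng_now <- preserve_rng()
      snapshot_callback(cur, it, loss)
      restore_rng(rng_now)
    }
  }

  model$theta <- theta
  model$iterations_trained <- model$iterations_trained + iterations
  log <- data.frame(iteration = seq_len(iterations), loss = loss_hist)
  class(log) <- c("train_log", class(log))
  list(model = model, log = log)
}

#' Save a model checkpoint
#'
#' Writes parameters, configuration and iteration count to a single JSON
#' archive (plain text, exactly reproducible on reload).
#'
#' @param model a `seq2seq_model`.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  jsonlite::write_json(
    list(config = unclass(model$config), theta = model$theta,
         iterations_trained = model$iterations_trained),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path checkpoint file.
#' @return A `seq2seq_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, ck$config[c("n_units", "n_features",
                                           "share_weights", "cell_kind",
                                           "n_layers", "seed")])
  structure(list(config = cfg, theta = as.numeric(ck$theta),
                 iterations_trained = as.integer(ck$iterations_trained)),
            class = "seq2seq_model")
}
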