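#' Describe a closed planar trajectory
#'
#' A trajectory spec is the deterministic recipe for one sequence type:
#' a circle or an ellipse, traversed once per `period_steps` time steps.
#' Two specs with identical fields always generate identical matrices.
#'
#' @param shape_kind "circle" or "ellipse".
#' @param period_steps steps per full revolution (Te); at least 2.
#' @param radius circle radius (ignored for ellipses).
#' @param semi_axes length-2 vector (a, b) of ellipse semi-axes.
#' @param center length-2 center of the curve.
#' @param phase_offset phase of the first point, radians; the default 0
#'   places it at (center[1] + a, center[2]).
#' @param type_id small integer tag used only for evaluation, never training.
#' @return An object of class `trajectory_spec`.
#' @examples
#' sp <- trajectory_spec("circle", period_steps = 50)
#' head(make_trajectory(sp))
#' @export
trajectory_spec <- function(shape_kind = c("circle", "ellipse"),
                            period_steps = 50L,
                            radius = 1,
                            semi_axes = c(2, 1),
                            center = c(0, 0),
                            phase_offset = 0,
                            type_id = 0L) {
  shape_kind <- match.arg(shape_kind)
  period_steps <- as.integer(period_steps)
  if (is.na(period_steps) || period_steps < 2L)
    stop("invalid spec: period_steps must be an integer >= 2")
  if (shape_kind == "circle" && (!is.finite(radius) || radius <= 0))
    stop("invalid spec: radius must be strictly positive")
  if (shape_kind == "ellipse" &&
      (length(semi_axes) != 2L || any(!is.finite(semi_axes)) ||
       any(semi_axes <= 0)))
    stop("invalid spec: semi_axes must be two strictly positive numbers")
  if (length(center) != 2L || any(!is.finite(center)))
    stop("invalid spec: center must be a finite 2-vector")
  structure(
    list(shape_kind = shape_kind, period_steps = period_steps,
         radius = radius, semi_axes = semi_axes, center = center,
         phase_offset = phase_offset, type_id = as.integer(type_id)),
    class = "trajectory_spec")
}

#' @export
print.trajectory_spec <- function(x, ...) {
  geom <- if (x$shape_kind == "circle") sprintf("r = %g", x$radius)
          else sprintf("a = %g, b = %g", x$semi_axes[1], x$semi_axes[2])
  cat(sprintf("<trajectory_spec> %s (%s), Te = %d, center (%g, %g), type %d\n",
              x$shape_kind, geom, x$period_steps,
              x$center[1], x$center[2], x$type_id))
  invisible(x)
}

curve_points <- function(spec, n_rows) {
  th <- spec$phase_offset + 2 * pi * (seq_len(n_rows) - 1) / spec$period_steps
  ab <- if (spec$shape_kind == "circle") c(spec$radius, spec$radius)
        else spec$semi_axes
  cbind(spec$center[1] + ab[1] * cos(th),
        spec$center[2] + ab[2] * sin(th))
}

#' Generate one period of a circle
#'
#' Row t (0-indexed) is `center + radius * (cos th_t, sin th_t)` with
#' `th_t = phase_offset + 2*pi*t/Te`; Te rows cover exactly one period
#' (row Te would repeat row 0).
#'
#' @param spec a [trajectory_spec()] with `shape_kind = "circle"`.
#' @return A numeric matrix Te x 2.
#' @export
make_circle <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (spec$shape_kind != "circle")
    stop("invalid spec: make_circle needs shape_kind = \"circle\"")
  curve_points(spec, spec$period_steps)
}

#' Generate one period of an ellipse
#'
#' Row t is `center + (a*cos th_t, b*sin th_t)`; with a = b this reproduces
#' [make_circle()] exactly.
#'
#' @param spec a [trajectory_spec()] with `shape_kind = "ellipse"`.
#' @return A numeric matrix Te x 2.
#' @export
make_ellipse <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (spec$shape_kind != "ellipse")
    stop("invalid spec: make_ellipse needs shape_kind = \"ellipse\"")
  curve_points(spec, spec$period_steps)
}

#' Generate a trajectory from a spec
#'
#' Dispatches on the spec's shape; `n_rows` (default one period) lets
#' composite builders continue the curve periodically past a single period.
#'
#' @param spec a [trajectory_spec()].
#' @param n_rows number of rows to generate.
#' @return A numeric matrix n_rows x 2.
#' @export
make_trajectory <- function(spec, n_rows = spec$period_steps) {
  stopifnot(inherits(spec, "trajectory_spec"), n_rows >= 1)
  curve_points(spec, n_rows)
}

#' Build an input/target pair for the periodic prediction task
#'
#' The prediction task on closed curves asks the decoder to continue the
#' input for one further full period, so the target equals the input
#' (Y == X). A shorter decoder horizon (`Td < Te`) is only permitted with
#' `allow_partial = TRUE`, in which case Y is the first Td rows of the
#' next period.
#'
#' @param traj numeric matrix Te x M, one period of the curve.
#' @param Td decoder steps; defaults to Te.
#' @param type_id evaluation-only integer tag.
#' @param allow_partial permit Td != Te.
#' @return A `sequence_pair`: list with X, Y, type_id, onehot_width.
#' @export
make_prediction_pair <- function(traj, Td = nrow(traj), type_id = 0L,
                                 allow_partial = FALSE) {
  stopifnot(is.matrix(traj), nrow(traj) >= 1)
  Te <- nrow(traj)
  Td <- as.integer(Td)
  if (Td < 1L) stop("Td must be positive")
  if (Td != Te && !allow_partial)
    stop("periodic pairs need Td == Te (set allow_partial = TRUE to override)")
  Y <- traj[((seq_len(Td) - 1L) %% Te) + 1L, , drop = FALSE]
  structure(list(X = traj, Y = Y, type_id = as.integer(type_id),
                 onehot_width = 0L),
            class = "sequence_pair")
}

#' @export
print.sequence_pair <- function(x, ...) {
  cat(sprintf("<sequence_pair> Te = %d, Td = %d, M = %d, type %d%s\n",
              nrow(x$X), nrow(x$Y), ncol(x$X), x$type_id,
              if (x$onehot_width > 0)
                sprintf(", one-hot width %d", x$onehot_width) else ""))
  invisible(x)
}

#' Append a constant one-hot type indicator to a pair
#'
#' Adds `n_types` trailing columns to both X and Y; column `M + type_id + 1`
#' is 1 in every row, the others 0. `type_id` is 0-based. Applying this to
#' a pair that already carries a one-hot block is an error (no silent
#' stacking).
#'
#' @param pair a `sequence_pair`.
#' @param type_id 0-based type index, `0 <= type_id < n_types`.
#' @param n_types number of indicator columns.
#' @return The augmented `sequence_pair` with `onehot_width = n_types`.
#' @export
attach_onehot <- function(pair, type_id, n_types) {
  stopifnot(inherits(pair, "sequence_pair"))
  type_id <- as.integer(type_id); n_types <- as.integer(n_types)
  if (pair$onehot_width > 0L)
    stop("pair already carries a one-hot block; refusing to stack another")
  if (n_types < 1L || type_id < 0L || type_id >= n_types)
    stop("type_id out of range: need 0 <= type_id < n_types")
  hot <- matrix(0, nrow = 1, ncol = n_types)
  hot[1, type_id + 1L] <- 1
  aug <- function(A) cbind(A, hot[rep(1, nrow(A)), , drop = FALSE])
  pair$X <- aug(pair$X)
  pair$Y <- aug(pair$Y)
  pair$onehot_width <- n_types
  pair
}

#' Two unit circles sampled at different rates
#'
#' Returns one pair with 50 steps/period and one with 25: identical support
#' in the x-y plane, different rotation speed. Exercises the claim that the
#' decoder states encode temporal (not just spatial) structure.
#'
#' @param Te_slow,Te_fast steps per period for the two circles.
#' @return A list of two `sequence_pair`s (`slow`, `fast`).
#' @export
make_variable_rate_pairs <- function(Te_slow = 50L, Te_fast = 25L) {
  slow <- trajectory_spec("circle", period_steps = Te_slow, type_id = 0L)
  fast <- trajectory_spec("circle", period_steps = Te_fast, type_id = 1L)
  list(slow = make_prediction_pair(make_circle(slow), type_id = 0L),
       fast = make_prediction_pair(make_circle(fast), type_id = 1L))
}

#' Concatenate trajectory segments into a long multi-activity sequence
#'
#' Each spec is extended periodically for its stated duration and the
#' segments are concatenated in order with no smoothing, so activity
#' boundaries carry a discontinuity, as manually composed sequences do.
#' Per-frame type labels are returned for evaluation only.
#'
#' @param specs list of [trajectory_spec()]s sharing the same dimension.
#' @param durations positive integer frame counts, one per spec.
#' @param seed optional; only consumed when `random_phase = TRUE`.
#' @param random_phase draw each segment's phase offset uniformly.
#' @return list(sequence = T x M matrix, frame_labels = integer vector T).
#' @export
make_composite_sequence <- function(specs, durations, seed = NULL,
                                    random_phase = FALSE) {
  stopifnot(length(specs) == length(durations), length(specs) >= 1)
  durations <- as.integer(durations)
  if (any(durations < 1L)) stop("durations must be positive")
  if (random_phase) {
    if (!is.null(seed)) set.seed(seed)
    specs <- lapply(specs, function(sp) {
      sp$phase_offset <- runif(1, 0, 2 * pi); sp
    })
  }
  segs <- mapply(function(sp, d) make_trajectory(sp, d),
                 specs, durations, SIMPLIFY = FALSE)
  dims <- vapply(segs, ncol, integer(1))
  if (length(unique(dims)) != 1L)
    stop("dimension mismatch across specs: all segments must share M")
  labels <- rep(vapply(specs, function(sp) sp$type_id, integer(1)),
                durations)
  list(sequence = do.call(rbind, segs), frame_labels = labels)
}

#' Write a set of sequence pairs as delimited text plus a JSON manifest
#'
#' Each pair becomes two headerless comma-delimited files (`<name>_X.csv`,
#' `<name>_Y.csv`, one row per time step) and one manifest entry
#' `{path, type_id, Te, Td, M}`; the manifest is written to
#' `manifest.json` in `dir`.
#'
#' @param pairs named or unnamed list of `sequence_pair`s.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_sequence_set <- function(pairs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nms <- names(pairs)
  if (is.null(nms) || any(nms == ""))
    nms <- sprintf("seq%03d", seq_along(pairs))
  manifest <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    fx <- file.path(dir, paste0(nms[i], "_X.csv"))
    fy <- file.path(dir, paste0(nms[i], "_Y.csv"))
    write.table(p$X, fx, sep = ",", row.names = FALSE, col.names = FALSE)
    write.table(p$Y, fy, sep = ",", row.names = FALSE, col.names = FALSE)
    manifest[[i]] <- list(name = nms[i], path = basename(fx),
                          path_y = basename(fy),
                          type_id = p$type_id, Te = nrow(p$X),
                          Td = nrow(p$Y), M = ncol(p$X),
                          onehot_width = p$onehot_width)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a sequence set written by [write_sequence_set()]
#'
#' @param dir directory holding `manifest.json` and the CSV files.
#' @return A named list of `sequence_pair`s.
#' @export
read_sequence_set <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  pairs <- lapply(mf, function(e) {
    X <- as.matrix(read.table(file.path(dir, e$path), sep = ","))
    Y <- as.matrix(read.table(file.path(dir, e$path_y), sep = ","))
    dimnames(X) <- dimnames(Y) <- NULL
    structure(list(X = X, Y = Y, type_id = as.integer(e$type_id),
                   onehot_width = as.integer(e$onehot_width)),
              class = "sequence_pair")
  })
  names(pairs) <- vapply(mf, function(e) e$name, character(1))
  pairs
}

#' Write per-frame integer labels, one per line
#' @param labels integer vector.
#' @param path output file.
#' @export
write_frame_labels <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
}

#' Read per-frame integer labels written by [write_frame_labels()]
#' @param path label file, one integer per line.
#' @return Integer vector.
#' @export
read_frame_labels <- function(path) {
  as.integer(readLines(path))
}
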