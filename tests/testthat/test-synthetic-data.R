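test_that("circle generation matches the parametric form", {
  sp <- trajectory_spec("circle", period_steps = 50)
  X <- make_circle(sp)
  expect_equal(dim(X), c(50L, 2L))
  expect_equal(rowSums(X^2), rep(1, 50), tolerance = 1e-12)
  expect_equal(X[1, ], c(1, 0))

  # quarter-turn symmetry at Te = 4
  q <- make_circle(trajectory_spec("circle", period_steps = 4))
  expect_equal(q, rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
               tolerance = 1e-14)

  # translation by the center
  sh <- make_circle(trajectory_spec("circle", period_steps = 4,
                                    center = c(2, 0)))
  expect_equal(sh, sweep(q, 2, c(2, 0), "+"), tolerance = 1e-14)
})

test_that("ellipse generation and degenerate cases", {
  e <- make_ellipse(trajectory_spec("ellipse", period_steps = 4,
                                    semi_axes = c(2, 1)))
  expect_equal(e, rbind(c(2, 0), c(0, 1), c(-2, 0), c(0, -1)),
               tolerance = 1e-14)
  expect_equal(dim(make_ellipse(trajectory_spec("ellipse", 50))), c(50L, 2L))

  # a = b reproduces the circle exactly
  c1 <- make_circle(trajectory_spec("circle", 13, radius = 1))
  e1 <- make_ellipse(trajectory_spec("ellipse", 13, semi_axes = c(1, 1)))
  expect_identical(c1, e1)
})

test_that("spec validation rejects degenerate parameters", {
  expect_error(trajectory_spec("circle", period_steps = 1), "period_steps")
  expect_error(trajectory_spec("circle", radius = 0), "radius")
  expect_error(trajectory_spec("ellipse", semi_axes = c(2, 0)), "semi_axes")
  expect_error(make_circle(trajectory_spec("ellipse", 10)), "shape_kind")
  expect_error(make_ellipse(trajectory_spec("circle", 10)), "shape_kind")
})

test_that("trajectories are periodic and deterministic", {
  for (sp in list(trajectory_spec("circle", 7, phase_offset = 0.3),
                  trajectory_spec("ellipse", 12, center = c(-1, 2)))) {
    two <- make_trajectory(sp, 2L * sp$period_steps)
    expect_equal(two[seq_len(sp$period_steps), ],
                 two[sp$period_steps + seq_len(sp$period_steps), ],
                 tolerance = 1e-12)
    expect_identical(make_trajectory(sp), make_trajectory(sp))
  }
})

test_that("prediction pairs implement the periodic target", {
  X <- make_circle(trajectory_spec("circle", 50))
  p <- make_prediction_pair(X)
  expect_identical(p$X, p$Y)

  expect_error(make_prediction_pair(X, Td = 25), "Td == Te")
  # index-arithmetic oracle for a partial continuation
  p25 <- make_prediction_pair(X, Td = 25, allow_partial = TRUE)
  expect_equal(p25$Y, X[1:25, ])
  p60 <- make_prediction_pair(X, Td = 60, allow_partial = TRUE)
  expect_equal(p60$Y, X[((0:59) %% 50) + 1, ])
})

test_that("one-hot augmentation is constant, exclusive, and guarded", {
  p <- attach_onehot(circle_pair(10), type_id = 0, n_types = 2)
  expect_equal(ncol(p$X), 4L)
  expect_true(all(p$X[, 3] == 1) && all(p$X[, 4] == 0))
  expect_true(all(p$Y[, 3] == 1))
  expect_equal(rowSums(p$X[, 3:4]), rep(1, 10))  # one-hot conservation
  expect_equal(p$onehot_width, 2L)

  p1 <- attach_onehot(circle_pair(5), 0, 1)
  expect_true(all(p1$X[, 3] == 1))

  expect_error(attach_onehot(p, 0, 2), "refusing to stack")
  expect_error(attach_onehot(circle_pair(5), 2, 2), "out of range")
  expect_error(attach_onehot(circle_pair(5), -1, 2), "out of range")
})

test_that("variable-rate pairs share support but differ in rate", {
  vr <- make_variable_rate_pairs()
  expect_equal(nrow(vr$slow$X), 50L)
  expect_equal(nrow(vr$fast$X), 25L)
  # angle-arithmetic oracle: fast row t (0-based) equals slow row 2t
  for (t in 0:24)
    expect_equal(vr$fast$X[t + 1, ], vr$slow$X[2 * t + 1, ],
                 tolerance = 1e-12)
  expect_equal(rowSums(vr$fast$X^2), rep(1, 25), tolerance = 1e-12)
})

test_that("composite sequences concatenate segments with exact labels", {
  specs <- list(trajectory_spec("circle", 10, type_id = 0L),
                trajectory_spec("ellipse", 10, type_id = 1L),
                trajectory_spec("circle", 10, center = c(2, 0),
                                type_id = 2L))
  cs <- make_composite_sequence(specs, c(120, 80, 150))
  expect_equal(nrow(cs$sequence), 350L)
  expect_equal(as.integer(table(cs$frame_labels)), c(120L, 80L, 150L))
  expect_equal(cs$frame_labels[1:120], rep(0L, 120))

  one <- make_composite_sequence(specs[1], 30)
  expect_equal(one$frame_labels, rep(0L, 30))
  # segments continue the curve periodically
  expect_equal(one$sequence[1:10, ], one$sequence[11:20, ], tolerance = 1e-12)

  expect_error(make_composite_sequence(specs, c(10, -5, 10)), "positive")
})

test_that("sequence sets round-trip through delimited text + manifest", {
  dir <- withr::local_tempdir()
  pairs <- list(circle = circle_pair(12, 0L),
                ellipse = attach_onehot(ellipse_pair(12, 1L), 1, 2))
  mf <- write_sequence_set(pairs, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_sequence_set(dir)
  expect_equal(back$circle$X, pairs$circle$X, tolerance = 1e-12)
  expect_equal(back$ellipse$Y, pairs$ellipse$Y, tolerance = 1e-12)
  expect_identical(back$ellipse$type_id, 1L)
  expect_identical(back$ellipse$onehot_width, 2L)

  lab_file <- file.path(dir, "labels.txt")
  write_frame_labels(c(0L, 0L, 2L, 1L), lab_file)
  expect_identical(read_frame_labels(lab_file), c(0L, 0L, 2L, 1L))
})
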