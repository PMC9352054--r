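test_that("neck detection finds the sharpest width decrease", {
  ## plateau, linear drop over four points, then flat (0-based 12..15)
  w <- c(rep(10, 12), 8.25, 6.5, 4.75, rep(3, 34))
  found <- detect_neck(w)
  expect_true((found - 1) %in% c(12, 13))   # 0-based neck at 12-13
  ## independent oracle: argmin of first differences of the smoothed profile
  sm <- vapply(1:49, function(i) mean(w[max(1, i - 2):min(49, i + 2)]),
               numeric(1))
  oracle <- which.min(diff(sm)[5:23]) + 4L
  expect_equal(found, oracle)

  expect_error(detect_neck(seq(1, 10, length.out = 49)), "no width decrease")
  expect_error(detect_neck(rep(5, 49)), "degenerate")
})

test_that("planted width constrictions are localized within one point", {
  for (nk in c(8, 10, 13, 17, 21)) {
    expect_lte(abs(detect_neck(width_template(nk)) - nk), 1)
  }
})

test_that("segment partition covers the skeleton disjointly with documented conventions", {
  ## 0-based neck 12 = 1-based 13: head 0..10, neck 11..13, five 7-point blocks
  p <- partition_segments(13)
  expect_equal(range(p$ranges$Head), c(1, 11))
  expect_equal(p$ranges$Neck, 12:14)
  expect_equal(unname(vapply(p$ranges[3:7], length, integer(1))), rep(7L, 5))
  ## boundary: smallest admissible neck leaves a 3-point head
  expect_equal(partition_segments(5)$ranges$Head, 1:3)
  ## posterior-heavy remainder and lower-middle midpoints
  p2 <- partition_segments(15)  # tail 17..49 = 33 points: 6,6,7,7,7
  sizes <- unname(vapply(p2$ranges[3:7], length, integer(1)))
  expect_equal(sizes, c(6L, 6L, 7L, 7L, 7L))
  expect_equal(unname(p2$midpoints[["TailBase"]]), 17L + 2L)  # lower-middle of 6
  for (nk in 5:23) {
    pp <- partition_segments(nk)
    all_ix <- sort(unname(unlist(pp$ranges)))
    expect_identical(all_ix, 1:49)
    expect_equal(anyDuplicated(unlist(pp$ranges)), 0L)
  }
  expect_error(partition_segments(3), "neck_index")
})

test_that("curvature matches analytic values and is rigid-motion invariant", {
  ## straight line
  expect_lt(max(abs(skeleton_curvature(straight_frame(0.3)))), 1e-10)
  ## 49 points on a 90-degree arc of a radius-100 circle
  theta <- seq(0, pi / 2, length.out = 49)
  circ <- cbind(100 * cos(theta), 100 * sin(theta))
  k <- skeleton_curvature(circ)
  expect_true(all(abs(abs(k[10:40]) - 0.01) / 0.01 < 0.05))
  ## rigid motions leave curvature unchanged
  set.seed(1)
  sim <- simulate_recording(swim_sim_config(duration_s = 1, seed = 3))
  fr <- cbind(sim$recording$x[10, ], sim$recording$y[10, ])
  k1 <- skeleton_curvature(fr)
  k2 <- skeleton_curvature(rigid_transform(fr, runif(1, 0, 2 * pi),
                                           runif(2, -50, 50)))
  expect_lt(max(abs(k1 - k2)), 1e-8)
})

test_that("relative tangent angles are zero when straight and follow geometry", {
  part <- partition_segments(13)
  expect_true(all(abs(relative_tangent_angles(straight_frame(1.1), part)) < 1e-12))
  ## L-shape: head chord along x, tail chord perpendicular
  xy <- straight_frame(0, spacing = 2)
  xy[31:49, 1] <- xy[30, 1]
  xy[31:49, 2] <- xy[30, 2] + (1:19) * 2
  rta <- relative_tangent_angles(xy, part)
  expect_equal(abs(unname(rta["rtaTT"])), pi / 2, tolerance = 1e-9)
  ## rotation invariance
  set.seed(2)
  sim <- simulate_recording(swim_sim_config(duration_s = 1, seed = 8))
  fr <- cbind(sim$recording$x[5, ], sim$recording$y[5, ])
  r1 <- relative_tangent_angles(fr, part)
  r2 <- relative_tangent_angles(rigid_transform(fr, 2.2, c(10, -3)), part)
  expect_lt(max(abs(r1 - r2)), 1e-8)
  bad <- straight_frame(0); bad[3, ] <- bad[1, ]
  expect_error(relative_tangent_angles(bad, partition_segments(5)), "coincident")
})

test_that("quirkiness spans its defining extremes", {
  expect_equal(quirkiness(straight_frame(0.7)), 1)
  ## equal principal extents: points on the corners of a square
  sq <- straight_frame(0)
  sq[, 1] <- rep(c(0, 10), length.out = 49)
  sq[, 2] <- rep(c(0, 0, 10, 10), length.out = 49)
  expect_lt(quirkiness(sq), 0.15)
  ## semicircle of radius r: extents 2r x r
  th <- seq(0, pi, length.out = 49)
  semi <- cbind(50 * cos(th), 50 * sin(th))
  expect_equal(quirkiness(semi), sqrt(3) / 2, tolerance = 0.02)
  expect_error(quirkiness(matrix(1, 49, 2)), "coincide")
})

test_that("segment speeds measure arena displacement per frame", {
  sim <- simulate_recording(swim_sim_config(duration_s = 1, seed = 4))
  rec <- sim$recording
  ## stationary: repeat one frame
  Tn <- 10
  still <- track_recording(matrix(rec$x[1, ], Tn, 49, byrow = TRUE),
                           matrix(rec$y[1, ], Tn, 49, byrow = TRUE),
                           matrix(rec$widths[1, ], Tn, 49, byrow = TRUE))
  sp <- segment_speeds(still)
  expect_true(all(sp[-1, ] == 0))
  expect_true(all(is.na(sp[1, ])))
  ## rigid translation by (3, 4) px/frame -> speed 5 everywhere
  x <- outer(0:9 * 3, rec$x[1, ], `+`)
  y <- outer(0:9 * 4, rec$y[1, ], `+`)
  mover <- track_recording(x, y, matrix(rec$widths[1, ], 10, 49, byrow = TRUE))
  expect_equal(unname(segment_speeds(mover)[-1, ]),
               matrix(5, 9, 6), tolerance = 1e-12)
  ## frames adjacent to dropouts are masked
  mover$valid[5] <- FALSE
  spm <- segment_speeds(mover)
  expect_true(all(is.na(spm[5:6, ])))
})

test_that("head rigidity diagnostic separates rigid head from undulating tail", {
  sim <- simulate_recording(swim_sim_config(duration_s = 20, seed = 6))
  hr <- head_rigidity_profile(sim$recording)
  expect_lt(median(hr$head, na.rm = TRUE), median(hr$tail, na.rm = TRUE))
  ## deviations invariant under rotation
  rec <- sim$recording
  ang <- 1.2
  for (t in seq_len(n_frames(rec))) {
    xy <- rigid_transform(cbind(rec$x[t, ], rec$y[t, ]), ang, c(5, 5))
    rec$x[t, ] <- xy[, 1]; rec$y[t, ] <- xy[, 2]
  }
  hr2 <- head_rigidity_profile(rec)
  expect_lt(max(abs(hr$head - hr2$head), na.rm = TRUE), 1e-8)
})

test_that("the feature panel has the 25 documented columns with values on valid frames", {
  sim <- simulate_recording(swim_sim_config(duration_s = 10, seed = 12,
                                            dropout_rate = 0.05))
  curv <- skeleton_curvature(sim$recording)
  basis <- eigencionas(curv, k = 6)
  panel <- feature_panel(sim$recording, basis = basis, curv = curv)
  expect_identical(setdiff(names(panel), c("frame_index", "valid")),
                   panel_feature_names())
  expect_equal(length(panel_feature_names()), 25L)
  ## no undefined values outside masked frames (speed needs the previous
  ## frame valid too)
  interior <- panel$valid & c(FALSE, panel$valid[-nrow(panel)])
  expect_false(anyNA(panel[interior, setdiff(names(panel), "valid")]))
  expect_true(all(is.na(panel[!panel$valid, "quirkiness"])))
})
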