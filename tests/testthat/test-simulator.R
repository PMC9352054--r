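test_that("a fixed seed reproduces recordings bit for bit", {
  cfg <- swim_sim_config(duration_s = 5, seed = 60, dropout_rate = 0.05)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$x, b$recording$x)
  expect_identical(a$truth$regime, b$truth$regime)
  c <- simulate_recording(swim_sim_config(duration_s = 5, seed = 61))
  expect_false(identical(a$recording$x, c$recording$x))
})

test_that("dwell-only larvae are straight and motionless", {
  trans <- diag(6); trans[1, 1] <- 1
  cfg <- swim_sim_config(duration_s = 5, seed = 62, transition = trans)
  sim <- simulate_recording(cfg)
  panel <- feature_panel(sim$recording)
  expect_true(all(sim$truth$regime == "dwell"))
  expect_true(all(panel$quirkiness > 0.999, na.rm = TRUE))
  expect_lt(max(as.matrix(panel[-1, paste0("s", c("N", "TB", "TT"))])), 1e-6)
})

test_that("beat-regime eigencoefficients oscillate at the configured frequency", {
  trans <- matrix(0, 6, 6); trans[, 2] <- 1   # locked in beat
  cfg <- swim_sim_config(duration_s = 30, seed = 63, transition = trans)
  sim <- simulate_recording(cfg)
  curv <- skeleton_curvature(sim$recording)
  ec <- project_curvature(curv, eigencionas(curv, k = 6))
  spec <- spec.pgram(ec[, 1], plot = FALSE, taper = 0, detrend = TRUE)
  dominant_hz <- spec$freq[which.max(spec$spec)] * 30
  expect_equal(dominant_hz, 5, tolerance = 0.3)
})

test_that("skeleton arc spacing is constant across frames and points", {
  sim <- simulate_recording(swim_sim_config(duration_s = 10, seed = 64))
  rec <- sim$recording
  seg <- sqrt(diff(t(rec$x))^2 + diff(t(rec$y))^2)
  expected <- 115.10 / 48
  expect_lt(max(abs(seg - expected)) / expected, 0.01)
})

test_that("planted neck constrictions are detected from simulated recordings", {
  for (nk in c(8, 13, 20)) {
    sim <- simulate_recording(swim_sim_config(duration_s = 3, seed = 65,
                                              neck_index = nk))
    found <- recording_partition(sim$recording)$neck_index
    expect_lte(abs(found - nk), 1)
  }
})

test_that("regime ground truth aligns with kinematics", {
  sim <- simulate_recording(swim_sim_config(duration_s = 60, seed = 66))
  truth <- sim$truth
  panel <- feature_panel(sim$recording)
  sp <- panel$sN
  beat_frames <- which(truth$regime == "beat")[-1]
  ## frames at least 30 frames into a dwell bout are slow
  bout <- cumsum(c(TRUE, truth$regime[-1] != truth$regime[-nrow(truth)]))
  in_bout_pos <- sequence(rle(bout)$lengths)
  late_dwell <- which(truth$regime == "dwell" & in_bout_pos > 30)
  if (length(beat_frames) > 5 && length(late_dwell) > 5) {
    ## late-dwell frames still jitter from observation noise, so the
    ## contrast is large but not unbounded
    expect_gt(median(sp[beat_frames], na.rm = TRUE),
              4 * median(sp[late_dwell], na.rm = TRUE))
  }
  ## turning regimes bend asymmetrically: opposite mean neck-side curvature
  cw <- which(truth$regime == "turn_cw")
  ccw <- which(truth$regime == "turn_ccw")
  if (length(cw) > 30 && length(ccw) > 30) {
    curv <- skeleton_curvature(sim$recording)
    tail_mean <- rowMeans(curv[, 20:45])
    expect_true(sign(mean(tail_mean[cw], na.rm = TRUE)) !=
                sign(mean(tail_mean[ccw], na.rm = TRUE)))
  }
})

test_that("planted motifs recur exactly and are found by the matrix profile", {
  sim <- simulate_recording(swim_sim_config(duration_s = 40, seed = 67))
  m <- 30
  ta <- seq(0, 4 * pi, length.out = m)
  tmpl <- outer(sin(ta), c(0.001, 0.01, 0.02, 0.03, 0.03, 0.02, 0.01))
  pl <- plant_motif(sim$recording, tmpl, starts = c(150, 600, 950))
  sc <- segment_curvature(skeleton_curvature(pl$recording),
                          recording_partition(pl$recording))
  ## the planted stretches carry identical shapes: raw profile minima ~ 0
  mp <- matrix_profile_md(sc, m)
  expect_lt(max(mp$profile[c(150, 600, 950)]), 1e-4)
  ## a single plant has nothing to recur with
  one <- plant_motif(simulate_recording(swim_sim_config(duration_s = 40,
                                                        seed = 68))$recording,
                     tmpl, starts = 400)
  sc1 <- segment_curvature(skeleton_curvature(one$recording),
                           recording_partition(one$recording))
  mp1 <- matrix_profile_md(sc1, m)
  expect_gt(mp1$profile[400], 1)
  expect_error(plant_motif(sim$recording, tmpl, starts = c(100, 110)),
               "overlap")
  expect_error(plant_motif(sim$recording, tmpl, starts = 1e6), "within")
})

test_that("planted stimulus responses shift speeds by the stated factor", {
  proto <- stimulus_protocol("blue")
  sim <- simulate_recording(swim_sim_config(duration_s = 100, seed = 69))
  slowed <- plant_stimulus_response(sim$recording, proto,
                                    effect = list(speed_factor = 0.5))
  ## body shapes untouched
  q0 <- quirkiness(cbind(sim$recording$x[950, ], sim$recording$y[950, ]))
  q1 <- quirkiness(cbind(slowed$x[950, ], slowed$y[950, ]))
  expect_equal(q0, q1, tolerance = 1e-10)
  ## centroid displacement halved inside the window
  cx0 <- rowMeans(sim$recording$x); cx1 <- rowMeans(slowed$x)
  win <- 902:2699
  expect_equal(diff(cx1[win]), 0.5 * diff(cx0[win]), tolerance = 1e-8)
  out <- 10:890
  expect_equal(diff(cx1[out]), diff(cx0[out]), tolerance = 1e-8)
})

test_that("simulated datasets carry conditions, controls and ground truth", {
  ds <- simulate_dataset(c(wild_type = 2, drug = 2),
                         base_config = swim_sim_config(duration_s = 2),
                         modifiers = list(drug = function(cfg) {
                           cfg$propulsion_gain <- 5; cfg
                         }),
                         control_map = c(drug = "wild_type"), seed = 70)
  expect_equal(length(ds), 4)
  expect_setequal(unique(dataset_conditions(ds)), c("wild_type", "drug"))
  expect_equal(length(attr(ds, "truths")), 4)
  expect_equal(control_of(ds, "drug"), "wild_type")
  ## invalid configs are rejected
  expect_error(swim_sim_config(transition = matrix(1, 6, 6)), "sum to 1")
  bad_freq <- list(dwell = list(amp = 0, freq = 20, asym = 0, turn_rate = 0,
                                propelled = FALSE))
  expect_error(swim_sim_config(regime_params = bad_freq), "Nyquist")
})
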