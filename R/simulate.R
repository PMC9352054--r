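#' Configuration for the synthetic larval-swim generator
#'
#' The generator emulates the kinematics the analysis pipeline targets: a
#' rigid head with an undulating tail, intermittent locomotion (dwell /
#' beat / glide / clockwise and counter-clockwise turns / startle) driven by
#' a per-frame Markov regime process, asymmetric tail bending during turns,
#' a contour-width profile with a sharp neck constriction, additive
#' curvature observation noise, and optional frame dropouts. The curvature
#' field is a traveling wave over a fixed basis of 6 orthonormal smooth
#' bend shapes on the tail (see [curvature_mode_basis()]), so the
#' eigenposture stage has an exact ground truth:
#' `kappa(s, t) = sum_i a_i(regime) b_i(s) sin(phase_t + (i-1) psi) +
#' asym(regime) b_1(s) + noise`.
#'
#' @param duration_s recording length in seconds.
#' @param fps frames per second (default 30).
#' @param seed RNG seed; fixed seed gives bit-identical recordings.
#' @param body_length_px body length in pixels (default 115.10, the average
#'   larva on the calibrated setup; 1,330.61 um).
#' @param neck_index 1-based skeleton index of the planted neck constriction
#'   (default 13).
#' @param base_curvature_amp peak curvature scale in 1/pixel for a
#'   full-amplitude beat (default 0.09, giving tail deflections up to
#'   roughly a half turn during full beats).
#' @param amp_profile relative amplitudes of the 6 curvature modes.
#' @param wave_phase_lag temporal phase lag between successive modes
#'   (radians); with the default pi/2 each harmonic pair is in quadrature,
#'   so the bend travels down the tail.
#' @param mode_harmonics per-mode frequency multipliers; pairs of modes at
#'   the fundamental and at higher harmonics give the curvature field full
#'   rank over the 6 shapes.
#' @param regime_params named list per regime: `amp` (relative beat
#'   amplitude), `freq` (tail-beat Hz, < fps/2), `asym` (left/right bend
#'   offset, positive = clockwise), `turn_rate` (heading drift, rad/s),
#'   `propelled` (does the regime generate thrust).
#' @param transition 6 x 6 per-frame Markov matrix over the regimes (rows
#'   sum to 1) in the order dwell, beat, glide, turn_cw, turn_ccw, startle.
#' @param propulsion_gain px scale linking beat amplitude x frequency to
#'   swim speed.
#' @param glide_tau_s,dwell_tau_s exponential speed-decay time constants.
#' @param noise_sd curvature observation noise, as a fraction of the maximum
#'   absolute noiseless curvature of the recording.
#' @param dropout_rate per-frame probability of an invalid (dropped) frame.
#' @param condition,animal_id metadata labels.
#' @param stimulus optional [stimulus_protocol()] attached to the recording.
#' @param stimulus_effect optional list (`speed_factor`, `amp_factor`)
#'   applied while the stimulus is on.
#' @return Object of class `swim_sim_config`.
#' @export
swim_sim_config <- function(duration_s = 60, fps = 30, seed = 1,
                            body_length_px = 115.10, neck_index = 13,
                            base_curvature_amp = 0.09,
                            amp_profile = c(1, 0.8, 0.6, 0.5, 0.4, 0.3),
                            wave_phase_lag = pi / 2,
                            mode_harmonics = c(1, 1, 1.5, 1.5, 2, 2),
                            regime_params = NULL,
                            transition = NULL,
                            propulsion_gain = 18,
                            glide_tau_s = 0.5, dwell_tau_s = 0.15,
                            noise_sd = 0.05, dropout_rate = 0,
                            condition = "wild_type", animal_id = "sim",
                            stimulus = NULL, stimulus_effect = NULL) {
  regimes <- c("dwell", "beat", "glide", "turn_cw", "turn_ccw", "startle")
  if (is.null(regime_params)) {
    regime_params <- list(
      dwell    = list(amp = 0,    freq = 0,  asym = 0,     turn_rate = 0,  propelled = FALSE),
      beat     = list(amp = 1,    freq = 5,  asym = 0,     turn_rate = 0,  propelled = TRUE),
      glide    = list(amp = 0.05, freq = 5,  asym = 0,     turn_rate = 0,  propelled = FALSE),
      turn_cw  = list(amp = 0.9,  freq = 5,  asym = 0.5,   turn_rate = 2,  propelled = TRUE),
      turn_ccw = list(amp = 0.9,  freq = 5,  asym = -0.5,  turn_rate = -2, propelled = TRUE),
      startle  = list(amp = 1.8,  freq = 7,  asym = 0.3,   turn_rate = 4,  propelled = TRUE))
  }
  if (is.null(transition)) {
    transition <- rbind(
      dwell    = c(0.9850, 0.0080, 0.0000, 0.0025, 0.0025, 0.0020),
      beat     = c(0.0040, 0.9500, 0.0300, 0.0070, 0.0070, 0.0020),
      glide    = c(0.0300, 0.0200, 0.9500, 0.0000, 0.0000, 0.0000),
      turn_cw  = c(0.0100, 0.0600, 0.0300, 0.9000, 0.0000, 0.0000),
      turn_ccw = c(0.0100, 0.0600, 0.0300, 0.0000, 0.9000, 0.0000),
      startle  = c(0.0000, 0.1000, 0.1000, 0.0000, 0.0000, 0.8000))
    colnames(transition) <- regimes
  }
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop_domain("regime transition rows must sum to 1")
  freqs <- vapply(regime_params, `[[`, numeric(1), "freq")
  if (any(freqs * max(mode_harmonics) >= fps / 2))
    stop_domain("tail-beat frequencies (including mode harmonics) must ",
                "respect the Nyquist limit fps/2")
  structure(list(duration_s = duration_s, fps = fps, seed = seed,
                 body_length_px = body_length_px, neck_index = neck_index,
                 base_curvature_amp = base_curvature_amp,
                 amp_profile = amp_profile, wave_phase_lag = wave_phase_lag,
                 mode_harmonics = mode_harmonics, regimes = regimes, regime_params = regime_params,
                 transition = transition, propulsion_gain = propulsion_gain,
                 glide_tau_s = glide_tau_s, dwell_tau_s = dwell_tau_s,
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 condition = condition, animal_id = animal_id,
                 stimulus = stimulus, stimulus_effect = stimulus_effect),
            class = "swim_sim_config")
}

#' Orthonormal curvature mode shapes
#'
#' Six smooth orthonormal bend shapes supported on the tail (zero on the
#' rigid head through the neck), used as the generating basis of the
#' simulator's curvature field. The shapes are the leading eigenshapes of
#' the linearized curvature measurement chain (skeleton reconstruction
#' followed by Savitzky-Golay curvature estimation, restricted to the tail):
#' the smoothest tail bends the measurement transmits, ordered by
#' transmission gain. Planting these shapes makes the eigenposture stage's
#' ground truth exactly recoverable from the extracted features.
#'
#' @param neck_index 1-based neck index.
#' @param n_modes number of modes (default 6).
#' @param body_length_px body length in pixels (sets the point spacing seen
#'   by the curvature filter).
#' @param sg_window,sg_order Savitzky-Golay parameters of the measurement
#'   chain being matched.
#' @return 49 x n_modes matrix with orthonormal columns and attribute
#'   `gains` (per-mode transmission gain of the measurement chain).
#' @export
curvature_mode_basis <- function(neck_index = 13, n_modes = 6,
                                 body_length_px = 115.10,
                                 sg_window = 15, sg_order = 2) {
  key <- paste(neck_index, n_modes, body_length_px, sg_window, sg_order)
  cached <- .basis_cache[[key]]
  if (!is.null(cached)) return(cached)
  tail_ix <- (neck_index + 2L):N_POINTS
  ds <- body_length_px / (N_POINTS - 1)
  measure <- function(kappa) {
    theta <- c(0, cumsum(-kappa[-N_POINTS] * ds))
    xy <- cbind(c(0, cumsum(cos(theta[-N_POINTS]) * ds)),
                c(0, cumsum(sin(theta[-N_POINTS]) * ds)))
    curvature_one(xy[, 1], xy[, 2], sg_window, sg_order)
  }
  base <- measure(numeric(N_POINTS))
  eps <- 1e-4
  L <- matrix(0, N_POINTS, length(tail_ix))
  for (j in seq_along(tail_ix)) {
    k <- numeric(N_POINTS); k[tail_ix[j]] <- eps
    L[, j] <- (measure(k) - base) / eps
  }
  E <- eigen(L[tail_ix, ])
  vals <- E$values[seq_len(n_modes)]
  if (max(abs(Im(vals))) > 1e-8)
    stop_domain("measurement operator has complex leading modes; ",
                "reduce n_modes")
  V <- qr.Q(qr(Re(E$vectors[, seq_len(n_modes), drop = FALSE])))
  ## fix signs for reproducibility: largest-|entry| positive
  for (i in seq_len(ncol(V)))
    if (V[which.max(abs(V[, i])), i] < 0) V[, i] <- -V[, i]
  B <- matrix(0, N_POINTS, n_modes)
  B[tail_ix, ] <- V
  attr(B, "gains") <- Re(vals)
  .basis_cache[[key]] <- B
  B
}

.basis_cache <- new.env(parent = emptyenv())

#' Contour-width template with a neck constriction
#'
#' Head bulb, sharp width drop across the neck, gently tapering tail --
#' the profile the neck detector keys on.
#'
#' @param neck_index 1-based constriction index.
#' @return Numeric vector of 49 widths (pixels).
#' @export
width_template <- function(neck_index = 13) {
  ## built from its discrete derivative: a triangular drop centered on the
  ## neck (so the smoothed width derivative has a unique minimum there),
  ## a mild head bulb when the head is long enough, and a gentle tail taper
  dw <- numeric(N_POINTS - 1)
  dw[(neck_index + 3L):(N_POINTS - 1L)] <- -0.05
  dw[neck_index + (-2L:2L)] <- c(-0.5, -1, -2, -1, -0.5)
  if (neck_index >= 11L) dw[c(2L, 3L, 5L, 6L)] <- c(1, 1, -1, -1)
  cumsum(c(10, dw))
}

#' Simulate a larval swim recording with ground truth
#'
#' Per frame, a regime is drawn from the Markov chain; the tail curvature
#' field is synthesized from the 6-mode traveling-wave model plus the
#' regime's bend asymmetry and additive observation noise; the skeleton is
#' reconstructed by integrating the tangent angle along arc length at fixed
#' point spacing; and the body is advanced head-first along its heading
#' with a speed proportional to beat amplitude x frequency (decaying
#' exponentially while gliding or dwelling). Widths follow the neck
#' template; dropout frames are marked invalid with missing coordinates.
#'
#' @param config a [swim_sim_config()].
#' @return List with `recording` (a [track_recording()]) and `truth` (a
#'   data.frame: `frame_index`, `regime`, `heading`, `speed_px`,
#'   `stimulus_on`).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "swim_sim_config"))
  set.seed(config$seed)
  fps <- config$fps
  Tn <- as.integer(round(config$duration_s * fps))
  nreg <- length(config$regimes)
  rp <- config$regime_params

  ## regime path
  reg <- integer(Tn)
  reg[1] <- 1L
  for (t in seq_len(Tn - 1L))
    reg[t + 1L] <- sample.int(nreg, 1L, prob = config$transition[reg[t], ])

  ## stimulus window (frames, 0-based half open) and effect multipliers
  stim_on <- rep(FALSE, Tn)
  speed_mult <- rep(1, Tn); amp_mult <- rep(1, Tn)
  if (!is.null(config$stimulus)) {
    on <- config$stimulus$onset_s * fps
    off <- (config$stimulus$onset_s + config$stimulus$duration_s) * fps
    fr <- seq_len(Tn) - 1L
    stim_on <- fr >= on & fr < off
    if (!is.null(config$stimulus_effect)) {
      speed_mult[stim_on] <- config$stimulus_effect$speed_factor %||% 1
      amp_mult[stim_on] <- config$stimulus_effect$amp_factor %||% 1
    }
  }

  ## mode coefficients: traveling wave with per-regime amplitude/asymmetry
  B <- curvature_mode_basis(config$neck_index,
                            body_length_px = config$body_length_px)
  amp <- vapply(rp, `[[`, numeric(1), "amp")[reg] * amp_mult
  freq <- vapply(rp, `[[`, numeric(1), "freq")[reg]
  asym <- vapply(rp, `[[`, numeric(1), "asym")[reg] * amp_mult
  turn <- vapply(rp, `[[`, numeric(1), "turn_rate")[reg]
  propelled <- vapply(rp, `[[`, logical(1), "propelled")[reg]
  phase <- cumsum(2 * pi * freq / fps)
  a0 <- config$base_curvature_amp
  Cmat <- matrix(0, Tn, ncol(B))          # T x 6 mode coefficients
  for (i in seq_len(ncol(B)))
    Cmat[, i] <- a0 * config$amp_profile[i] * amp *
      sin(config$mode_harmonics[i] * phase + (i - 1) * config$wave_phase_lag)
  Cmat[, 1] <- Cmat[, 1] + a0 * 0.8 * asym
  kappa <- Cmat %*% t(B)                  # T x 49 noiseless field

  kmax <- max(abs(kappa))
  if (config$noise_sd > 0 && kmax > 0)
    kappa <- kappa + matrix(rnorm(Tn * N_POINTS, sd = config$noise_sd * kmax),
                            Tn, N_POINTS)

  ## speed dynamics (px/frame)
  v_target <- config$propulsion_gain * amp * freq / fps
  decay_glide <- exp(-1 / (config$glide_tau_s * fps))
  decay_dwell <- exp(-1 / (config$dwell_tau_s * fps))
  v <- numeric(Tn)
  for (t in seq_len(Tn)) {
    prev <- if (t == 1) 0 else v[t - 1]
    v[t] <- if (propelled[t]) v_target[t]
            else prev * (if (reg[t] == 1L) decay_dwell else decay_glide)
    v[t] <- v[t] * speed_mult[t]
  }

  heading <- cumsum(turn / fps) + runif(1, 0, 2 * pi)

  ## skeleton reconstruction: integrate tangent angle along arc length
  ds <- config$body_length_px / (N_POINTS - 1)
  x <- matrix(0, Tn, N_POINTS); y <- matrix(0, Tn, N_POINTS)
  ## head tip trajectory: head-first motion opposite the head->tail tangent
  hx <- cumsum(c(200, -v[-1] * cos(heading[-1])))
  hy <- cumsum(c(200, -v[-1] * sin(heading[-1])))
  for (t in seq_len(Tn)) {
    theta <- heading[t] + c(0, cumsum(-kappa[t, -N_POINTS] * ds))
    x[t, ] <- hx[t] + c(0, cumsum(cos(theta[-N_POINTS]) * ds))
    y[t, ] <- hy[t] + c(0, cumsum(sin(theta[-N_POINTS]) * ds))
  }

  widths <- matrix(rep(width_template(config$neck_index), each = Tn), Tn)
  valid <- rep(TRUE, Tn)
  if (config$dropout_rate > 0) {
    valid <- runif(Tn) >= config$dropout_rate
    x[!valid, ] <- NA_real_; y[!valid, ] <- NA_real_
    widths[!valid, ] <- NA_real_
  }

  rec <- track_recording(x, y, widths, valid = valid, fps = fps,
                         um_per_pixel = 1330.61 / 115.10,
                         condition = config$condition,
                         animal_id = config$animal_id,
                         stimulus = config$stimulus)
  truth <- data.frame(frame_index = rec$frame_index,
                      regime = factor(config$regimes[reg],
                                      levels = config$regimes),
                      heading = heading, speed_px = v, stimulus_on = stim_on)
  attr(truth, "mode_basis") <- B
  attr(truth, "mode_coefficients") <- Cmat
  list(recording = rec, truth = truth)
}

#' Overwrite stretches of a recording with exact repeats of a curvature
#' template
#'
#' Plants a fixed-length 7-channel segment-curvature pattern at the given
#' start frames: the template (one value per body-segment midpoint per
#' frame) is interpolated to a full 49-point curvature field with a natural
#' spline and the skeleton is re-synthesized at those frames, keeping each
#' frame's original head position and heading. All plant sites therefore
#' carry identical body shapes (up to optional noise), which the matrix
#' profile must rediscover.
#'
#' @param rec a [track_recording()].
#' @param template m x 7 matrix of segment-midpoint curvatures (channels
#'   cH..cTT).
#' @param starts 1-based start frames; plants must not overlap and must fit.
#' @param noise_sd optional sd of curvature noise added independently at
#'   each plant site.
#' @return List with `recording` (modified) and `plants` (data.frame of
#'   `start`, `length`).
#' @export
plant_motif <- function(rec, template, starts, noise_sd = 0) {
  template <- as.matrix(template)
  m <- nrow(template)
  stopifnot(ncol(template) == 7)
  starts <- sort(as.integer(starts))
  if (any(starts < 1) || any(starts + m - 1L > n_frames(rec)))
    stop_domain("plant sites must lie within the recording")
  if (any(diff(starts) < m)) stop_domain("plant sites must not overlap")
  part <- recording_partition(rec)
  mids <- part$midpoints
  spacing <- mean(sqrt(diff(rec$x[which(rec$valid)[1], ])^2 +
                       diff(rec$y[which(rec$valid)[1], ])^2))
  for (s in starts) {
    for (off in seq_len(m) - 1L) {
      t <- s + off
      field <- stats::spline(mids, template[off + 1L, ], xout = 1:N_POINTS,
                             method = "natural")$y
      if (noise_sd > 0) field <- field + rnorm(N_POINTS, sd = noise_sd)
      heading <- atan2(rec$y[t, 2] - rec$y[t, 1], rec$x[t, 2] - rec$x[t, 1])
      theta <- heading + c(0, cumsum(-field[-N_POINTS] * spacing))
      rec$x[t, ] <- rec$x[t, 1] + c(0, cumsum(cos(theta[-N_POINTS]) * spacing))
      rec$y[t, ] <- rec$y[t, 1] + c(0, cumsum(sin(theta[-N_POINTS]) * spacing))
      rec$valid[t] <- TRUE
    }
  }
  list(recording = rec, plants = data.frame(start = starts, length = m))
}

#' Plant a stimulus response into a recording
#'
#' Scales the whole-body translation speed by `effect$speed_factor` during
#' the stimulus window: frame-to-frame centroid displacements inside the
#' window are multiplied by the factor while body shapes are untouched, so
#' speed features shift by the planted effect and posture features do not.
#' The protocol is attached to the recording for downstream window analysis.
#'
#' @param rec a [track_recording()].
#' @param protocol a [stimulus_protocol()].
#' @param effect list with `speed_factor` (1 = no change).
#' @return The modified [track_recording()].
#' @export
plant_stimulus_response <- function(rec, protocol, effect = list(speed_factor = 0.5)) {
  fps <- rec$fps
  on <- protocol$onset_s * fps
  off <- (protocol$onset_s + protocol$duration_s) * fps
  f <- effect$speed_factor %||% 1
  Tn <- n_frames(rec)
  in_win <- rec$frame_index >= on & rec$frame_index < off
  cx <- rowMeans(rec$x); cy <- rowMeans(rec$y)
  shift_x <- 0; shift_y <- 0
  for (t in 2:Tn) {
    if (in_win[t]) {
      shift_x <- shift_x - (1 - f) * (cx[t] - cx[t - 1])
      shift_y <- shift_y - (1 - f) * (cy[t] - cy[t - 1])
    }
    rec$x[t, ] <- rec$x[t, ] + shift_x
    rec$y[t, ] <- rec$y[t, ] + shift_y
  }
  rec$stimulus <- protocol
  rec
}

#' Simulate a multi-condition dataset
#'
#' Convenience wrapper generating several recordings per condition with
#' per-condition config modifiers (e.g. a drug arm with altered regime
#' transition probabilities), wired into a [swim_dataset()] with a control
#' map.
#'
#' @param n_per_condition named integer vector: recordings per condition.
#' @param base_config a [swim_sim_config()] serving as the template.
#' @param modifiers named list of functions `function(config) config`
#'   applied to each condition's config.
#' @param control_map condition -> control map.
#' @param seed base seed; recording i of condition c gets a distinct
#'   derived seed.
#' @return A [swim_dataset()] with ground truths in
#'   `attr(, "truths")`.
#' @export
simulate_dataset <- function(n_per_condition, base_config = swim_sim_config(),
                             modifiers = list(), control_map = character(),
                             seed = 1) {
  recs <- list(); truths <- list()
  counter <- 0L
  for (cond in names(n_per_condition)) {
    cfg0 <- base_config
    cfg0$condition <- cond
    if (cond %in% names(modifiers)) cfg0 <- modifiers[[cond]](cfg0)
    for (i in seq_len(n_per_condition[[cond]])) {
      counter <- counter + 1L
      cfg <- cfg0
      cfg$seed <- seed + counter * 101L
      cfg$animal_id <- sprintf("%s_%02d", cond, i)
      sim <- simulate_recording(cfg)
      recs[[cfg$animal_id]] <- sim$recording
      truths[[cfg$animal_id]] <- sim$truth
    }
  }
  ds <- swim_dataset(recs, control_map)
  attr(ds, "truths") <- truths
  ds
}
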