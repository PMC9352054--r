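#' Construct a tracked skeleton recording
#'
#' A `track_recording` holds one animal's midline time series: per frame, 49
#' ordered `(x, y)` midline points in pixels (index 1 = head tip, 49 = tail
#' tip), 49 contour widths in pixels, and a validity flag marking frames where
#' upstream segmentation succeeded. Invalid frames are retained (coordinates
#' may be `NA`) so the time base is preserved; each downstream stage applies
#' its own gap policy.
#'
#' @param x,y numeric T x 49 matrices of midline coordinates (pixels, image
#'   convention: origin top-left, y increasing downward).
#' @param widths numeric T x 49 matrix of contour widths (pixels, >= 0).
#' @param valid logical vector of length T; `FALSE` marks frames where
#'   segmentation failed.
#' @param fps frames per second (default 30).
#' @param frame_index integer frame indices, strictly increasing
#'   (default `0:(T-1)`).
#' @param um_per_pixel optional micrometer-per-pixel scale, see
#'   [calibrate_scale()].
#' @param condition,animal_id metadata labels.
#' @param stimulus optional [stimulus_protocol()].
#' @return An object of class `track_recording`.
#' @export
track_recording <- function(x, y, widths, valid = NULL, fps = 30,
                            frame_index = NULL, um_per_pixel = NA_real_,
                            condition = "wild_type", animal_id = "animal",
                            stimulus = NULL) {
  x <- as.matrix(x); y <- as.matrix(y); widths <- as.matrix(widths)
  n <- nrow(x)
  if (ncol(x) != N_POINTS || ncol(y) != N_POINTS || ncol(widths) != N_POINTS)
    stop_domain("skeletons must have exactly ", N_POINTS, " points per frame; got ",
                ncol(x), "/", ncol(y), "/", ncol(widths), " columns")
  if (nrow(y) != n || nrow(widths) != n)
    stop_domain("x, y and widths must have the same number of frames")
  valid <- if (is.null(valid)) rep(TRUE, n) else as.logical(valid)
  if (length(valid) != n) stop_domain("valid must have one flag per frame")
  ## A frame with any missing coordinate cannot be a valid frame.
  valid <- valid & complete.cases(x) & complete.cases(y)
  if (any(widths[valid, ] < 0, na.rm = TRUE))
    stop_domain("contour widths must be non-negative")
  if (fps <= 0) stop_domain("fps must be positive")
  frame_index <- if (is.null(frame_index)) seq_len(n) - 1L else as.integer(frame_index)
  if (length(frame_index) != n || any(diff(frame_index) <= 0))
    stop_domain("frame_index must be strictly increasing, one per frame")
  if (any(valid)) {
    dx <- x[valid, -1, drop = FALSE] - x[valid, -N_POINTS, drop = FALSE]
    dy <- y[valid, -1, drop = FALSE] - y[valid, -N_POINTS, drop = FALSE]
    if (any(dx^2 + dy^2 <= 0))
      stop_domain("consecutive skeleton points must be strictly separated on valid frames")
  }
  structure(list(x = x, y = y, widths = widths, valid = valid,
                 frame_index = frame_index, fps = fps,
                 um_per_pixel = um_per_pixel, condition = condition,
                 animal_id = animal_id, stimulus = stimulus),
            class = "track_recording")
}

#' @export
print.track_recording <- function(x, ...) {
  cat(sprintf("<track_recording> %s | condition: %s\n", x$animal_id, x$condition))
  cat(sprintf("  %d frames at %g fps (%.1f s), %.1f%% valid\n",
              nrow(x$x), x$fps, nrow(x$x) / x$fps, 100 * mean(x$valid)))
  if (!is.na(x$um_per_pixel))
    cat(sprintf("  scale: %.4f um/px\n", x$um_per_pixel))
  invisible(x)
}

#' @export
length.track_recording <- function(x) nrow(x$x)

#' Number of frames in a recording
#' @param rec a [track_recording()].
#' @return Integer frame count.
#' @export
n_frames <- function(rec) nrow(rec$x)

#' Fraction of valid frames
#' @param rec a [track_recording()].
#' @return Fraction in \[0, 1\].
#' @export
valid_fraction <- function(rec) mean(rec$valid)

#' Calibrate the micrometer-per-pixel scale
#'
#' Converts a measured reference length in pixels and micrometers into a scale
#' factor. The average Ciona larva measures 1,330.61 um, equivalently 115.10
#' pixels, on the acquisition setup the package targets, giving 11.56 um/px.
#'
#' @param length_px reference length in pixels (> 0).
#' @param length_um the same length in micrometers (> 0).
#' @return um-per-pixel scale (`length_um / length_px`).
#' @export
calibrate_scale <- function(length_px, length_um) {
  if (length_px <= 0 || length_um <= 0)
    stop_domain("calibration lengths must be positive")
  length_um / length_px
}

#' Group recordings into a dataset with control pairing
#'
#' @param recordings list of [track_recording()] objects.
#' @param control_map named character vector mapping each non-control
#'   condition to its control condition (e.g. every drug to wild type and
#'   dopamine to ascorbic acid). Conditions absent from the map are treated
#'   as controls themselves.
#' @return An object of class `swim_dataset`.
#' @export
swim_dataset <- function(recordings, control_map = character()) {
  stopifnot(is.list(recordings))
  ok <- vapply(recordings, inherits, logical(1), "track_recording")
  if (!all(ok)) stop_domain("all elements must be track_recording objects")
  conds <- vapply(recordings, function(r) r$condition, character(1))
  for (cond in names(control_map)) {
    if (!control_map[[cond]] %in% conds && cond %in% conds)
      stop_domain("condition '", cond, "' declares control '", control_map[[cond]],
                  "' which has no recordings")
  }
  structure(list(recordings = recordings, control_map = control_map),
            class = "swim_dataset")
}

#' @export
print.swim_dataset <- function(x, ...) {
  conds <- table(vapply(x$recordings, function(r) r$condition, character(1)))
  cat(sprintf("<swim_dataset> %d recordings, %d conditions\n",
              length(x$recordings), length(conds)))
  for (i in seq_along(conds))
    cat(sprintf("  %s: %d\n", names(conds)[i], conds[i]))
  invisible(x)
}

#' @export
length.swim_dataset <- function(x) length(x$recordings)

#' Condition labels of a dataset
#' @param ds a [swim_dataset()].
#' @return Character vector, one label per recording.
#' @export
dataset_conditions <- function(ds) {
  vapply(ds$recordings, function(r) r$condition, character(1))
}

#' Control condition for a condition label
#' @param ds a [swim_dataset()].
#' @param condition condition label.
#' @return The declared control label (the condition itself if none declared).
#' @export
control_of <- function(ds, condition) {
  if (condition %in% names(ds$control_map)) ds$control_map[[condition]] else condition
}

#' Filter recordings by valid-frame fraction
#'
#' Keeps recordings whose fraction of successfully segmented frames is at
#' least `min_valid_fraction` (the model-fitting stages use 0.8, mirroring
#' the "at least 80% of the frames" selection rule). Order is preserved and
#' the filter is idempotent and monotone in the threshold.
#'
#' @param ds a [swim_dataset()].
#' @param min_valid_fraction threshold in \[0, 1\].
#' @return Filtered `swim_dataset`.
#' @export
filter_recordings <- function(ds, min_valid_fraction = 0.8) {
  if (min_valid_fraction < 0 || min_valid_fraction > 1)
    stop_domain("min_valid_fraction must lie in [0, 1]")
  keep <- vapply(ds$recordings, valid_fraction, numeric(1)) >= min_valid_fraction
  swim_dataset(ds$recordings[keep], ds$control_map)
}
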