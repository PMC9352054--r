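#' Signed curvature along the skeleton
#'
#' Treats the 49 midline points as samples of a differentiable plane curve
#' and computes the rate of change of the tangent angle with respect to arc
#' length, `kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)`, with first and
#' second derivatives over point index estimated by a Savitzky-Golay filter
#' (window 15, polynomial order 2). Units are 1/pixel. Positive curvature is
#' a leftward bend relative to head-to-tail traversal in the image coordinate
#' frame (y down). Invalid frames yield rows of `NA`.
#'
#' @param rec a [track_recording()], or a single frame given as a 49 x 2
#'   matrix of (x, y).
#' @param sg_window,sg_order Savitzky-Golay window length and polynomial
#'   order.
#' @return T x 49 matrix of curvatures (a vector of 49 for a single frame).
#' @export
skeleton_curvature <- function(rec, sg_window = 15, sg_order = 2) {
  if (is.matrix(rec)) {
    return(curvature_one(rec[, 1], rec[, 2], sg_window, sg_order))
  }
  out <- matrix(NA_real_, n_frames(rec), N_POINTS)
  ok <- rec$valid
  if (!any(ok)) return(out)
  ## Savitzky-Golay differentiation is linear, so apply its (cached) matrix
  ## form to all valid frames at once
  D1 <- t(sg_operator(N_POINTS, sg_order, sg_window, 1))
  D2 <- t(sg_operator(N_POINTS, sg_order, sg_window, 2))
  X <- rec$x[ok, , drop = FALSE]; Y <- rec$y[ok, , drop = FALSE]
  xp <- X %*% D1; yp <- Y %*% D1
  xpp <- X %*% D2; ypp <- Y %*% D2
  out[ok, ] <- -(xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  out
}

curvature_one <- function(x, y, sg_window, sg_order) {
  xp <- signal::sgolayfilt(x, p = sg_order, n = sg_window, m = 1)
  yp <- signal::sgolayfilt(y, p = sg_order, n = sg_window, m = 1)
  xpp <- signal::sgolayfilt(x, p = sg_order, n = sg_window, m = 2)
  ypp <- signal::sgolayfilt(y, p = sg_order, n = sg_window, m = 2)
  ## image y axis points down, so the sign flip makes positive curvature a
  ## leftward bend along head-to-tail traversal
  num <- xp * ypp - yp * xpp
  den <- (xp^2 + yp^2)^1.5
  -num / den
}

## matrix form of sgolayfilt on signals of length n (built column-by-column
## from the filter itself, so it is exactly equivalent)
sg_operator <- local({
  cache <- new.env(parent = emptyenv())
  function(n, p, w, m) {
    key <- paste(n, p, w, m)
    M <- cache[[key]]
    if (is.null(M)) {
      M <- vapply(seq_len(n), function(j) {
        e <- numeric(n); e[j] <- 1
        signal::sgolayfilt(e, p = p, n = w, m = m)
      }, numeric(n))
      cache[[key]] <- M
    }
    M
  }
})

#' Relative tangent angles of the 6 posterior segments
#'
#' Each segment's tangent angle is the four-quadrant arctangent of the chord
#' joining its two end skeleton points; the head segment's angle is the
#' reference, and the relative tangent angle of each of the 6 segments from
#' neck to tail tip is the wrapped difference into (-pi, pi]. This expresses
#' posture in the animal's own frame: a straight animal has all six equal to
#' zero regardless of heading.
#'
#' @param frame_xy 49 x 2 matrix of (x, y) for one frame.
#' @param partition a [partition_segments()] result.
#' @return Named numeric vector of 6 angles (radians), `rtaN..rtaTT`.
#' @export
relative_tangent_angles <- function(frame_xy, partition) {
  angles <- vapply(partition$ranges, function(ix) {
    a <- ix[1]; b <- ix[length(ix)]
    dx <- frame_xy[b, 1] - frame_xy[a, 1]
    dy <- frame_xy[b, 2] - frame_xy[a, 2]
    if (dx == 0 && dy == 0)
      stop_domain("coincident segment endpoints: tangent angle undefined")
    atan2(dy, dx)
  }, numeric(1))
  rta <- wrap_angle(angles[-1] - angles[1])
  names(rta) <- paste0("rta", SEGMENT_CODES[-1])
  rta
}

#' Quirkiness of a skeleton
#'
#' A bounded eccentricity of the body's bounding box taken along the skeleton
#' point cloud's principal axes: `q = sqrt(1 - (b/a)^2)` where `a >= b` are
#' the extents along the two principal axes. A perfectly straight skeleton
#' has q = 1; a skeleton whose principal-axis bounding box is a square
#' (a maximally curled body) approaches q = 0. Using principal axes rather
#' than image axes makes the measure rotation invariant.
#'
#' @param frame_xy 49 x 2 matrix of (x, y) for one frame.
#' @return Scalar in \[0, 1\].
#' @export
quirkiness <- function(frame_xy) {
  ctr <- scale(frame_xy, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 2)
  proj <- ctr %*% sv$v
  ext <- apply(proj, 2, function(p) diff(range(p)))
  a <- max(ext); b <- min(ext)
  if (a == 0) stop_domain("all skeleton points coincide: quirkiness undefined")
  sqrt(1 - (b / a)^2)
}

#' Per-frame segment speeds
#'
#' The speed of each skeleton point is its Euclidean displacement in the
#' arena between two adjacent frames (pixels/frame); a segment's speed is the
#' mean over its points. The first frame and any frame adjacent to an invalid
#' frame are `NA` (masked, not interpolated). Multiply by
#' `um_per_pixel * fps` for um/s.
#'
#' @param rec a [track_recording()].
#' @param partition a [partition_segments()] result (default: derived from
#'   the recording's median width profile).
#' @return T x 6 matrix with columns `sN..sTT`.
#' @export
segment_speeds <- function(rec, partition = recording_partition(rec)) {
  Tn <- n_frames(rec)
  out <- matrix(NA_real_, Tn, 6L,
                dimnames = list(NULL, paste0("s", SEGMENT_CODES[-1])))
  if (Tn < 2) return(out)
  ok <- rec$valid[-Tn] & rec$valid[-1]
  disp <- sqrt((rec$x[-1, , drop = FALSE] - rec$x[-Tn, , drop = FALSE])^2 +
               (rec$y[-1, , drop = FALSE] - rec$y[-Tn, , drop = FALSE])^2)
  segs <- partition$ranges[-1]
  for (j in seq_along(segs)) {
    v <- rowMeans(disp[, segs[[j]], drop = FALSE])
    v[!ok] <- NA_real_
    out[-1, j] <- v
  }
  out
}

#' Head- and tail-region straight-line deviation profiles
#'
#' Diagnostic for head rigidity: for every skeleton point in the head region,
#' the perpendicular distance to the straight line joining the head tip and
#' the neck point; for every point in the tail region, the distance to the
#' line joining the neck point and the tail tip. A rigid head shows small
#' head-region deviations compared to the undulating tail.
#'
#' @param rec a [track_recording()].
#' @param partition a [partition_segments()] result.
#' @return List with T x n matrices `head` and `tail` of distances (pixels;
#'   `NA` on invalid frames or degenerate chords), and the index vectors used.
#' @export
head_rigidity_profile <- function(rec, partition = recording_partition(rec)) {
  nk <- partition$neck_index
  head_ix <- 1L:(nk - 1L)          # between head tip and neck
  tail_ix <- (nk + 1L):N_POINTS    # between neck and tail tip
  Tn <- n_frames(rec)
  H <- matrix(NA_real_, Tn, length(head_ix))
  Tl <- matrix(NA_real_, Tn, length(tail_ix))
  for (t in which(rec$valid)) {
    p <- cbind(rec$x[t, ], rec$y[t, ])
    H[t, ] <- point_line_dist(p[head_ix, , drop = FALSE], p[1L, ], p[nk, ])
    Tl[t, ] <- point_line_dist(p[tail_ix, , drop = FALSE], p[nk, ], p[N_POINTS, ])
  }
  list(head = H, tail = Tl, head_index = head_ix, tail_index = tail_ix)
}

point_line_dist <- function(pts, a, b) {
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0) return(rep(NA_real_, nrow(pts)))
  abs((pts[, 1] - a[1]) * d[2] - (pts[, 2] - a[2]) * d[1]) / len
}

#' Build the 25-feature posture panel for a recording
#'
#' Per frame: the 6 segment curvatures at segment midpoints (neck to tail
#' tip), the 6 relative tangent angles, the 6 segment speeds, the 6
#' eigencoefficients (when an eigenbasis is supplied) and quirkiness --
#' 25 named features. Invalid frames carry `NA`.
#'
#' @param rec a [track_recording()].
#' @param basis optional [eigencionas()] basis for the EC columns.
#' @param partition segment partition (default from the recording).
#' @param curv optional precomputed [skeleton_curvature()] matrix.
#' @return data.frame with `frame_index`, `valid` and the 25 feature columns
#'   of [panel_feature_names()].
#' @export
feature_panel <- function(rec, basis = NULL,
                          partition = recording_partition(rec),
                          curv = skeleton_curvature(rec)) {
  Tn <- n_frames(rec)
  segc <- segment_curvature(curv, partition)[, -1, drop = FALSE]  # drop head
  rta <- matrix(NA_real_, Tn, 6L,
                dimnames = list(NULL, paste0("rta", SEGMENT_CODES[-1])))
  quirk <- rep(NA_real_, Tn)
  for (t in which(rec$valid)) {
    p <- cbind(rec$x[t, ], rec$y[t, ])
    rta[t, ] <- relative_tangent_angles(p, partition)
    quirk[t] <- quirkiness(p)
  }
  sp <- segment_speeds(rec, partition)
  ec <- matrix(NA_real_, Tn, 6L, dimnames = list(NULL, paste0("EC", 1:6)))
  if (!is.null(basis)) ec[, ] <- project_curvature(curv, basis)[, 1:6]
  out <- data.frame(frame_index = rec$frame_index, valid = rec$valid,
                    segc, rta, sp, ec, quirkiness = quirk,
                    check.names = FALSE)
  stopifnot(identical(setdiff(names(out), c("frame_index", "valid")),
                      panel_feature_names()))
  out
}

#' Curvature at the 7 segment midpoints
#'
#' @param curv T x 49 curvature matrix (see [skeleton_curvature()]).
#' @param partition a [partition_segments()] result.
#' @return T x 7 matrix with columns `cH, cN, cTB, cTprM, cTM, cTpoM, cTT`.
#' @export
segment_curvature <- function(curv, partition) {
  m <- curv[, partition$midpoints, drop = FALSE]
  colnames(m) <- paste0("c", SEGMENT_CODES)
  m
}
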