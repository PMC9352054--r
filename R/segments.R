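#' Detect the neck point from a contour-width profile
#'
#' The neck is the point where the wide head region ends and the narrow tail
#' begins: the contour width decreases sharply there. The width profile is
#' smoothed with a 5-point moving average (truncated at the ends), first
#' differences are taken, and the index with the most negative difference
#' within the admissible anterior range is returned; ties break toward the
#' anterior. The admissible range is points 4..22 in 0-based skeleton
#' numbering, i.e. 5..23 in R's 1-based indexing used throughout.
#'
#' @param widths numeric vector of 49 contour widths (pixels).
#' @param range admissible 1-based index range (default `c(5, 23)`).
#' @return 1-based neck index.
#' @export
detect_neck <- function(widths, range = c(5L, 23L)) {
  if (length(widths) != N_POINTS || !all(is.finite(widths)))
    stop_domain("widths must be ", N_POINTS, " finite values")
  if (diff(stats::fivenum(widths)[c(1, 5)]) == 0)
    stop_domain("degenerate width profile: all widths equal, no neck")
  ws <- smooth_ma(widths, 5L)
  d <- diff(ws)                       # d[i] = ws[i+1] - ws[i], decrease at i
  lo <- max(range[1], 1L); hi <- min(range[2], N_POINTS - 1L)
  dd <- d[lo:hi]
  if (min(dd) >= 0)
    stop_domain("no width decrease in the neck range: cannot locate a neck")
  lo + which.min(dd) - 1L             # which.min breaks ties to the anterior
}

## Centered moving average with truncated edge windows.
smooth_ma <- function(x, w) {
  n <- length(x)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
}

#' Partition the 49 skeleton points into 7 body segments
#'
#' Head runs from the head tip to two points before the neck, the neck
#' segment is the 3 points centered on the neck index, and the remaining tail
#' points are split into 5 contiguous blocks (tail base, tail pre-mid, tail
#' mid, tail post-mid, tail tip) of as-equal-as-possible size, any remainder
#' going to the most posterior blocks. Each segment's midpoint is its central
#' index (lower-middle for even sizes).
#'
#' @param neck_index 1-based neck index in 5..23 (see [detect_neck()]).
#' @return Object of class `segment_partition`: list with `neck_index`,
#'   `ranges` (named list of index vectors) and `midpoints` (named integer
#'   vector of 7).
#' @export
partition_segments <- function(neck_index) {
  neck_index <- as.integer(neck_index)
  if (neck_index < 5L || neck_index > 23L)
    stop_domain("neck_index must lie in 5..23 (1-based); got ", neck_index)
  ranges <- vector("list", 7L)
  names(ranges) <- SEGMENT_NAMES
  ranges$Head <- 1L:(neck_index - 2L)
  ranges$Neck <- (neck_index - 1L):(neck_index + 1L)
  tail_idx <- (neck_index + 2L):N_POINTS
  L <- length(tail_idx)
  base <- L %/% 5L; rem <- L %% 5L
  sizes <- rep(base, 5L) + c(rep(0L, 5L - rem), rep(1L, rem))  # posterior-heavy
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (b in 1:5) ranges[[b + 2L]] <- tail_idx[starts[b]:ends[b]]
  midpoints <- vapply(ranges, function(ix) ix[(length(ix) + 1L) %/% 2L], integer(1))
  structure(list(neck_index = neck_index, ranges = ranges, midpoints = midpoints),
            class = "segment_partition")
}

#' @export
print.segment_partition <- function(x, ...) {
  cat(sprintf("<segment_partition> neck at point %d\n", x$neck_index))
  for (nm in names(x$ranges)) {
    ix <- x$ranges[[nm]]
    cat(sprintf("  %-12s %2d..%2d (mid %2d)\n", nm, min(ix), max(ix),
                x$midpoints[[nm]]))
  }
  invisible(x)
}

#' Segment partition for a whole recording
#'
#' Detects the neck from the median width profile over valid frames (stable
#' against per-frame segmentation jitter) and partitions the skeleton.
#'
#' @param rec a [track_recording()].
#' @param range admissible 1-based neck range.
#' @return A [partition_segments()] result.
#' @export
recording_partition <- function(rec, range = c(5L, 23L)) {
  if (!any(rec$valid)) stop_domain("recording has no valid frames")
  med_w <- apply(rec$widths[rec$valid, , drop = FALSE], 2, median)
  partition_segments(detect_neck(med_w, range = range))
}
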