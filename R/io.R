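#' Write a recording to the CSV interchange format
#'
#' One row per frame with columns `frame_index`, `valid`, `x0..x48`,
#' `y0..y48`, `w0..w48`. Coordinates are written with enough digits for an
#' exact (to 1e-6 px) round trip. Metadata (fps, scale, condition, animal id)
#' travels in the dataset manifest, not in the per-frame file.
#'
#' @param rec a [track_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  idx <- 0:(N_POINTS - 1)
  df <- data.frame(frame_index = rec$frame_index, valid = as.integer(rec$valid))
  xs <- as.data.frame(rec$x); names(xs) <- paste0("x", idx)
  ys <- as.data.frame(rec$y); names(ys) <- paste0("y", idx)
  ws <- as.data.frame(rec$widths); names(ws) <- paste0("w", idx)
  out <- cbind(df, xs, ys, ws)
  ## signif keeps files compact while preserving 1e-6 px round trips
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 12))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tracked skeleton recording
#'
#' Reads the documented CSV interchange (one row per frame: `frame_index`,
#' `valid`, `x0..x48`, `y0..y48`, `w0..w48`). Invalid or missing frames are
#' loaded with `valid = FALSE`, never dropped, so the recording keeps its
#' clock.
#'
#' @param path file path.
#' @param dialect input dialect; only `"csv-interchange"` is readable here.
#'   `"tierpsy-hdf5"` names the upstream tracker's HDF5 layout and raises an
#'   informative error (export such files to the CSV interchange upstream).
#' @param ... further arguments passed to [track_recording()] (fps, condition,
#'   animal_id, um_per_pixel, stimulus).
#' @return A [track_recording()].
#' @export
read_recording <- function(path, dialect = c("csv-interchange", "tierpsy-hdf5"),
                           ...) {
  dialect <- match.arg(dialect)
  if (dialect == "tierpsy-hdf5")
    stop_domain("the tierpsy-hdf5 dialect requires an HDF5 reader; ",
                "export the skeletons/widths arrays to the CSV interchange")
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("frame_index", "valid",
            paste0("x", 0:(N_POINTS - 1)),
            paste0("y", 0:(N_POINTS - 1)),
            paste0("w", 0:(N_POINTS - 1)))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    ## distinguish a wrong point count (schema) from a malformed file
    got_x <- sum(grepl("^x[0-9]+$", names(df)))
    if (got_x > 0 && got_x != N_POINTS)
      stop_domain("schema error in ", path, ": expected ", N_POINTS,
                  " skeleton points per frame, found ", got_x)
    stop_domain("parse error in ", path, ": missing column '", missing_cols[1], "'")
  }
  for (col in need) {
    bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop_domain("parse error in ", path, ": non-numeric value in column '",
                  col, "', row ", bad[1])
    df[[col]] <- as.numeric(df[[col]])
  }
  grab <- function(prefix)
    as.matrix(df[paste0(prefix, 0:(N_POINTS - 1))])
  track_recording(x = grab("x"), y = grab("y"), widths = grab("w"),
                  valid = df$valid > 0, frame_index = as.integer(df$frame_index),
                  ...)
}

#' Write a dataset manifest
#'
#' Tabular description of a dataset: one row per recording with its file
#' path, condition, declared control condition, animal id, fps and scale.
#'
#' @param ds a [swim_dataset()].
#' @param paths character vector of per-recording file paths (as written by
#'   [write_recording()]).
#' @param path manifest output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(ds, paths, path) {
  stopifnot(length(paths) == length(ds$recordings))
  rows <- lapply(seq_along(ds$recordings), function(i) {
    r <- ds$recordings[[i]]
    data.frame(path = paths[i], animal_id = r$animal_id, condition = r$condition,
               control = control_of(ds, r$condition), fps = r$fps,
               um_per_pixel = r$um_per_pixel)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a dataset from a manifest
#'
#' @param path manifest CSV path (columns `path`, `animal_id`, `condition`,
#'   `control`, `fps`, `um_per_pixel`); recording paths are resolved relative
#'   to the manifest's directory when not absolute.
#' @return A [swim_dataset()].
#' @export
read_manifest <- function(path) {
  man <- read.csv(path)
  base <- dirname(path)
  recs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_recording(p, fps = man$fps[i], condition = man$condition[i],
                   animal_id = man$animal_id[i],
                   um_per_pixel = man$um_per_pixel[i] %||% NA_real_)
  })
  cm <- man$control[match(unique(man$condition), man$condition)]
  names(cm) <- unique(man$condition)
  cm <- cm[!is.na(cm) & cm != names(cm)]
  swim_dataset(recs, cm)
}
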