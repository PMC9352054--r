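#' Rolling-mean smoothing of multichannel series
#'
#' Centered rolling mean of width `width` (default 10 frames) applied to each
#' channel independently before matrix profiling; edge windows are computed
#' on the truncated window.
#'
#' @param series T x C numeric matrix (frames in rows).
#' @param width window width in frames.
#' @return Smoothed T x C matrix.
#' @export
smooth_channels <- function(series, width = 10L) {
  series <- as.matrix(series)
  if (nrow(series) < width)
    stop_domain("series shorter than the smoothing window (", width, " frames)")
  apply(series, 2, smooth_ma, w = width)
}

#' Multidimensional matrix profile
#'
#' For each subsequence start, the mean across all channels of the
#' z-normalized Euclidean distance to the best jointly matching other
#' subsequence of length `m`, with a trivial-match exclusion zone of
#' `ceiling(m/2)` around self. Low profile values mark recurring
#' multichannel motifs. Windows covering invalid (`NA`) frames neither
#' receive nor provide matches and carry `Inf`. Near-constant windows are
#' handled by a variance floor.
#'
#' @param series T x C numeric matrix (e.g. the 7 segment curvatures over
#'   time); `NA` rows mark invalid frames.
#' @param m window length in frames (the package uses 30 and 150 at 30 fps).
#' @param var_floor lower bound on window variances for z-normalization.
#' @return Object of class `matrix_profile`: list with `profile`
#'   (length T-m+1), `index` (1-based best-match starts), `m`.
#' @export
matrix_profile_md <- function(series, m, var_floor = 1e-8) {
  series <- as.matrix(series)
  Tn <- nrow(series)
  if (m < 4) stop_domain("window m must be at least 4")
  if (Tn < 2 * m)
    stop_domain("series must be at least twice the window length")
  bad_frame <- !complete.cases(series)
  ## a window is bad if any frame inside it is invalid
  nwin <- Tn - m + 1L
  bad_start <- as.logical(stats::filter(as.numeric(bad_frame), rep(1, m),
                                        sides = 1)[m:Tn] > 0)
  filled <- series
  filled[bad_frame, ] <- 0
  res <- mp_multidim(filled, as.integer(m), bad_start, var_floor)
  structure(list(profile = res$profile, index = res$index, m = as.integer(m)),
            class = "matrix_profile")
}

#' @export
print.matrix_profile <- function(x, ...) {
  fin <- x$profile[is.finite(x$profile)]
  cat(sprintf("<matrix_profile> m = %d, %d windows (%d valid)\n",
              x$m, length(x$profile), length(fin)))
  if (length(fin))
    cat(sprintf("  profile: min %.3f, median %.3f, max %.3f\n",
                min(fin), median(fin), max(fin)))
  invisible(x)
}

#' Extract motif start indices from a matrix profile
#'
#' Local minima of the profile with value below `threshold` are candidate
#' motif onsets; they are accepted greedily in ascending profile order with
#' an exclusion zone of `m` frames between accepted starts, so extracted
#' motifs never overlap.
#'
#' @param mp a [matrix_profile_md()] result (or a numeric profile vector,
#'   in which case `m` must be given).
#' @param threshold profile threshold (default 8).
#' @param m window length (taken from `mp` when available).
#' @return Integer vector of accepted 1-based start indices (possibly empty),
#'   sorted by position.
#' @export
extract_motifs <- function(mp, threshold = 8, m = NULL) {
  if (inherits(mp, "matrix_profile")) {
    prof <- mp$profile; m <- mp$m
  } else {
    prof <- as.numeric(mp)
    if (is.null(m)) stop_domain("m must be supplied with a bare profile")
  }
  n <- length(prof)
  if (n == 0) return(integer(0))
  ## local minima (edges count when they dip below their single neighbor)
  left <- c(Inf, prof[-n]); right <- c(prof[-1], Inf)
  cand <- which(prof < threshold & prof <= left & prof <= right &
                is.finite(prof))
  if (!length(cand)) return(integer(0))
  cand <- cand[order(prof[cand], cand)]
  accepted <- integer(0)
  for (s in cand) {
    if (!length(accepted) || all(abs(accepted - s) >= m))
      accepted <- c(accepted, s)
  }
  sort(accepted)
}

#' Build a motif catalog across recordings
#'
#' Smooths each recording's 7-channel segment-curvature series, computes the
#' multidimensional matrix profile, extracts motif onsets under the
#' threshold, and collects the motif subsequences.
#'
#' @param seg_curv named list of T x 7 segment-curvature matrices, one per
#'   recording (see [segment_curvature()]).
#' @param m motif window length in frames (30 or 150).
#' @param threshold profile threshold (default 8).
#' @param smooth_width rolling-mean width (default 10).
#' @param conditions optional named character vector of per-recording
#'   condition labels (defaults to names of `seg_curv`).
#' @return Object of class `motif_set`: `info` data.frame (recording,
#'   condition, start), `data` list of m x 7 motif matrices, `m`,
#'   `threshold`.
#' @export
motif_catalog <- function(seg_curv, m, threshold = 8, smooth_width = 10L,
                          conditions = NULL) {
  if (is.null(names(seg_curv)))
    names(seg_curv) <- paste0("rec", seq_along(seg_curv))
  if (is.null(conditions))
    conditions <- setNames(names(seg_curv), names(seg_curv))
  info <- list(); data <- list()
  for (id in names(seg_curv)) {
    x <- smooth_channels(seg_curv[[id]], smooth_width)
    if (nrow(x) < 2 * m) next
    mp <- matrix_profile_md(x, m)
    starts <- extract_motifs(mp, threshold)
    for (s in starts) {
      info[[length(info) + 1L]] <-
        data.frame(recording = id, condition = unname(conditions[id]),
                   start = s, stringsAsFactors = FALSE)
      data[[length(data) + 1L]] <- x[s:(s + m - 1L), , drop = FALSE]
    }
  }
  info <- if (length(info)) do.call(rbind, info) else
    data.frame(recording = character(0), condition = character(0),
               start = integer(0))
  structure(list(info = info, data = data, m = as.integer(m),
                 threshold = threshold),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> %d motifs of %d frames (threshold %g)\n",
              length(x$data), x$m, x$threshold))
  invisible(x)
}

#' Cluster motifs by time-series k-means
#'
#' Euclidean k-means on the flattened (un-normalized) m x 7 motif matrices,
#' with a fixed seed for reproducibility; motif clusters therefore separate
#' both by shape and by amplitude.
#'
#' @param motifs a [motif_catalog()] result, or a list of m x 7 matrices.
#' @param k number of clusters (default 15).
#' @param seed RNG seed for the k-means initialization.
#' @param nstart number of random starts.
#' @return Object of class `motif_cluster_model`: `labels` (1..k), `centers`
#'   (list of m x 7 matrices), `inertia` (total within-cluster sum of
#'   squares), `k`, `seed`.
#' @export
cluster_motifs <- function(motifs, k = 15, seed = 1, nstart = 10) {
  data <- if (inherits(motifs, "motif_set")) motifs$data else motifs
  if (length(data) < k)
    stop_domain("need at least k = ", k, " motifs to form ", k, " clusters; got ",
                length(data))
  X <- t(vapply(data, as.vector, numeric(length(data[[1]]))))
  set.seed(seed)
  km <- kmeans(X, centers = k, nstart = nstart, iter.max = 100)
  centers <- lapply(seq_len(k), function(i)
    matrix(km$centers[i, ], nrow = nrow(data[[1]]), ncol = ncol(data[[1]])))
  structure(list(labels = km$cluster, centers = centers,
                 inertia = km$tot.withinss, k = as.integer(k), seed = seed),
            class = "motif_cluster_model")
}

#' Within-cluster inertia over a range of k
#'
#' @param motifs as in [cluster_motifs()].
#' @param ks candidate cluster counts.
#' @param seed,nstart as in [cluster_motifs()].
#' @return data.frame with columns `k` and `inertia`.
#' @export
inertia_curve <- function(motifs, ks, seed = 1, nstart = 10) {
  inertia <- vapply(ks, function(k)
    cluster_motifs(motifs, k = k, seed = seed, nstart = nstart)$inertia,
    numeric(1))
  data.frame(k = ks, inertia = inertia)
}

#' Elbow selection of the cluster count
#'
#' Picks the k at the maximum discrete second difference of the inertia
#' curve (the point where the decrease in inertia levels out); ties break to
#' the smallest k. Requires at least 4 candidate values.
#'
#' @param ks candidate cluster counts (increasing).
#' @param inertia within-cluster inertia at each k (same length).
#' @return The selected k.
#' @export
elbow_select <- function(ks, inertia) {
  if (length(ks) < 4) stop_domain("need at least 4 candidate k values")
  o <- order(ks)
  ks <- ks[o]; inertia <- inertia[o]
  d2 <- diff(inertia, differences = 2)    # at ks[2..(n-1)]
  ks[which.max(d2) + 1L]
}

#' Per-condition motif-cluster usage and fold change
#'
#' For each condition, the percentage share of its motifs falling in each
#' cluster (rows sum to 100), and the percentage fold change relative to the
#' declared control: `(condition% - control%) / control% * 100`.
#'
#' @param motifs a [motif_catalog()] result.
#' @param model a [cluster_motifs()] model for the same motifs.
#' @param control_map named character vector mapping conditions to control
#'   conditions (conditions not named are their own control).
#' @return List with matrices `usage` and `fold_change`
#'   (condition x cluster, in percent).
#' @export
motif_usage <- function(motifs, model, control_map = character()) {
  usage_table(motifs$info$condition, model$labels, model$k, control_map)
}

## shared by motif_usage / state_usage / cluster-map usage
usage_table <- function(conditions, labels, k, control_map) {
  keep <- !is.na(labels) & labels >= 1
  conditions <- conditions[keep]; labels <- labels[keep]
  conds <- unique(conditions)
  usage <- matrix(0, length(conds), k,
                  dimnames = list(conds, seq_len(k)))
  for (cond in conds) {
    tab <- tabulate(labels[conditions == cond], nbins = k)
    usage[cond, ] <- 100 * tab / sum(tab)
  }
  fold <- usage * NA_real_
  for (cond in conds) {
    ctrl <- if (cond %in% names(control_map)) control_map[[cond]] else cond
    if (!ctrl %in% conds)
      stop_domain("control condition '", ctrl, "' absent from the data")
    fold[cond, ] <- 100 * (usage[cond, ] - usage[ctrl, ]) / usage[ctrl, ]
  }
  list(usage = usage, fold_change = fold)
}
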