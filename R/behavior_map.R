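#' Morlet wavelet features of eigencoefficient series
#'
#' Continuous Morlet wavelet transform modulus of each eigencoefficient
#' channel at 30 uniformly spaced frequencies in 1..30 Hz (at 30 fps),
#' giving the 6 x 30 = 180-dimensional spatiotemporal feature vector per
#' frame. The transform is computed in the Fourier domain with reflective
#' edge padding; the analytic Morlet mother wavelet has center parameter
#' `omega0` (default 5), scales follow the standard Morlet center-frequency
#' relation, and each scale's modulus is normalized by `scale^(-1/2)` so
#' responses across frequencies are comparable. All entries are >= 0.
#'
#' @param ec T x C matrix of eigencoefficients (no gaps; split recordings at
#'   invalid frames first).
#' @param fps sampling rate in frames/second.
#' @param freqs frequency grid in Hz (default 30 values in 1..30).
#' @param omega0 Morlet center parameter.
#' @return T x (C * length(freqs)) matrix of wavelet moduli; columns grouped
#'   by channel, frequency fastest.
#' @export
wavelet_features <- function(ec, fps = 30, freqs = seq(1, 30, length.out = 30),
                             omega0 = 5) {
  ec <- as.matrix(ec)
  Tn <- nrow(ec); C <- ncol(ec)
  if (Tn < 64) stop_domain("series too short for wavelet features (need >= 64 frames)")
  if (any(!is.finite(ec)))
    stop_domain("gaps in the series; split at invalid frames first")
  ## Morlet center frequency (cycles/sample at scale 1)
  fc <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  scales <- fc * fps / freqs
  ## reflective padding to blunt edge effects
  pad <- min(Tn - 1L, ceiling(max(scales) * 6))
  idx_pre <- (pad + 1):2
  idx_post <- (Tn - 1):(Tn - pad)
  N <- Tn + 2 * pad
  omega <- 2 * pi * c(seq(0, floor(N / 2)), seq(-ceiling(N / 2) + 1, -1)) / N
  out <- matrix(0, Tn, C * length(freqs))
  cn <- character(C * length(freqs))
  chan_names <- colnames(ec) %||% paste0("EC", seq_len(C))
  for (c in seq_len(C)) {
    xp <- c(ec[idx_pre, c], ec[, c], ec[idx_post, c])
    Fx <- fft(xp)
    for (s in seq_along(scales)) {
      sc <- scales[s]
      psi_hat <- ifelse(omega > 0,
                        pi^(-0.25) * exp(-0.5 * (sc * omega - omega0)^2), 0)
      w <- fft(Fx * psi_hat, inverse = TRUE) / N
      col <- (c - 1L) * length(freqs) + s
      out[, col] <- Mod(w[pad + seq_len(Tn)]) / sqrt(sc)
      cn[col] <- sprintf("%s_%gHz", chan_names[c], freqs[s])
    }
  }
  colnames(out) <- cn
  out
}

#' Speed-weighted frame sampling
#'
#' Samples frames with probability proportional to a weighted sum of
#' segment speeds -- 50% weight on the neck segment and 10% on each of the
#' 5 tail segments -- so active swimming is well represented in the
#' embedding training set. Draws are without replacement unless more frames
#' are requested than exist (then with replacement, flagged). Frames with
#' missing speeds are excluded; if every weight is zero, sampling falls back
#' to uniform with a warning.
#'
#' @param speeds n x 6 matrix of segment speeds (`sN..sTT`).
#' @param n number of frames to draw (default 200000).
#' @param seed RNG seed.
#' @return Integer vector of sampled row indices, with attribute
#'   `replacement` (logical).
#' @export
speed_weighted_sample <- function(speeds, n = 200000, seed = 1) {
  speeds <- as.matrix(speeds)
  stopifnot(ncol(speeds) == 6)
  w <- 0.5 * speeds[, 1] + 0.1 * rowSums(speeds[, 2:6, drop = FALSE])
  ok <- which(is.finite(w))
  if (!length(ok)) stop_domain("no frames with finite speed weights")
  wv <- w[ok]
  if (sum(wv) <= 0) {
    warning("all speed weights are zero; falling back to uniform sampling")
    wv <- rep(1, length(ok))
  }
  replacement <- n > length(ok)
  if (replacement)
    warning("requested more frames than available; sampling with replacement")
  set.seed(seed)
  draw <- sample(ok, size = n, replace = replacement, prob = wv)
  attr(draw, "replacement") <- replacement
  draw
}

#' Fit the composite behavioral-space embedding
#'
#' Three planar t-SNE embeddings of the wavelet features, each PCA
#' initialized with a cosine metric and an early-exaggeration phase
#' (exaggeration 12) followed by a main phase: embedding 1 at perplexity 500
#' with final exaggeration 1, embedding 2 at perplexity 250 with
#' exaggeration 3, embedding 3 at perplexity 750 with exaggeration 2. The
#' composite 4-D coordinates are `[e1.x, e1.y, e2.x, e3.y]` (e2.y and e3.x
#' are computed but discarded). When fewer than `3 * max(perplexity)` points
#' are supplied, all perplexities are scaled down proportionally and the
#' factor is recorded.
#'
#' @param features n x 180 wavelet feature matrix (training sample).
#' @param seed RNG seed (initialization is PCA-based and deterministic;
#'   the seed is stored for provenance).
#' @param perplexities the three perplexities (default 500, 250, 750).
#' @param final_exaggerations main-phase exaggeration of each embedding
#'   (default 1, 3, 2).
#' @param early_exaggeration shared early-phase exaggeration (default 12).
#' @param iters c(early, main) gradient-descent iteration counts.
#' @return Object of class `behavior_embedding`: `composite` (n x 4),
#'   `embeddings` (list of three n x 2 matrices), `features` (training
#'   matrix, row-normalized), `params`.
#' @export
fit_behavior_embedding <- function(features, seed = 1,
                                   perplexities = c(500, 250, 750),
                                   final_exaggerations = c(1, 3, 2),
                                   early_exaggeration = 12,
                                   iters = c(250, 500)) {
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop_domain("features must be finite")
  n <- nrow(X)
  scale_factor <- min(1, n / (3 * max(perplexities)))
  perp <- pmax(perplexities * scale_factor, 5)
  ## cosine metric: Euclidean distance on unit-normalized rows is a
  ## monotone transform of cosine distance
  norms <- sqrt(rowSums(X^2))
  Xn <- X / pmax(norms, 1e-12)
  pca <- prcomp(Xn, rank. = 2, center = TRUE, scale. = FALSE)
  init <- pca$x[, 1:2, drop = FALSE]
  init <- init / sd(init[, 1]) * 1e-4   # conventional tight PCA init
  embeddings <- vector("list", 3)
  for (i in 1:3) {
    k <- min(n - 1L, as.integer(ceiling(3 * perp[i])))
    nn <- knn_brute(Xn, Xn, k + 1L)     # self comes back at distance 0
    nn_idx <- nn$index[, -1, drop = FALSE]
    nn_d2 <- nn$dist[, -1, drop = FALSE]^2
    lr <- max(n / early_exaggeration, 50)
    embeddings[[i]] <- tsne_embed(nn_idx, nn_d2, perp[i], init,
                                  early_exaggeration, iters[1],
                                  final_exaggerations[i], iters[2], lr)
  }
  composite <- cbind(e1x = embeddings[[1]][, 1], e1y = embeddings[[1]][, 2],
                     e2x = embeddings[[2]][, 1], e3y = embeddings[[3]][, 2])
  structure(list(composite = composite, embeddings = embeddings,
                 features = Xn,
                 params = list(perplexities = perp,
                               scale_factor = scale_factor,
                               final_exaggerations = final_exaggerations,
                               early_exaggeration = early_exaggeration,
                               iters = iters, seed = seed)),
            class = "behavior_embedding")
}

#' @export
print.behavior_embedding <- function(x, ...) {
  cat(sprintf("<behavior_embedding> %d training frames, perplexities %s\n",
              nrow(x$composite),
              paste(signif(x$params$perplexities, 3), collapse = "/")))
  invisible(x)
}

#' Density clustering of the composite behavioral space
#'
#' DBSCAN over the 4-D composite coordinates. Points in low-density regions
#' form an outlier class (label 0). When `eps` is `NULL` it is tuned
#' automatically by bisection on the number of clusters found, targeting
#' `target_clusters` (6, the number of stereotyped behavioral regions);
#' the sweep is returned for diagnostics. An error with the sweep attached
#' is raised if no eps yields any cluster.
#'
#' @param embedding a [fit_behavior_embedding()] result.
#' @param eps DBSCAN radius, or `NULL` to tune.
#' @param min_samples DBSCAN core-point threshold.
#' @param target_clusters desired cluster count for the eps sweep.
#' @param knn_k neighbors used by the assigner (default 200).
#' @return Object of class `behavior_map`: the embedding plus `labels`
#'   (0 = outlier), `eps`, `min_samples`, `outlier_fraction`, `n_clusters`,
#'   `knn_k`, and `eps_sweep` when tuned.
#' @export
cluster_map <- function(embedding, eps = NULL, min_samples = 20,
                        target_clusters = 6, knn_k = 200) {
  co <- embedding$composite
  sweep_log <- NULL
  if (is.null(eps)) {
    tuned <- tune_eps(co, min_samples, target_clusters)
    eps <- tuned$eps
    sweep_log <- tuned$sweep
  }
  labels <- dbscan_label(co, eps, as.integer(min_samples))
  ncl <- length(setdiff(unique(labels), 0L))
  if (ncl == 0)
    stop_domain("DBSCAN found no clusters at eps = ", signif(eps, 4),
                "; inspect the eps sweep and adjust min_samples")
  structure(c(unclass(embedding),
              list(labels = labels, eps = eps, min_samples = min_samples,
                   n_clusters = ncl,
                   outlier_fraction = mean(labels == 0L),
                   knn_k = as.integer(knn_k), eps_sweep = sweep_log)),
            class = "behavior_map")
}

#' @export
print.behavior_map <- function(x, ...) {
  cat(sprintf("<behavior_map> %d clusters, %.4f%% outliers (eps %.4g, min_samples %d)\n",
              x$n_clusters, 100 * x$outlier_fraction, x$eps, x$min_samples))
  invisible(x)
}

## geometric grid sweep on eps; the cluster count is not monotone in eps
## (too small: everything is noise; too large: one blob), so the sweep picks
## the middle of the plateau achieving the target count
tune_eps <- function(co, min_samples, target_clusters, n_grid = 30) {
  probe <- co[round(seq(1, nrow(co), length.out = min(300, nrow(co)))), ,
              drop = FALSE]
  d <- as.vector(stats::dist(probe))
  lo <- max(quantile(d[d > 0], 0.001), max(d) * 1e-5)
  hi <- max(d) / 2
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  sweep <- data.frame(eps = grid, n_clusters = NA_integer_,
                      outlier_fraction = NA_real_)
  for (i in seq_len(n_grid)) {
    lab <- dbscan_label(co, grid[i], as.integer(min_samples))
    sweep$n_clusters[i] <- length(setdiff(unique(lab), 0L))
    sweep$outlier_fraction[i] <- mean(lab == 0L)
  }
  hits <- which(sweep$n_clusters == target_clusters)
  best <- if (length(hits)) {
    grid[hits[ceiling(length(hits) / 2)]]   # middle of the target plateau
  } else {
    grid[which.min(abs(sweep$n_clusters - target_clusters))]
  }
  list(eps = best, sweep = sweep)
}

#' Assign frames to behavioral clusters
#'
#' Distance-weighted k-nearest-neighbor vote (k = 200 by default) in the
#' 180-dimensional wavelet feature space against the labeled training
#' frames. An exact feature match (distance 0) inherits its neighbor's label
#' directly. Deterministic for a fixed map.
#'
#' @param map a [cluster_map()] result.
#' @param new_features m x 180 feature matrix (raw; normalized internally
#'   to match the map's cosine geometry).
#' @return Integer labels (0 = outlier class).
#' @export
assign_behavior <- function(map, new_features) {
  Q <- as.matrix(new_features)
  if (ncol(Q) != ncol(map$features))
    stop_domain("feature dimension ", ncol(Q), " does not match the map (",
                ncol(map$features), ")")
  Qn <- Q / pmax(sqrt(rowSums(Q^2)), 1e-12)
  k <- min(map$knn_k, nrow(map$features))
  nn <- knn_brute(map$features, Qn, k)
  out <- integer(nrow(Qn))
  classes <- sort(unique(map$labels))
  for (i in seq_len(nrow(Qn))) {
    d <- nn$dist[i, ]; lab <- map$labels[nn$index[i, ]]
    if (d[1] == 0) { out[i] <- lab[1]; next }
    w <- 1 / d
    votes <- vapply(classes, function(cl) sum(w[lab == cl]), numeric(1))
    out[i] <- classes[which.max(votes)]
  }
  out
}

#' Occupancy density of the behavioral plane
#'
#' 2-D histogram of the first embedding's coordinates on a fixed grid,
#' smoothed with a Gaussian filter, with intensities clipped at
#' `saturation` times the maximum (0.8% by default, matching the density
#' rendering convention used for behavioral-space occupancy maps; the
#' clipping level is exposed for sensitivity checks).
#'
#' @param coords n x 2 planar coordinates.
#' @param bins grid resolution per axis.
#' @param bandwidth Gaussian smoothing bandwidth in grid cells.
#' @param saturation clip level as a fraction of the smoothed maximum.
#' @param range_x,range_y optional fixed axis ranges (so maps across
#'   conditions share a grid).
#' @return List with `x`, `y` (bin centers) and `z` (bins x bins density,
#'   clipped).
#' @export
occupancy_density <- function(coords, bins = 100, bandwidth = 2,
                              saturation = 0.008,
                              range_x = range(coords[, 1]),
                              range_y = range(coords[, 2])) {
  bx <- seq(range_x[1], range_x[2], length.out = bins + 1)
  by <- seq(range_y[1], range_y[2], length.out = bins + 1)
  ix <- pmin(pmax(findInterval(coords[, 1], bx, all.inside = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(coords[, 2], by, all.inside = TRUE), 1), bins)
  H <- matrix(0, bins, bins)
  for (i in seq_along(ix)) H[ix[i], iy[i]] <- H[ix[i], iy[i]] + 1
  ## separable Gaussian blur
  half <- ceiling(3 * bandwidth)
  kern <- dnorm(-half:half, sd = bandwidth)
  kern <- kern / sum(kern)
  blur <- function(M) {
    M2 <- apply(M, 2, function(col)
      stats::filter(c(rep(0, half), col, rep(0, half)), kern,
                    sides = 2)[half + seq_along(col)])
    t(apply(t(M2), 2, function(row)
      stats::filter(c(rep(0, half), row, rep(0, half)), kern,
                    sides = 2)[half + seq_along(row)]))
  }
  Z <- blur(H)
  Z[is.na(Z)] <- 0
  cap <- saturation * max(Z)
  Z[Z > cap] <- cap
  list(x = (bx[-1] + bx[-(bins + 1)]) / 2,
       y = (by[-1] + by[-(bins + 1)]) / 2, z = Z)
}

#' Transition matrix between behavioral clusters
#'
#' As [empirical_transitions()] over cluster labels: counts are pooled
#' within condition and never across recording boundaries. Outlier frames
#' (label 0) are dropped and bridged over -- the transition joins the
#' surrounding labeled frames -- while invalid frames (`NA`) break the
#' chain.
#'
#' @param label_seqs list of per-recording cluster-label vectors
#'   (0 = outlier, `NA` = invalid frame).
#' @param n_clusters number of clusters.
#' @param show_threshold,label_threshold thresholds for the exported edge
#'   list (see [export_transition_graph()]).
#' @return List with `trans`, `counts`, `uniform_rows`, `edges`.
#' @export
cluster_transitions <- function(label_seqs, n_clusters,
                                show_threshold = 0.001,
                                label_threshold = 0.01) {
  bridged <- lapply(label_seqs, function(ls) {
    ls <- as.integer(ls)
    ## split at NA (no bridging), drop outliers within each chunk
    chunks <- split(ls, cumsum(is.na(ls)))
    lapply(chunks, function(ch) ch[!is.na(ch) & ch != 0L])
  })
  flat <- unlist(bridged, recursive = FALSE)
  et <- empirical_transitions(flat, n_clusters)
  et$edges <- export_transition_graph(et$trans, show_threshold, label_threshold)
  et
}
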