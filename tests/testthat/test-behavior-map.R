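# Synthetic eigencoefficient series with distinct per-regime spectral
# signatures; used to exercise the wavelet -> embedding -> clustering chain.
regime_ec_series <- function(regime, Tn = 512, fps = 30, seed = 1) {
  set.seed(seed)
  t <- seq_len(Tn) / fps
  base <- matrix(rnorm(Tn * 6, sd = 0.02), Tn, 6)
  f <- c(2, 4, 6, 8, 10, 12)[regime]
  ch <- ((regime - 1) %% 3) + 1
  base[, ch] <- base[, ch] + sin(2 * pi * f * t)
  base[, ch + 3] <- base[, ch + 3] + 0.6 * cos(2 * pi * f * t)
  colnames(base) <- paste0("EC", 1:6)
  base
}

test_that("wavelet features have the documented dimension and spectral peak", {
  ec <- regime_ec_series(1, Tn = 600)
  wf <- wavelet_features(ec)
  expect_equal(ncol(wf), 180)       # 6 channels x 30 scales
  expect_equal(nrow(wf), 600)
  expect_true(all(wf >= 0))
  ## a pure 5 Hz tone peaks at the 5 Hz scale
  t <- seq_len(900) / 30
  tone <- cbind(sin(2 * pi * 5 * t), matrix(0, 900, 5))
  resp <- colMeans(wavelet_features(tone)[200:700, 1:30])
  expect_equal(unname(which.max(resp)), 5L)
  ## zero series gives zero features
  expect_true(all(wavelet_features(matrix(0, 200, 6)) == 0))
  expect_error(wavelet_features(matrix(0, 10, 6)), "short")
  expect_error(wavelet_features(rbind(matrix(1, 100, 6), NA)), "gaps")
})

test_that("speed-weighted sampling follows the 50/10 weighting", {
  ## two frames with weight ratio 9:1
  speeds <- rbind(c(1.8, 0, 0, 0, 0, 0),    # w = 0.9
                  c(0.2, 0, 0, 0, 0, 0))    # w = 0.1
  speeds <- speeds[rep(1:2, 500), ]
  expect_warning(draw <- speed_weighted_sample(speeds, n = 20000, seed = 4),
                 "replacement")
  expect_true(attr(draw, "replacement"))
  frac <- mean(draw %% 2 == 1)   # odd rows carry weight 0.9
  se <- sqrt(0.9 * 0.1 / 20000)
  expect_lt(abs(frac - 0.9), 3 * se)
  ## all-zero speeds fall back to uniform with a warning
  expect_warning(u <- speed_weighted_sample(matrix(0, 100, 6), n = 50,
                                            seed = 1), "uniform")
  expect_equal(length(u), 50)
  ## without replacement when enough frames exist
  d2 <- speed_weighted_sample(speeds, n = 100, seed = 2)
  expect_false(attr(d2, "replacement"))
  expect_equal(anyDuplicated(d2), 0L)
})

test_that("the composite embedding separates well-separated blobs", {
  set.seed(40)
  n <- 450
  lab <- rep(1:3, each = n / 3)
  centers <- matrix(rnorm(3 * 180), 3, 180) * 5
  X <- centers[lab, ] + matrix(rnorm(n * 180, sd = 0.3), n, 180)
  emb <- fit_behavior_embedding(X, seed = 1, iters = c(80, 150))
  expect_equal(ncol(emb$composite), 4)
  co <- emb$composite
  cent <- apply(co, 2, function(v) tapply(v, lab, mean))
  d <- sapply(1:3, function(k) rowSums(sweep(co, 2, cent[k, ])^2))
  expect_gte(mean(max.col(-d) == lab), 0.99)
  ## duplicated points land on near-identical coordinates
  Xd <- rbind(X, X[1, , drop = FALSE])
  embd <- fit_behavior_embedding(Xd, seed = 1, iters = c(80, 150))
  dup <- sqrt(sum((embd$composite[n + 1, ] - embd$composite[1, ])^2))
  span <- max(dist(embd$composite[seq(1, n, by = 9), ]))
  expect_lt(dup, 0.02 * span)
  ## deterministic re-fit
  emb2 <- fit_behavior_embedding(X, seed = 1, iters = c(80, 150))
  expect_identical(emb$composite, emb2$composite)
  ## perplexities are scaled down proportionally for small n
  expect_equal(emb$params$perplexities,
               c(500, 250, 750) * emb$params$scale_factor)
  expect_error(fit_behavior_embedding(X * NA), "finite")
})

fake_embedding <- function(composite, features) {
  structure(list(composite = composite, features = features,
                 params = list(perplexities = c(1, 1, 1))),
            class = "behavior_embedding")
}

test_that("density clustering finds planted blobs and an outlier class", {
  set.seed(41)
  n_per <- 120
  centers <- rbind(c(0, 0, 0, 0), c(8, 0, 0, 0), c(0, 8, 0, 0),
                   c(0, 0, 8, 0), c(0, 0, 0, 8), c(6, 6, 6, 6))
  lab <- rep(1:6, each = n_per)
  co <- centers[lab, ] + matrix(rnorm(6 * n_per * 4, sd = 0.4), ncol = 4)
  F180 <- cbind(co, matrix(0, nrow(co), 176))
  map <- cluster_map(fake_embedding(co, F180), min_samples = 10,
                     target_clusters = 6)
  expect_equal(map$n_clusters, 6)
  core <- map$labels != 0
  expect_gte(adjusted_rand(map$labels[core], lab[core]), 0.99)
  ## all points identical: one cluster, no outliers
  same <- matrix(1, 50, 4)
  map1 <- cluster_map(fake_embedding(same, cbind(same, matrix(0, 50, 176))),
                      eps = 0.5, min_samples = 5)
  expect_equal(map1$n_clusters, 1)
  expect_equal(map1$outlier_fraction, 0)
  ## an isolated far point becomes an outlier
  iso <- rbind(matrix(rnorm(200, sd = 0.3), 50, 4), rep(50, 4))
  mapo <- cluster_map(fake_embedding(iso, cbind(iso, matrix(0, 51, 176))),
                      eps = 2, min_samples = 5)
  expect_equal(mapo$labels[51], 0L)
})

test_that("kNN assignment reproduces training labels and votes by distance", {
  set.seed(42)
  n <- 300
  lab <- rep(1:3, each = n / 3)
  F180 <- matrix(rnorm(n * 180, sd = 0.2), n, 180) +
    (matrix(rnorm(3 * 180), 3, 180) * 4)[lab, ]
  co <- cbind(lab * 5 + rnorm(n, sd = 0.2), rnorm(n, sd = 0.2),
              rnorm(n, sd = 0.2), rnorm(n, sd = 0.2))
  map <- cluster_map(fake_embedding(co, F180 / sqrt(rowSums(F180^2))),
                     eps = 1.5, min_samples = 5, knn_k = 20)
  ## training frames reproduce their own labels (distance-zero match)
  expect_equal(assign_behavior(map, F180), map$labels)
  expect_error(assign_behavior(map, matrix(0, 5, 10)), "dimension")
})

test_that("held-out frames from planted regimes are assigned to their regime", {
  set.seed(43)
  centers <- matrix(rnorm(3 * 180), 3, 180) * 4
  mk <- function(n, sd = 0.2) {
    lab <- rep(1:3, each = n / 3)
    list(lab = lab, X = centers[lab, ] + matrix(rnorm(n * 180, sd = sd),
                                                n, 180))
  }
  train <- mk(300)
  co <- cbind(train$lab * 10 + rnorm(300, sd = 0.3),
              matrix(rnorm(900, sd = 0.3), 300, 3))
  map <- cluster_map(fake_embedding(co, train$X /
                                      sqrt(rowSums(train$X^2))),
                     eps = 2, min_samples = 5, knn_k = 50)
  ## map cluster id per regime (clusters are relabeled by dbscan order)
  test_set <- mk(120)
  pred <- assign_behavior(map, test_set$X)
  regime_to_cluster <- vapply(1:3, function(r) {
    as.integer(names(which.max(table(map$labels[train$lab == r]))))
  }, integer(1))
  expect_gte(mean(pred == regime_to_cluster[test_set$lab]), 0.95)
})

test_that("occupancy density is flat for uniform input and clipped at saturation", {
  set.seed(44)
  u <- cbind(runif(20000), runif(20000))
  d <- occupancy_density(u, bins = 40, bandwidth = 2, saturation = 1)
  inner <- d$z[10:30, 10:30]
  expect_lt(max(inner) / max(mean(inner), 1e-12), 1.6)
  ## clipping: output maximum is at the saturation level
  two <- rbind(matrix(rnorm(4000, 0, 0.05), ncol = 2),
               matrix(rnorm(4000, 1, 0.05), ncol = 2))
  dc <- occupancy_density(two, bins = 50, saturation = 0.008)
  du <- occupancy_density(two, bins = 50, saturation = 1)
  expect_equal(max(dc$z), 0.008 * max(du$z), tolerance = 1e-9)
  ## two blobs give two modes near the planted centers
  cell_near <- function(cx, cy)
    du$z[which.min(abs(du$x - cx)), which.min(abs(du$y - cy))]
  expect_gt(cell_near(0, 0), 0.5 * max(du$z))
  expect_gt(cell_near(1, 1), 0.5 * max(du$z))
  expect_lt(cell_near(0.5, 0.5), 0.2 * max(du$z))
})

test_that("cluster transitions skip outliers, bridge over them, and respect gaps", {
  ## hand count: 1 1 0 2 2 -> bridged 1 1 2 2: 1->1, 1->2, 2->2
  ct <- cluster_transitions(list(c(1, 1, 0, 2, 2)), 2)
  expect_equal(ct$counts, rbind(c(1, 1), c(0, 1)))
  ## NA breaks the chain: no 1->2 transition
  ct2 <- cluster_transitions(list(c(1, 1, NA, 2, 2)), 2)
  expect_equal(ct2$counts, rbind(c(1, 0), c(0, 1)))
  ## recordings never concatenate
  ct3 <- cluster_transitions(list(c(1, 1), c(2, 2)), 2)
  expect_equal(ct3$counts[1, 2], 0)
  expect_equal(rowSums(ct3$trans), c(1, 1))
  ## edge list filtered like the transition graphs
  expect_true(all(ct$edges$prob > 0.001))
})
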