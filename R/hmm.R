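#' Fit a Gaussian hidden Markov model by EM
#'
#' Baum-Welch over a pooled set of observation sequences (a 10-state model
#' with full covariance over the six eigencoefficients plus quirkiness is the
#' package default, mirroring the behavioral-state segmentation this package
#' implements). Initialization is by k-means on the pooled frames with the
#' given seed: state means from the cluster centers, covariances from the
#' within-cluster scatter, initial and transition probabilities from the
#' k-means label sequences. EM stops when the log-likelihood gain drops
#' below `tol` (default 1e-3) or after `max_iter` (default 200) iterations;
#' covariance diagonals are floored at `cov_floor`.
#'
#' @param sequences list of T_i x D numeric matrices (no missing rows; split
#'   recordings at invalid-frame gaps first, see [split_valid_segments()]).
#' @param n_states number of hidden states (default 10).
#' @param covariance_type `"full"` or `"diagonal"`.
#' @param seed RNG seed for initialization.
#' @param max_iter,tol EM stopping rule.
#' @param cov_floor diagonal covariance floor.
#' @return Object of class `ghmm`: `init` (K), `trans` (K x K,
#'   row-stochastic), `means` (K x D), `covs` (D x D x K), `loglik_trace`,
#'   `covariance_type`, `seed`, `feature_names`.
#' @export
fit_ghmm <- function(sequences, n_states = 10, covariance_type = c("full", "diagonal"),
                     seed = 1, max_iter = 200, tol = 1e-3, cov_floor = 1e-6) {
  covariance_type <- match.arg(covariance_type)
  if (!length(sequences)) stop_domain("need at least one sequence")
  sequences <- lapply(sequences, as.matrix)
  if (any(vapply(sequences, function(s) any(!is.finite(s)), logical(1))))
    stop_domain("sequences contain non-finite values; split recordings at ",
                "invalid-frame gaps before fitting (split_valid_segments)")
  K <- as.integer(n_states)
  if (any(vapply(sequences, nrow, integer(1)) < K))
    stop_domain("every sequence must have at least n_states frames")
  D <- ncol(sequences[[1]])
  X <- do.call(rbind, sequences)
  feature_names <- colnames(X) %||% paste0("f", seq_len(D))

  set.seed(seed)
  km <- kmeans(X, centers = K, nstart = 10, iter.max = 100)
  means <- unname(km$centers)
  covs <- array(0, c(D, D, K))
  global_cov <- cov(X) + diag(cov_floor, D)
  for (k in seq_len(K)) {
    Xi <- X[km$cluster == k, , drop = FALSE]
    Ck <- if (nrow(Xi) > D + 1) cov(Xi) else global_cov
    covs[, , k] <- regularize_cov(Ck, covariance_type, cov_floor)
  }
  ## transition/initial estimates from the k-means label sequences
  lens <- vapply(sequences, nrow, integer(1))
  lab_seqs <- split(km$cluster, rep(seq_along(sequences), lens))
  A <- matrix(1, K, K)  # +1 smoothing keeps the chain irreducible at init
  for (ls in lab_seqs)
    for (t in seq_len(length(ls) - 1))
      A[ls[t], ls[t + 1]] <- A[ls[t], ls[t + 1]] + 1
  A <- A / rowSums(A)
  init <- tabulate(vapply(lab_seqs, `[`, integer(1), 1), K) + 0.5
  init <- init / sum(init)

  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    logA <- log(A); logpi <- log(init)
    ld_all <- gaussian_logdens(X, means, covs)
    loglik <- 0
    Nk <- numeric(K); first <- numeric(K)
    xi <- matrix(0, K, K)
    mean_acc <- matrix(0, K, D)
    cov_acc <- array(0, c(D, D, K))
    offset <- 0L
    gammas <- vector("list", length(sequences))
    for (s in seq_along(sequences)) {
      Ti <- lens[s]
      ld <- ld_all[offset + seq_len(Ti), , drop = FALSE]
      fb <- hmm_forward_backward(ld, logpi, logA)
      loglik <- loglik + fb$loglik
      gammas[[s]] <- fb$gamma
      xi <- xi + fb$xi_sum
      first <- first + fb$gamma[1, ]
      offset <- offset + Ti
    }
    G <- do.call(rbind, gammas)
    Nk <- colSums(G)
    means_new <- t(G) %*% X / Nk
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, means_new[k, ])
      Ck <- crossprod(Xc * G[, k], Xc) / Nk[k]
      cov_acc[, , k] <- regularize_cov(Ck, covariance_type, cov_floor)
    }
    A_new <- xi / pmax(rowSums(xi), .Machine$double.eps)
    zero_rows <- rowSums(xi) <= .Machine$double.eps
    A_new[zero_rows, ] <- 1 / K
    init_new <- first / sum(first)

    trace <- c(trace, loglik)
    converged <- iter > 1 && (loglik - trace[iter - 1]) < tol
    means <- unname(as.matrix(means_new)); covs <- cov_acc
    A <- A_new; init <- init_new
    if (converged) break
  }
  structure(list(init = init, trans = A, means = means, covs = covs,
                 loglik_trace = trace, covariance_type = covariance_type,
                 n_states = K, seed = seed, feature_names = feature_names,
                 cov_floor = cov_floor),
            class = "ghmm")
}

regularize_cov <- function(C, covariance_type, floor) {
  C <- (C + t(C)) / 2
  if (covariance_type == "diagonal") C <- diag(diag(C), nrow = nrow(C))
  diag(C) <- pmax(diag(C), floor)
  C
}

## T x K matrix of multivariate normal log densities
gaussian_logdens <- function(X, means, covs) {
  K <- nrow(means); D <- ncol(means)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    ch <- tryCatch(chol(covs[, , k]),
                   error = function(e) chol(covs[, , k] + diag(1e-8, D)))
    Xc <- sweep(X, 2, means[k, ])
    Z <- Xc %*% backsolve(ch, diag(D))   # whiten
    out[, k] <- -0.5 * rowSums(Z^2) - sum(log(diag(ch))) -
      0.5 * D * log(2 * pi)
  }
  out
}

#' @export
print.ghmm <- function(x, ...) {
  cat(sprintf("<ghmm> %d states, %s covariance, %d features (%s)\n",
              x$n_states, x$covariance_type, ncol(x$means),
              paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  EM: %d iterations, final log-likelihood %.2f\n",
              length(x$loglik_trace), tail(x$loglik_trace, 1)))
  invisible(x)
}

#' @export
coef.ghmm <- function(object, ...) {
  list(init = object$init, trans = object$trans, means = object$means,
       covs = object$covs)
}

#' Viterbi decoding of a feature sequence
#'
#' The exact most probable hidden-state path given the fitted model.
#'
#' @param model a fitted [fit_ghmm()] model.
#' @param sequence T x D matrix of observations (D matching the model).
#' @return Integer vector of per-frame state labels in 1..K.
#' @export
decode_states <- function(model, sequence) {
  sequence <- as.matrix(sequence)
  if (ncol(sequence) != ncol(model$means))
    stop_domain("sequence has ", ncol(sequence), " features; model expects ",
                ncol(model$means))
  ld <- gaussian_logdens(sequence, model$means, model$covs)
  hmm_viterbi(ld, log(model$init), log(model$trans))
}

#' Split a feature matrix into contiguous valid segments
#'
#' HMM fitting and decoding need gap-free observations; recordings are split
#' at invalid-frame gaps (rows with any `NA`) into contiguous valid chunks.
#'
#' @param features T x D matrix, `NA` rows marking invalid frames.
#' @param min_length drop chunks shorter than this (default 2).
#' @return List with `segments` (list of matrices) and `rows` (list of the
#'   original row indices of each segment).
#' @export
split_valid_segments <- function(features, min_length = 2L) {
  ok <- complete.cases(as.matrix(features))
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_length)
  rows <- lapply(keep, function(i) starts[i]:ends[i])
  list(segments = lapply(rows, function(ix)
         as.matrix(features)[ix, , drop = FALSE]),
       rows = rows)
}

#' Decode a recording's feature panel into per-frame states
#'
#' Splits at invalid-frame gaps, Viterbi-decodes each contiguous segment,
#' and reassembles a per-frame label vector with `NA` on invalid frames.
#'
#' @param model a [fit_ghmm()] model.
#' @param features T x D feature matrix with `NA` rows for invalid frames.
#' @return Integer vector of length T with states in 1..K or `NA`.
#' @export
decode_recording <- function(model, features) {
  sp <- split_valid_segments(features)
  out <- rep(NA_integer_, nrow(as.matrix(features)))
  for (i in seq_along(sp$segments))
    out[sp$rows[[i]]] <- decode_states(model, sp$segments[[i]])
  out
}

#' Simulate observations from a Gaussian HMM
#'
#' @param object a [fit_ghmm()] model (or a hand-built list with the same
#'   fields).
#' @param nsim number of frames.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return List with `states` (length `nsim`) and `obs` (`nsim` x D).
#' @export
simulate.ghmm <- function(object, nsim = 1000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(object$init); D <- ncol(object$means)
  chols <- lapply(seq_len(K), function(k) chol(object$covs[, , k]))
  states <- integer(nsim)
  states[1] <- sample.int(K, 1, prob = object$init)
  for (t in seq_len(nsim - 1))
    states[t + 1] <- sample.int(K, 1, prob = object$trans[states[t], ])
  Z <- matrix(rnorm(nsim * D), nsim, D)
  obs <- matrix(0, nsim, D)
  for (k in seq_len(K)) {
    ix <- states == k
    if (any(ix))
      obs[ix, ] <- sweep(Z[ix, , drop = FALSE] %*% chols[[k]], 2,
                         object$means[k, ], `+`)
  }
  colnames(obs) <- object$feature_names
  list(states = states, obs = obs)
}

#' Per-condition state usage and fold change
#'
#' Share of frames per state for each condition (rows sum to 100%), plus
#' percentage fold change relative to the declared control.
#'
#' @param conditions character vector, one label per frame.
#' @param states integer state labels per frame (`NA` skipped).
#' @param n_states number of states.
#' @param control_map named character vector of condition -> control.
#' @return List with `usage` and `fold_change` matrices (percent).
#' @export
state_usage <- function(conditions, states, n_states, control_map = character()) {
  usage_table(conditions, states, n_states, control_map)
}

#' Empirical transition matrix from decoded state sequences
#'
#' Transition counts are pooled within a condition but never across
#' recording boundaries; `NA` frames break the chain. Rows are normalized to
#' probabilities; rows with no observed transitions are set uniform and
#' flagged.
#'
#' @param label_seqs list of per-recording label vectors (integer, `NA`
#'   allowed).
#' @param n_states number of states.
#' @return List with `trans` (row-stochastic matrix), `counts`,
#'   `uniform_rows` (logical).
#' @export
empirical_transitions <- function(label_seqs, n_states) {
  K <- as.integer(n_states)
  counts <- matrix(0, K, K)
  for (ls in label_seqs) {
    ls <- as.integer(ls)
    for (t in seq_len(length(ls) - 1L)) {
      a <- ls[t]; b <- ls[t + 1L]
      if (!is.na(a) && !is.na(b)) counts[a, b] <- counts[a, b] + 1
    }
  }
  rs <- rowSums(counts)
  uniform <- rs == 0
  trans <- counts / pmax(rs, 1)
  trans[uniform, ] <- 1 / K
  list(trans = trans, counts = counts, uniform_rows = uniform)
}

#' Filtered edge list of a transition matrix
#'
#' Edges with probability above `show_threshold` are exported; probability
#' labels are attached only above `label_threshold` (mirroring transition
#' graphs that draw edges > 0.001 and print values > 0.01).
#'
#' @param trans row-stochastic matrix.
#' @param show_threshold minimum probability for an edge to appear.
#' @param label_threshold minimum probability for a printed label.
#' @return data.frame with `from`, `to`, `prob`, `labeled`.
#' @export
export_transition_graph <- function(trans, show_threshold = 0.001,
                                    label_threshold = 0.01) {
  K <- nrow(trans)
  idx <- which(trans > show_threshold, arr.ind = TRUE)
  df <- data.frame(from = idx[, 1], to = idx[, 2],
                   prob = trans[idx],
                   labeled = trans[idx] > label_threshold)
  df[order(df$from, df$to), , drop = FALSE]
}

#' Model-selection report over state counts and covariance types
#'
#' Fits candidate models and summarizes each: final log-likelihood, the
#' per-state share of decoded frames, and the count of states used in less
#' than 1% of frames (the over-segmentation symptom that argues against too
#' many states).
#'
#' @param sequences as in [fit_ghmm()].
#' @param n_states_set candidate state counts (default 6, 8, 10, 12, 15).
#' @param covariance_types candidate covariance structures.
#' @param seed RNG seed passed to each fit.
#' @param ... further arguments to [fit_ghmm()].
#' @return data.frame with one row per candidate model (`n_states`,
#'   `covariance_type`, `loglik`, `n_rare_states`, `min_share_pct`) and the
#'   fitted models in `attr(, "models")`.
#' @export
selection_report <- function(sequences, n_states_set = c(6, 8, 10, 12, 15),
                             covariance_types = c("full", "diagonal"),
                             seed = 1, ...) {
  rows <- list(); models <- list()
  for (cv in covariance_types) for (K in n_states_set) {
    fit <- fit_ghmm(sequences, n_states = K, covariance_type = cv,
                    seed = seed, ...)
    states <- unlist(lapply(sequences, function(s) decode_states(fit, s)))
    share <- 100 * tabulate(states, K) / length(states)
    rows[[length(rows) + 1L]] <-
      data.frame(n_states = K, covariance_type = cv,
                 loglik = tail(fit$loglik_trace, 1),
                 n_rare_states = sum(share < 1),
                 min_share_pct = min(share))
    models[[paste(cv, K, sep = "_")]] <- fit
  }
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}

#' Refit-stability protocol
#'
#' Refits the model (a) on the full data under several seeds, (b) on
#' mutually exclusive random splits, and (c) on mutually exclusive
#' condition-balanced splits, then reports the correlation of state means
#' between each replicate and the reference model after optimal state
#' alignment (Hungarian matching on state means).
#'
#' @param sequences as in [fit_ghmm()].
#' @param conditions per-sequence condition labels (for balanced splits).
#' @param n_states,covariance_type,seed model settings.
#' @param n_splits number of exclusive subsets (default 3).
#' @param ... further arguments to [fit_ghmm()].
#' @return data.frame with one row per replicate (`scheme`, `replicate`,
#'   `mean_correlation`) and the models in `attr(, "models")`.
#' @export
stability_protocol <- function(sequences, conditions = NULL, n_states = 10,
                               covariance_type = "full", seed = 1,
                               n_splits = 3, ...) {
  n <- length(sequences)
  if (n < n_splits * 2)
    stop_domain("dataset too small to split into ", n_splits, " subsets")
  if (is.null(conditions)) conditions <- rep("all", n)
  reference <- fit_ghmm(sequences, n_states = n_states,
                        covariance_type = covariance_type, seed = seed, ...)
  models <- list(reference = reference)
  rows <- list()
  add <- function(scheme, rep_i, fit) {
    al <- align_states(reference$means, fit$means)
    r <- cor(as.vector(reference$means),
             as.vector(fit$means[al, , drop = FALSE]))
    rows[[length(rows) + 1L]] <<-
      data.frame(scheme = scheme, replicate = rep_i, mean_correlation = r)
    models[[paste(scheme, rep_i, sep = "_")]] <<- fit
  }
  for (i in seq_len(3))
    add("full_reseed", i, fit_ghmm(sequences, n_states = n_states,
                                   covariance_type = covariance_type,
                                   seed = seed + i, ...))
  set.seed(seed)
  perm <- sample.int(n)
  splits <- split(perm, rep(seq_len(n_splits), length.out = n))
  for (i in seq_len(n_splits))
    add("random_split", i, fit_ghmm(sequences[splits[[i]]],
                                    n_states = n_states,
                                    covariance_type = covariance_type,
                                    seed = seed, ...))
  set.seed(seed + 1000)
  balanced <- vector("list", n_splits)
  for (cond in unique(conditions)) {
    ix <- sample(which(conditions == cond))
    parts <- split(ix, rep(seq_len(n_splits), length.out = length(ix)))
    for (i in seq_len(n_splits))
      balanced[[i]] <- c(balanced[[i]], parts[[i]])
  }
  for (i in seq_len(n_splits))
    add("balanced_split", i, fit_ghmm(sequences[balanced[[i]]],
                                      n_states = n_states,
                                      covariance_type = covariance_type,
                                      seed = seed, ...))
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}

#' Optimal state alignment between two models
#'
#' Hungarian assignment minimizing the total Euclidean distance between
#' state means; used whenever models with arbitrary state labels are
#' compared.
#'
#' @param means_a,means_b K x D state-mean matrices.
#' @return Integer permutation `p` such that `means_b[p, ]` aligns with
#'   `means_a`.
#' @export
align_states <- function(means_a, means_b) {
  K <- nrow(means_a)
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    cost[i, j] <- sqrt(sum((means_a[i, ] - means_b[j, ])^2))
  solve_assignment(cost)
}

## Hungarian algorithm (Kuhn-Munkres with potentials), O(K^3).
## Returns match[i] = column assigned to row i, minimizing total cost.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  J0 <- n + 1L                     # virtual column
  u <- numeric(n); v <- numeric(n + 1)
  p <- integer(n + 1)              # p[j] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      u[p[J0]] <- u[p[J0]] + delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) match[p[j]] <- j
  match
}
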