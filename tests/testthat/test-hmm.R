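make_truth <- function(means, self = 0.95, sd = 1) {
  K <- nrow(means); D <- ncol(means)
  trans <- matrix((1 - self) / (K - 1), K, K); diag(trans) <- self
  covs <- array(0, c(D, D, K))
  for (k in seq_len(K)) covs[, , k] <- diag(sd^2, D)
  structure(list(init = rep(1 / K, K), trans = trans, means = means,
                 covs = covs, n_states = K,
                 feature_names = paste0("f", seq_len(D))),
            class = "ghmm")
}

test_that("EM recovers a well-separated two-state model", {
  truth <- make_truth(rbind(c(-3, -3), c(3, 3)))
  sim <- simulate(truth, nsim = 10000, seed = 31)
  fit <- fit_ghmm(list(sim$obs), n_states = 2, seed = 1)
  al <- align_states(truth$means, fit$means)
  expect_lt(max(abs(fit$means[al, ] - truth$means)), 0.2)
  expect_lt(max(abs(diag(fit$trans)[al] - 0.95)), 0.03)
  ## log-likelihood trace non-decreasing
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  ## determinism under the seed
  fit2 <- fit_ghmm(list(sim$obs), n_states = 2, seed = 1)
  expect_identical(fit$means, fit2$means)
  expect_identical(fit$trans, fit2$trans)
  expect_error(fit_ghmm(list(cbind(c(1, NA), c(2, 3)))), "non-finite")
})

test_that("Viterbi decoding is exact and beats random paths", {
  truth <- make_truth(rbind(c(-6, 0), c(6, 0)), sd = 1)  # 6 sd separation
  sim <- simulate(truth, nsim = 3000, seed = 32)
  dec <- decode_states(truth, sim$obs)
  expect_gte(mean(dec == sim$states), 0.99)
  ## single-state model: constant path
  one <- make_truth(matrix(c(0, 0), 1, 2))
  expect_true(all(decode_states(one, sim$obs) == 1))
  ## path likelihood dominates 1,000 random paths
  path_ll <- function(states, model, obs) {
    ld <- cionaswim:::gaussian_logdens(obs, model$means, model$covs)
    sum(ld[cbind(seq_along(states), states)]) +
      log(model$init[states[1]]) +
      sum(log(model$trans[cbind(states[-length(states)], states[-1])]))
  }
  obs_small <- sim$obs[1:200, ]
  dec_small <- decode_states(truth, obs_small)
  best <- path_ll(dec_small, truth, obs_small)
  set.seed(33)
  for (i in 1:1000) {
    rand_path <- sample.int(2, 200, replace = TRUE)
    expect_gte(best, path_ll(rand_path, truth, obs_small))
  }
  expect_error(decode_states(truth, matrix(0, 5, 3)), "features")
})

test_that("decoding a gappy recording splits at invalid frames", {
  truth <- make_truth(rbind(c(-4, -4), c(4, 4)))
  sim <- simulate(truth, nsim = 300, seed = 34)
  feats <- sim$obs
  feats[c(100:110, 200), ] <- NA
  dec <- decode_recording(truth, feats)
  expect_true(all(is.na(dec[c(100:110, 200)])))
  expect_false(anyNA(dec[1:99]))
  sp <- split_valid_segments(feats)
  expect_equal(length(sp$segments), 3)
  expect_equal(sum(vapply(sp$segments, nrow, integer(1))), 300 - 12)
})

test_that("state usage sums to 100% per condition with hand-counted shares", {
  conds <- c(rep("wt", 6), rep("drug", 4))
  states <- c(1, 1, 2, 2, 3, 3, 1, 1, 1, 1)
  u <- state_usage(conds, states, 3, c(drug = "wt"))
  expect_equal(rowSums(u$usage), c(wt = 100, drug = 100))
  expect_equal(unname(u$usage["wt", ]), c(100 / 3, 100 / 3, 100 / 3))
  expect_equal(unname(u$usage["drug", ]), c(100, 0, 0))
  expect_equal(unname(u$fold_change["drug", 1]), 200)
  ## NA frames are skipped
  u2 <- state_usage(c(conds, "wt"), c(states, NA), 3, c(drug = "wt"))
  expect_equal(u2$usage["wt", ], u$usage["wt", ])
})

test_that("empirical transitions pool within but not across recordings", {
  ## one recording alpha alpha beta beta
  et <- empirical_transitions(list(c(1, 1, 2, 2)), 2)
  expect_equal(et$trans[1, ], c(0.5, 0.5))
  expect_equal(et$trans[2, ], c(0, 1))
  ## the boundary pair of two recordings contributes nothing
  et2 <- empirical_transitions(list(c(1, 1), c(2, 2)), 2)
  expect_equal(et2$counts[1, 2], 0)
  ## rows always sum to 1; unobserved rows are uniform and flagged
  et3 <- empirical_transitions(list(c(1, 1, 1)), 3)
  expect_equal(rowSums(et3$trans), rep(1, 3))
  expect_identical(et3$uniform_rows, c(FALSE, TRUE, TRUE))
  ## NA breaks the chain
  et4 <- empirical_transitions(list(c(1, NA, 2)), 2)
  expect_equal(sum(et4$counts), 0)
})

test_that("transition graph export filters and labels by the documented thresholds", {
  P <- rbind(c(0.9945, 0.005, 0.0005),
             c(0.001, 0.499, 0.5),
             c(0, 0.6, 0.4))
  g <- export_transition_graph(P)
  expect_false(any(g$from == 1 & g$to == 3))     # 0.0005 omitted
  row_shown <- g[g$from == 1 & g$to == 2, ]
  expect_false(row_shown$labeled)                # 0.005 shown, unlabeled
  expect_true(g[g$from == 2 & g$to == 3, "labeled"])  # 0.5 labeled
  expect_false(any(g$from == 2 & g$to == 1))     # exactly at threshold: omitted
})

test_that("model selection flags over-segmentation and is reproducible", {
  ## three common states plus one visited well under 1% of the time: fits
  ## with excess states should report at least one rarely-used state
  truth <- make_truth(rbind(c(-5, -5), c(0, 5), c(5, -5), c(8, 8)),
                      self = 0.9)
  truth$trans[, 4] <- 0.0025
  truth$trans[4, ] <- c(0.4, 0.3, 0.3, 0)
  truth$trans <- truth$trans / rowSums(truth$trans)
  truth$init <- c(1 / 3, 1 / 3, 1 / 3, 0)
  sim <- simulate(truth, nsim = 4000, seed = 35)
  seqs <- list(sim$obs[1:2000, ], sim$obs[2001:4000, ])
  rep1 <- selection_report(seqs, n_states_set = c(2, 3, 6),
                           covariance_types = "full", seed = 2, max_iter = 50)
  expect_gte(rep1$n_rare_states[rep1$n_states == 6], 1)
  expect_true(all(diff(rep1$loglik) > -1e-6))    # more states fit no worse
  rep2 <- selection_report(seqs, n_states_set = c(2, 3, 6),
                           covariance_types = "full", seed = 2, max_iter = 50)
  expect_equal(rep1$loglik, rep2$loglik)
})

test_that("refit stability: replicate state means correlate after alignment", {
  truth <- make_truth(rbind(c(-6, -6), c(-6, 6), c(6, -6), c(6, 6)),
                      self = 0.9)
  set.seed(36)
  seqs <- lapply(1:12, function(i) simulate(truth, nsim = 600,
                                            seed = 400 + i)$obs)
  conds <- rep(c("wt", "drug"), 6)
  st <- stability_protocol(seqs, conds, n_states = 4, seed = 3,
                           max_iter = 40)
  expect_true(all(st$mean_correlation >= 0.9))
  expect_setequal(unique(st$scheme),
                  c("full_reseed", "random_split", "balanced_split"))
  expect_equal(nrow(st), 9)
})

test_that("Hungarian alignment matches brute-force optimal assignment", {
  set.seed(37)
  for (r in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n)
    best <- min(vapply(all_perms(seq_len(n)),
                       function(p) sum(cost[cbind(seq_len(n), p)]),
                       numeric(1)))
    got <- sum(cost[cbind(seq_len(n), cionaswim:::solve_assignment(cost))])
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("simulating from a model with a fixed seed is reproducible", {
  truth <- make_truth(rbind(c(-2, 0), c(2, 0)))
  a <- simulate(truth, nsim = 100, seed = 9)
  b <- simulate(truth, nsim = 100, seed = 9)
  expect_identical(a$states, b$states)
  expect_identical(a$obs, b$obs)
})
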