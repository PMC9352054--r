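# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force multidimensional matrix profile: O(T^2) pairwise z-normalized
# distances per channel, averaged, with the trivial-match exclusion zone.
mp_oracle <- function(x, m, excl = ceiling(m / 2), var_floor = 1e-8) {
  x <- as.matrix(x)
  Tn <- nrow(x); C <- ncol(x); n <- Tn - m + 1
  total <- matrix(0, n, n)
  for (c in seq_len(C)) {
    W <- t(vapply(seq_len(n), function(i) x[i:(i + m - 1), c], numeric(m)))
    mu <- rowMeans(W)
    s <- sqrt(pmax(rowMeans(W^2) - mu^2, var_floor))
    Z <- (W - mu) / s
    total <- total + as.matrix(dist(Z))
  }
  total <- total / C
  for (i in seq_len(n)) {
    lo <- max(1, i - excl + 1); hi <- min(n, i + excl - 1)
    total[i, lo:hi] <- Inf
  }
  apply(total, 1, min)
}

# Exact Mann-Whitney null by enumeration of all rank assignments (no ties).
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ranks <- seq_len(n1 + n2)
  cmb <- utils::combn(n1 + n2, n1)
  Us <- apply(cmb, 2, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  list(U = U_obs,
       p_two = min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs))),
       p_less = mean(Us <= U_obs),
       p_greater = mean(Us >= U_obs))
}

# Exact Wilcoxon signed-rank null by enumeration of all sign patterns
# (zero differences dropped, no ties among |d|).
signed_rank_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  list(V = V_obs,
       p_two = min(1, 2 * min(mean(Vs <= V_obs), mean(Vs >= V_obs))),
       p_less = mean(Vs <= V_obs),
       p_greater = mean(Vs >= V_obs))
}

# Principal angles (degrees) between the column spans of A and B.
subspace_angles <- function(A, B) {
  QA <- qr.Q(qr(A)); QB <- qr.Q(qr(B))
  acos(pmin(svd(crossprod(QA, QB))$d, 1)) * 180 / pi
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# All permutations of a small vector (for assignment brute force).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# A straight synthetic skeleton frame along a given direction.
straight_frame <- function(angle = 0, spacing = 2.4, origin = c(100, 100)) {
  s <- (0:48) * spacing
  cbind(origin[1] + s * cos(angle), origin[2] + s * sin(angle))
}

rigid_transform <- function(xy, angle, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  sweep(xy %*% t(R), 2, shift, `+`)
}
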