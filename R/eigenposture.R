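#' Covariance matrix of curvature profiles
#'
#' Sample covariance (denominator n-1) of the 49 per-point curvature values
#' over frames, after dropping rows with missing values. The smooth structure
#' of this matrix reflects the strong coupling of neighboring skeleton points
#' and motivates the eigenposture decomposition.
#'
#' @param curv T x 49 curvature matrix, or a list of such matrices pooled
#'   over recordings.
#' @return Symmetric 49 x 49 covariance matrix.
#' @export
curvature_covariance <- function(curv) {
  if (is.list(curv)) curv <- do.call(rbind, curv)
  curv <- curv[complete.cases(curv), , drop = FALSE]
  if (nrow(curv) < 2)
    stop_domain("need at least 2 complete curvature frames for a covariance")
  C <- cov(curv)
  (C + t(C)) / 2
}

#' Eigenposture basis ("eigencionas") of a curvature covariance
#'
#' Eigendecomposition (PCA) of the 49 x 49 curvature covariance. Eigenpairs
#' are sorted by descending eigenvalue; each eigenvector's sign is fixed so
#' its largest-magnitude entry is positive, making the basis reproducible.
#' Six modes suffice to capture ~97% of wild-type curvature variance, so
#' `k = 6` is the default.
#'
#' @param C symmetric 49 x 49 covariance matrix, or a curvature matrix /
#'   list of curvature matrices (the covariance is then computed first, and
#'   the mean curvature over the training frames is retained for centering).
#' @param k number of retained modes (default 6).
#' @param center logical; subtract the training mean curvature when
#'   projecting (default `TRUE`). Only available when `C` is curvature data.
#' @param input `"auto"` treats a symmetric 49 x 49 matrix as a covariance
#'   and anything else as curvature data; `"covariance"` or `"curvature"`
#'   force the interpretation (a non-symmetric forced covariance is an
#'   error).
#' @return Object of class `eigencionas`: list with `mean_curvature`,
#'   `vectors` (k x 49, rows unit norm), `values` (k), `variance_fraction`
#'   (k, of the all-49 total), `k`, `center`.
#' @export
eigencionas <- function(C, k = 6, center = TRUE,
                        input = c("auto", "covariance", "curvature")) {
  input <- match.arg(input)
  mean_curv <- rep(0, N_POINTS)
  is_cov <- !is.list(C) && nrow(C) == N_POINTS && ncol(C) == N_POINTS &&
    isSymmetric(unname(as.matrix(C)), tol = 1e-8)
  if (input == "covariance" && !is_cov)
    stop_domain("covariance matrix must be symmetric 49 x 49")
  if (input == "curvature") is_cov <- FALSE
  if (!is_cov) {
    dat <- if (is.list(C)) do.call(rbind, C) else C
    if (ncol(dat) != N_POINTS)
      stop_domain("curvature data must have ", N_POINTS, " columns")
    dat <- dat[complete.cases(dat), , drop = FALSE]
    mean_curv <- colMeans(dat)
    C <- curvature_covariance(dat)
  }
  C <- unname(as.matrix(C))
  if (!isSymmetric(C, tol = 1e-8))
    stop_domain("covariance matrix must be symmetric")
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- t(e$vectors)                       # rows are eigenvectors
  for (i in seq_len(nrow(vecs))) {
    j <- which.max(abs(vecs[i, ]))
    if (vecs[i, j] < 0) vecs[i, ] <- -vecs[i, ]
  }
  total <- sum(vals)
  structure(list(mean_curvature = if (center) mean_curv else rep(0, N_POINTS),
                 vectors = vecs[seq_len(k), , drop = FALSE],
                 values = vals[seq_len(k)],
                 variance_fraction = vals[seq_len(k)] / total,
                 all_values = vals, k = as.integer(k), center = center),
            class = "eigencionas")
}

#' @export
print.eigencionas <- function(x, ...) {
  cat(sprintf("<eigencionas> %d modes retained of %d\n", x$k, N_POINTS))
  cat(sprintf("  variance explained: %s (cum %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = " "),
              100 * sum(x$variance_fraction)))
  invisible(x)
}

#' Project curvature frames onto an eigenposture basis
#'
#' `EC = V (kappa - mean_curvature)` per frame: the eigencoefficients
#' EC1..ECk are the posture's coordinates in eigenshape space.
#'
#' @param curv T x 49 curvature matrix (or a single 49-vector).
#' @param basis an [eigencionas()] basis.
#' @return T x k matrix of eigencoefficients (columns `EC1..ECk`).
#' @export
project_curvature <- function(curv, basis) {
  if (is.null(dim(curv))) curv <- matrix(curv, nrow = 1)
  if (ncol(curv) != N_POINTS)
    stop_domain("curvature frames must have ", N_POINTS, " points")
  ec <- sweep(curv, 2, basis$mean_curvature) %*% t(basis$vectors)
  colnames(ec) <- paste0("EC", seq_len(basis$k))
  ec
}

#' Reconstruct curvature from eigencoefficients
#'
#' `kappa_hat = mean_curvature + V' EC`; the residual to the original
#' curvature equals the discarded eigenvalue mass on the training sample.
#'
#' @param ec T x k eigencoefficient matrix.
#' @param basis an [eigencionas()] basis.
#' @return T x 49 reconstructed curvature matrix.
#' @export
reconstruct_curvature <- function(ec, basis) {
  if (is.null(dim(ec))) ec <- matrix(ec, nrow = 1)
  sweep(ec %*% basis$vectors, 2, basis$mean_curvature, `+`)
}

#' Serialize / load an eigenposture basis
#'
#' The basis is written as a CSV of 49-column rows (mean curvature first,
#' then the k eigenvectors) plus a JSON sidecar holding eigenvalues,
#' variance fractions and the centering flag.
#'
#' @param basis an [eigencionas()] basis.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `path` invisibly; `read_eigencionas()` returns the basis.
#' @export
write_eigencionas <- function(basis, path) {
  m <- rbind(basis$mean_curvature, basis$vectors)
  rownames(m) <- c("mean", paste0("eigenvector", seq_len(basis$k)))
  write.csv(signif(m, 12), path, row.names = TRUE)
  side <- list(values = basis$values,
               variance_fraction = basis$variance_fraction,
               all_values = basis$all_values, k = basis$k,
               center = basis$center)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eigencionas
#' @param path CSV path previously written by `write_eigencionas()`.
#' @export
read_eigencionas <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(mean_curvature = unname(m[1, ]),
                 vectors = unname(m[-1, , drop = FALSE]),
                 values = side$values,
                 variance_fraction = side$variance_fraction,
                 all_values = side$all_values, k = as.integer(side$k),
                 center = side$center),
            class = "eigencionas")
}
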