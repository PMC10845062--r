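#' Nearest correlation matrix by alternating projections
#'
#' Higham's alternating-projections algorithm with Dykstra correction:
#' repeatedly project onto the cone of positive semidefinite matrices (eigen
#' decomposition, negative eigenvalues floored at zero) and onto the affine
#' set of unit-diagonal symmetric matrices, until the iterates stabilize.
#' Used to make simulated population connectomes valid covariance inputs for
#' time-series generation.
#'
#' @param m symmetric matrix with unit diagonal (approximately a correlation
#'   matrix)
#' @param tol convergence tolerance on the max absolute change per sweep
#' @param max_iter iteration cap
#' @return symmetric unit-diagonal matrix with minimum eigenvalue
#'   >= `-1e-12`; already-PSD inputs are returned (numerically) unchanged.
#' @export
nearest_correlation <- function(m, tol = 1e-10, max_iter = 200L) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("input must be a symmetric square matrix", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  y <- m
  ds <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(max_iter)) {
    r <- y - ds
    e <- eigen(r, symmetric = TRUE)
    x <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    x <- (x + t(x)) / 2
    ds <- x - r
    y_new <- x
    diag(y_new) <- 1
    delta <- max(abs(y_new - y))
    y <- y_new
    if (delta < tol) break
  }
  # final safeguard: floor tiny negative eigenvalues left by the diagonal
  # restoration, then renormalize to unit diagonal
  e <- eigen(y, symmetric = TRUE)
  if (min(e$values) < -1e-12) {
    x <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    d <- sqrt(pmax(diag(x), .Machine$double.eps))
    y <- x / tcrossprod(d)
    y <- (y + t(y)) / 2
    diag(y) <- 1
  }
  y
}
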