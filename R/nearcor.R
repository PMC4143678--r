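#' Nearest correlation matrix by alternating projections
#'
#' Finds the correlation matrix (symmetric, unit diagonal, positive
#' semidefinite) closest in Frobenius norm to a symmetric input, by Higham's
#' alternating-projections algorithm with Dykstra's correction. The two sets
#' projected onto are the PSD cone (eigenvalue clipping at zero) and the
#' unit-diagonal affine set; the correction term makes the iteration converge
#' to the true nearest point of the intersection rather than merely a point in
#' it. Empirical kinship matrices, which need not be positive semidefinite,
#' are repaired this way before inversion.
#'
#' @param M Symmetric numeric matrix.
#' @param tol Convergence tolerance on the successive-iterate max-norm change
#'   (default 1e-8); the returned matrix has smallest eigenvalue >= -tol.
#' @param max_iter Iteration cap (default 500).
#' @return Symmetric matrix with exact unit diagonal.
#' @export
#' @examples
#' A <- matrix(c(1, 0.9, 0.6, 0.9, 1, 0.9, 0.6, 0.9, 1), 3, 3)
#' A[1, 3] <- A[3, 1] <- -0.5   # indefinite
#' C <- nearest_correlation(A)
#' min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8
nearest_correlation <- function(M, tol = 1e-8, max_iter = 500L) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8)
    stop("input must be a symmetric square matrix")
  M <- (M + t(M)) / 2
  dn <- dimnames(M)
  n <- nrow(M)
  dS <- matrix(0, n, n)
  Y <- M
  for (it in seq_len(max_iter)) {
    Rk <- Y - dS
    # project onto the PSD cone
    eg <- eigen(Rk, symmetric = TRUE)
    pos <- pmax(eg$values, 0)
    X <- eg$vectors %*% (pos * t(eg$vectors))
    X <- (X + t(X)) / 2
    dS <- X - Rk
    Yold <- Y
    Y <- X
    diag(Y) <- 1
    delta <- max(abs(Y - Yold), abs(Y - X))
    if (delta < tol) {
      dimnames(Y) <- dn
      return(Y)
    }
  }
  stop("nearest_correlation did not converge in ", max_iter,
       " iterations (last change ", format(delta, digits = 3), ")")
}
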