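# Small linear-algebra helpers shared by the estimation and robust modules.
# vech ordering is column-major over the lower triangle (including the
# diagonal) throughout the package.

#' Half-vectorization of a symmetric matrix
#'
#' Stacks the lower triangle (including the diagonal) of a square matrix
#' column by column. This ordering is the package-wide convention for the
#' moment vector, the model Jacobian and the asymptotic weight matrices.
#'
#' @param M a square numeric matrix.
#' @return numeric vector of length \code{p(p+1)/2}.
#' @export
vech <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  M[lower.tri(M, diag = TRUE)]
}

# (row, col) indices of the vech elements, in vech order
vechIndices <- function(p) {
  which(lower.tri(matrix(0L, p, p), diag = TRUE), arr.ind = TRUE)
}

#' Duplication matrix
#'
#' The \code{p^2 x p(p+1)/2} matrix \code{D} with \code{vec(M) = D vech(M)}
#' for symmetric \code{M}, under the package's column-major lower-triangle
#' vech ordering.
#'
#' @param p matrix order.
#' @return a dense 0/1 matrix.
#' @export
duplicationMatrix <- function(p) {
  idx <- vechIndices(p)
  pstar <- nrow(idx)
  D <- matrix(0, p * p, pstar)
  for (k in seq_len(pstar)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    D[(j - 1L) * p + i, k] <- 1
    D[(i - 1L) * p + j, k] <- 1
  }
  D
}

symmetrize <- function(M) (M + t(M)) / 2

# Cholesky-based positive-definiteness probe
isPositiveDefinite <- function(M, tol = 0) {
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) return(FALSE)
  ev <- tryCatch(chol(M), error = function(e) NULL)
  !is.null(ev)
}

# log|M| via Cholesky; error for non-PD input
logDetPD <- function(M) {
  ch <- chol(M)
  2 * sum(log(diag(ch)))
}

# normal-theory weight matrix W = 0.5 D'(Sigma^-1 (x) Sigma^-1) D
normalTheoryWeight <- function(Sigma) {
  p <- nrow(Sigma)
  Sinv <- chol2inv(chol(Sigma))
  D <- duplicationMatrix(p)
  0.5 * crossprod(D, kronecker(Sinv, Sinv) %*% D)
}
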