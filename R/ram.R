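# RAM (reticular action model) internals. Variables are ordered observed
# first, then latents; A holds directed paths (A[target, source]), S holds
# variances/covariances of exogenous terms and residuals, and the filter
# selects the observed block. Sigma(theta) = F (I-A)^-1 S (I-A)^-T F'.

ramSkeleton <- function(spec) {
  pt <- spec@ptable
  vars <- c(spec@observed, spec@latents)
  t <- length(vars)
  A <- matrix(0, t, t, dimnames = list(vars, vars))
  S <- matrix(0, t, t, dimnames = list(vars, vars))
  Aid <- matrix(0L, t, t)
  Sid <- matrix(0L, t, t)
  for (k in seq_len(nrow(pt))) {
    r <- pt[k, ]
    i <- match(r$row, vars); j <- match(r$col, vars)
    if (r$mat == "A") {
      if (r$free) Aid[i, j] <- r$id else A[i, j] <- r$value
    } else {
      if (r$free) { Sid[i, j] <- r$id; Sid[j, i] <- r$id }
      else { S[i, j] <- r$value; S[j, i] <- r$value }
    }
  }
  list(vars = vars, p = length(spec@observed), t = t,
       A0 = A, S0 = S, Aid = Aid, Sid = Sid,
       q = countFreeParameters(spec))
}

ramMatrices <- function(skel, theta) {
  A <- skel$A0; S <- skel$S0
  if (skel$q) {
    freeA <- skel$Aid > 0L
    A[freeA] <- theta[skel$Aid[freeA]]
    freeS <- skel$Sid > 0L
    S[freeS] <- theta[skel$Sid[freeS]]
  }
  list(A = A, S = S)
}

# implied covariance over ALL variables (observed + latent)
ramSigmaAll <- function(skel, theta) {
  m <- ramMatrices(skel, theta)
  ImA <- diag(skel$t) - m$A
  B <- tryCatch(solve(ImA), error = function(e) {
    stop("singular (I - A): non-recursive or degenerate model", call. = FALSE)
  })
  sigmaAll <- B %*% m$S %*% t(B)
  list(sigmaAll = symmetrize(sigmaAll), B = B, A = m$A, S = m$S)
}

#' Model-implied covariance matrix
#'
#' Evaluates \code{Sigma(theta) = F (I-A)^-1 S (I-A)^-T F'} for a parameter
#' vector, where F filters the observed block of the RAM system.
#'
#' @param spec a [ModelSpec-class].
#' @param theta numeric vector of free-parameter values (length
#'   \code{countFreeParameters(spec)}).
#' @return the p x p implied covariance matrix of the observed variables.
#' @export
impliedCov <- function(spec, theta) {
  skel <- ramSkeleton(spec)
  if (length(theta) != skel$q) stop("theta has wrong length", call. = FALSE)
  ramSigmaAll(skel, theta)$sigmaAll[seq_len(skel$p), seq_len(skel$p), drop = FALSE]
}

# per-parameter derivative structure, precomputed once per skeleton:
# list of (mat, i, j) for each free id (possibly several slots per id)
ramDerivSlots <- function(skel) {
  slots <- vector("list", skel$q)
  for (k in seq_len(skel$q)) slots[[k]] <- list(A = NULL, S = NULL)
  idxA <- which(skel$Aid > 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(idxA))) {
    k <- skel$Aid[idxA[r, 1], idxA[r, 2]]
    slots[[k]]$A <- rbind(slots[[k]]$A, idxA[r, , drop = FALSE])
  }
  # lower triangle incl diagonal only: one slot per symmetric pair
  idxS <- which(skel$Sid > 0L & row(skel$Sid) >= col(skel$Sid), arr.ind = TRUE)
  for (r in seq_len(nrow(idxS))) {
    k <- skel$Sid[idxS[r, 1], idxS[r, 2]]
    slots[[k]]$S <- rbind(slots[[k]]$S, idxS[r, , drop = FALSE])
  }
  slots
}

# gradient of F_ML wrt theta, and optionally the Jacobian d vech(Sigma)/d theta
ramDifferentials <- function(skel, slots, theta, Sobs = NULL, jacobian = FALSE) {
  sa <- ramSigmaAll(skel, theta)
  p <- skel$p
  Sigma <- sa$sigmaAll[seq_len(p), seq_len(p), drop = FALSE]
  B <- sa$B
  P <- B[seq_len(p), , drop = FALSE]              # F B  (p x t)
  Q <- (sa$S %*% t(B))[, seq_len(p), drop = FALSE] # S B' F'  (t x p)
  BQ <- B %*% Q                                    # B S B' F' (t x p)

  grad <- NULL; M <- NULL
  if (!is.null(Sobs)) {
    Sinv <- chol2inv(chol(Sigma))
    M <- Sinv - Sinv %*% Sobs %*% Sinv
  }
  J <- if (jacobian) matrix(0, p * (p + 1) / 2, skel$q) else NULL
  lowIdx <- if (jacobian) lower.tri(Sigma, diag = TRUE) else NULL
  if (!is.null(Sobs)) grad <- numeric(skel$q)

  for (k in seq_len(skel$q)) {
    dS <- matrix(0, p, p)
    sl <- slots[[k]]
    if (!is.null(sl$A)) for (r in seq_len(nrow(sl$A))) {
      i <- sl$A[r, 1]; j <- sl$A[r, 2]
      C <- P[, i] %o% BQ[j, ]               # F B E_ij B S B' F'
      dS <- dS + C + t(C)
    }
    if (!is.null(sl$S)) for (r in seq_len(nrow(sl$S))) {
      i <- sl$S[r, 1]; j <- sl$S[r, 2]
      C <- P[, i] %o% P[, j]
      dS <- dS + if (i == j) C else C + t(C)
    }
    if (!is.null(grad)) grad[k] <- sum(M * dS)
    if (jacobian) J[, k] <- dS[lowIdx]
  }
  list(sigma = Sigma, grad = grad, jacobian = J, sigmaAll = sa$sigmaAll,
       A = sa$A, S = sa$S, B = B)
}

#' Jacobian of the implied moments
#'
#' Derivative of \code{vech(Sigma(theta))} with respect to the free
#' parameters, in the package's column-major lower-triangle vech order.
#'
#' @param spec a [ModelSpec-class].
#' @param theta free-parameter vector.
#' @return a \code{p(p+1)/2 x q} matrix.
#' @export
semJacobian <- function(spec, theta) {
  skel <- ramSkeleton(spec)
  slots <- ramDerivSlots(skel)
  ramDifferentials(skel, slots, theta, jacobian = TRUE)$jacobian
}
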