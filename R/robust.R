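# Distribution-robust statistics from raw data: asymptotic fourth-moment
# matrix, Satorra-Bentler scaling, sandwich standard errors, robust indices.

#' Asymptotic covariance matrix of the sample covariances
#'
#' Distribution-free (fourth-moment) estimate of the asymptotic covariance
#' of \code{sqrt(n) vech(S)}: element \code{(ij, kl)} is the biased (1/n)
#' sample estimate of \code{Cov(s_ij, s_kl)} built from centered fourth
#' moments.
#'
#' @param raw n x p numeric matrix or data.frame of raw scores
#'   (complete cases).
#' @return symmetric \code{p(p+1)/2} square matrix.
#' @export
adfGamma <- function(raw) {
  X <- as.matrix(raw)
  if (anyNA(X)) stop("raw data must be complete cases", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  pstar <- p * (p + 1) / 2
  if (n <= pstar) stop(sprintf("n = %d too small for p* = %d fourth-moment elements", n, pstar),
                       call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  idx <- vechIndices(p)
  Y <- Xc[, idx[, 1], drop = FALSE] * Xc[, idx[, 2], drop = FALSE]  # n x p*
  Yc <- sweep(Y, 2, colMeans(Y))
  symmetrize(crossprod(Yc) / n)
}

# robust workspace: everything the SB scaling and sandwich SEs need
robustWorkspace <- function(fit, gamma) {
  skel <- ramSkeleton(fit@spec)
  slots <- ramDerivSlots(skel)
  delta <- ramDifferentials(skel, slots, fit@theta, jacobian = TRUE)$jacobian
  W <- normalTheoryWeight(fit@sigma)
  WD <- W %*% delta
  DWD <- symmetrize(crossprod(delta, WD))
  DWDinv <- chol2inv(chol(DWD))
  U <- W - WD %*% DWDinv %*% t(WD)
  list(gamma = gamma, w = W, delta = delta, u = symmetrize(U),
       dwdInv = DWDinv, df = fit@df)
}

#' Satorra-Bentler scaled chi-square
#'
#' Computes the scaling factor \code{c = tr(U Gamma) / df} with the residual
#' weight \code{U = W - W Delta (Delta' W Delta)^-1 Delta' W}, and the scaled
#' statistic \code{T_SB = T_ML / c}. Under normal-theory fourth moments
#' (\code{Gamma = W^-1}) the factor is exactly 1.
#'
#' @param fit a converged [SemFit-class].
#' @param gamma fourth-moment matrix from [adfGamma()] (mutually exclusive
#'   with \code{raw}).
#' @param raw raw score table from which to compute \code{gamma}; columns are
#'   matched to the model's observed variables.
#' @return list with \code{t_sb}, \code{c}, \code{t_ml}, \code{df} and the
#'   workspace matrices (\code{gamma, w, delta, u}).
#' @export
satorraBentler <- function(fit, gamma = NULL, raw = NULL) {
  if (!fit@converged) stop("Satorra-Bentler scaling requires a converged fit", call. = FALSE)
  if (is.null(gamma)) {
    if (is.null(raw)) stop("supply gamma or raw", call. = FALSE)
    raw <- as.matrix(raw)[, fit@spec@observed, drop = FALSE]
    gamma <- adfGamma(raw)
  }
  ws <- robustWorkspace(fit, gamma)
  if (ws$df == 0) stop("scaling is undefined for a saturated model (df = 0)", call. = FALSE)
  cfac <- sum(ws$u * t(ws$gamma)) / ws$df   # tr(U Gamma), both symmetric
  if (cfac <= 0) stop("numerical degeneracy: nonpositive scaling factor", call. = FALSE)
  c(list(t_sb = fit@tml / cfac, c = cfac, t_ml = fit@tml, df = ws$df), ws)
}

#' Sandwich robust standard errors
#'
#' \code{(Delta' W Delta)^-1 Delta' W Gamma W Delta (Delta' W Delta)^-1 /
#' (n - 1)}, diagonal square-rooted. Collapses to the normal-theory standard
#' errors when \code{Gamma} equals the normal-theory \code{W^-1}.
#'
#' @param fit a converged [SemFit-class].
#' @param gamma fourth-moment matrix (or supply \code{raw}).
#' @param raw raw score table.
#' @return named vector of robust standard errors, one per free parameter.
#' @export
robustSE <- function(fit, gamma = NULL, raw = NULL) {
  if (!fit@converged) stop("robust standard errors require a converged fit", call. = FALSE)
  if (is.null(gamma)) {
    if (is.null(raw)) stop("supply gamma or raw", call. = FALSE)
    raw <- as.matrix(raw)[, fit@spec@observed, drop = FALSE]
    gamma <- adfGamma(raw)
  }
  ws <- robustWorkspace(fit, gamma)
  bread <- ws$dwdInv %*% crossprod(ws$delta, ws$w)
  acov <- bread %*% gamma %*% t(bread) / (fit@moments@n - 1)
  stats::setNames(sqrt(pmax(diag(acov), 0)), names(fit@theta))
}

#' Robust (scaled) fit indices
#'
#' Applies the CFI and RMSEA formulas to Satorra-Bentler scaled statistics:
#' the hypothesized model and the independence baseline are both scaled
#' against the same fourth-moment matrix.
#'
#' @param fit a converged [SemFit-class].
#' @param raw raw score table (columns matched to the model variables).
#' @return named vector: \code{chisq.scaled, df, c, baseline.chisq.scaled,
#'   baseline.df, baseline.c, cfi.robust, rmsea.robust, rel.chisq.scaled}.
#' @export
robustFitIndices <- function(fit, raw) {
  raw <- as.matrix(raw)[, fit@spec@observed, drop = FALSE]
  gamma <- adfGamma(raw)
  sb <- satorraBentler(fit, gamma = gamma)

  # baseline: diagonal model, scaled with the same Gamma
  b <- baselineFit(fit@moments)
  p <- length(fit@spec@observed)
  pstar <- p * (p + 1) / 2
  Wb <- normalTheoryWeight(b$sigma)
  dIdx <- which(vechIndices(p)[, 1] == vechIndices(p)[, 2])
  deltaB <- matrix(0, pstar, p)
  for (k in seq_len(p)) deltaB[dIdx[k], k] <- 1
  WDb <- Wb %*% deltaB
  Ub <- Wb - WDb %*% chol2inv(chol(symmetrize(crossprod(deltaB, WDb)))) %*% t(WDb)
  cB <- sum(Ub * t(gamma)) / b$df
  tbScaled <- b$tml / cB

  n <- fit@moments@n
  c(chisq.scaled = sb$t_sb, df = sb$df, c = sb$c,
    baseline.chisq.scaled = tbScaled, baseline.df = b$df, baseline.c = cB,
    cfi.robust = cfi(sb$t_sb, sb$df, tbScaled, b$df),
    rmsea.robust = rmsea(sb$t_sb, sb$df, n),
    rel.chisq.scaled = relativeChiSquare(sb$t_sb, sb$df))
}
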