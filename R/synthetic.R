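# Non-normal multivariate generation: Fleishman cubic margins combined
# through Vale-Maurelli intermediate correlations.

#' Fleishman polynomial coefficients
#'
#' Finds \code{(a, b, c, d)} such that \code{Y = a + bZ + cZ^2 + dZ^3} of a
#' standard normal \code{Z} has mean 0, variance 1 and the requested skewness
#' and excess kurtosis (\code{a = -c} by construction). The three moment
#' equations are solved numerically.
#'
#' @param skew target skewness.
#' @param kurtosis target excess kurtosis; must satisfy
#'   \code{kurtosis >= skew^2 - 2}, and lie inside the cubic-transform
#'   feasible region for a solution to exist.
#' @return named numeric vector \code{c(a, b, c, d)}.
#' @export
fleishmanCoefficients <- function(skew, kurtosis) {
  if (kurtosis < skew^2 - 2) {
    stop(sprintf("infeasible margin: excess kurtosis %.3f below the boundary skew^2 - 2 = %.3f",
                 kurtosis, skew^2 - 2), call. = FALSE)
  }
  if (skew == 0 && kurtosis == 0) {
    return(c(a = 0, b = 1, c = 0, d = 0))
  }
  fn <- function(x) {
    b <- x[1]; cc <- x[2]; d <- x[3]
    c(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
      2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - skew,
      24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
              d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) - kurtosis)
  }
  starts <- list(c(1, skew / 6, kurtosis / 100),
                 c(0.9, skew / 8, 0.05),
                 c(1.1, sign(skew) * 0.1 + skew / 10, -0.02),
                 c(0.8, skew / 4, 0.1))
  for (st in starts) {
    sol <- tryCatch(pracma::fsolve(fn, st, tol = 1e-12), error = function(e) NULL)
    if (!is.null(sol) && max(abs(fn(sol$x))) < 1e-8 && sol$x[1] > 0) {
      return(c(a = -sol$x[2], b = sol$x[1], c = sol$x[2], d = sol$x[3]))
    }
  }
  stop(sprintf("no cubic-transform solution for skew %.3f, excess kurtosis %.3f: request lies outside the feasible region",
               skew, kurtosis), call. = FALSE)
}

#' Intermediate normal correlation for a target product-moment correlation
#'
#' Solves the Vale-Maurelli cubic
#' \code{r = rho k1 + rho^2 (2 c_i c_j) + rho^3 (6 d_i d_j)} with
#' \code{k1 = b_i b_j + 3 b_i d_j + 3 d_i b_j + 9 d_i d_j} for the
#' correlation \code{rho} of the underlying normals.
#'
#' @param target_r target correlation between the transformed variables
#'   (absolute value below 1).
#' @param coef_i,coef_j Fleishman coefficient vectors of the two margins.
#' @return the intermediate correlation in (-1, 1).
#' @export
intermediateCorrelation <- function(target_r, coef_i, coef_j) {
  if (abs(target_r) >= 1) stop("|target_r| must be below 1", call. = FALSE)
  if (target_r == 0) return(0)
  bi <- coef_i["b"]; ci <- coef_i["c"]; di <- coef_i["d"]
  bj <- coef_j["b"]; cj <- coef_j["c"]; dj <- coef_j["d"]
  k1 <- bi * bj + 3 * bi * dj + 3 * di * bj + 9 * di * dj
  k2 <- 2 * ci * cj
  k3 <- 6 * di * dj
  roots <- polyroot(c(-target_r, k1, k2, k3))
  real <- Re(roots)[abs(Im(roots)) < 1e-8]
  real <- real[abs(real) < 1]
  if (!length(real)) stop("infeasible correlation: no intermediate correlation in (-1, 1)",
                          call. = FALSE)
  unname(real[which.min(abs(real - target_r))])
}

#' Construct a synthetic-sample specification
#'
#' @param R target correlation matrix (symmetric, unit diagonal, PD).
#' @param sds,means per-variable standard deviations and means.
#' @param skew,kurtosis per-variable skewness and excess kurtosis (recycled).
#' @param n sample size.
#' @param seed integer seed through which all randomness flows.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(R, sds = rep(1, nrow(R)), means = rep(0, nrow(R)),
                          skew = 0, kurtosis = 0, n, seed = 1L) {
  p <- nrow(R)
  if (is.null(colnames(R))) colnames(R) <- rownames(R) <- paste0("V", seq_len(p))
  new("SyntheticSpec", R = as.matrix(R), sds = as.numeric(sds),
      means = as.numeric(means), skew = rep_len(as.numeric(skew), p),
      kurtosis = rep_len(as.numeric(kurtosis), p), n = as.numeric(n),
      seed = as.numeric(seed))
}

#' Generate a raw sample with target covariance and non-normal margins
#'
#' Vale-Maurelli generation: each margin is a Fleishman cubic of a standard
#' normal; the underlying normals carry intermediate correlations solved so
#' that the transformed variables hit the target correlations. Fully
#' reproducible from the spec's seed; the caller's random state is left
#' untouched.
#'
#' @param spec a [SyntheticSpec-class].
#' @param strict error (rather than repair with a warning) when the
#'   intermediate correlation matrix is not positive definite.
#' @return n x p data.frame of scores, columns named as in \code{spec@R}.
#' @export
generateSample <- function(spec, strict = FALSE) {
  validObject(spec)
  p <- nrow(spec@R)
  coefs <- lapply(seq_len(p), function(j) fleishmanCoefficients(spec@skew[j], spec@kurtosis[j]))
  Rz <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    Rz[i, j] <- Rz[j, i] <- intermediateCorrelation(spec@R[i, j], coefs[[i]], coefs[[j]])
  }
  ch <- tryCatch(chol(Rz), error = function(e) NULL)
  if (is.null(ch)) {
    if (strict) stop("intermediate correlation matrix is not positive definite", call. = FALSE)
    warning("intermediate correlation matrix repaired to the nearest positive definite matrix")
    Rz <- as.matrix(Matrix::nearPD(Rz, corr = TRUE)$mat)
    ch <- chol(Rz)
  }
  X <- withr::with_seed(as.integer(spec@seed), {
    Z <- matrix(stats::rnorm(spec@n * p), nrow = spec@n) %*% ch
    Y <- Z
    for (j in seq_len(p)) {
      cf <- coefs[[j]]
      zj <- Z[, j]
      Y[, j] <- cf["a"] + cf["b"] * zj + cf["c"] * zj^2 + cf["d"] * zj^3
    }
    sweep(sweep(Y, 2, spec@sds, `*`), 2, spec@means, `+`)
  })
  colnames(X) <- colnames(spec@R)
  as.data.frame(X)
}

# default margin non-normality for the alcohol-involvement indicators;
# affect and motivation scores are left normal
.alcoholVars <- c("ADS", "PACS", "COUNT", "DRINC", "CIWA", "DPDD", "BINGE_PCT")

defaultMargins <- function(vars, skew.alcohol = 1, kurtosis.alcohol = 1.5) {
  list(skew = ifelse(vars %in% .alcoholVars, skew.alcohol, 0),
       kurtosis = ifelse(vars %in% .alcoholVars, kurtosis.alcohol, 0))
}

#' Generate a two-group (gender-structured) study-like sample
#'
#' Draws both groups from the covariance matrix implied by the severity
#' model fitted to the bundled moment table; the second group's factor
#' loadings for the named indicators are offset on the standardized scale
#' (the indicator's residual variance is adjusted so its total variance is
#' preserved). Alcohol-involvement margins are right-skewed by default.
#'
#' @param nWomen,nMen group sample sizes; defaults are the study's 75 and 205.
#' @param loadingOffsets named numeric vector of standardized-loading offsets
#'   applied in the men's group (e.g. \code{c(BAI = 0.2, BDI = 0.2)}).
#' @param seed integer seed.
#' @param skew.alcohol,kurtosis.alcohol margin non-normality for the alcohol
#'   indicators.
#' @return data.frame with a leading \code{group} column
#'   (\code{"female"}/\code{"male"}) followed by the 12 indicator scores.
#' @export
generateStudyGroups <- function(nWomen = 75, nMen = 205,
                                loadingOffsets = numeric(0), seed = 1L,
                                skew.alcohol = 1, kurtosis.alcohol = 1.5) {
  fit <- .fittedModelA()
  vars <- fit@spec@observed
  p <- length(vars)
  if (nWomen <= p || nMen <= p) stop("group sizes must exceed the variable count", call. = FALSE)
  sigW <- fit@sigma
  sigM <- .offsetLoadings(fit, loadingOffsets)
  marg <- defaultMargins(vars, skew.alcohol, kurtosis.alcohol)
  mns <- if (length(fit@moments@means)) fit@moments@means else rep(0, p)

  mk <- function(sig, n, seed) {
    generateSample(syntheticSpec(
      R = stats::cov2cor(sig), sds = sqrt(diag(sig)), means = mns,
      skew = marg$skew, kurtosis = marg$kurtosis, n = n, seed = seed))
  }
  women <- mk(sigW, nWomen, seed)
  men <- mk(sigM, nMen, seed + 1000003L)
  out <- rbind(cbind(group = "female", women), cbind(group = "male", men))
  rownames(out) <- NULL
  out
}

# implied covariance with standardized loadings of selected indicators offset,
# residual variances compensated to preserve total indicator variance
.offsetLoadings <- function(fit, offsets) {
  if (!length(offsets)) return(fit@sigma)
  spec <- fit@spec
  skel <- ramSkeleton(spec)
  theta <- fit@theta
  sa <- ramSigmaAll(skel, theta)
  sdAll <- sqrt(diag(sa$sigmaAll))
  pt <- spec@ptable
  vars <- skel$vars
  for (v in names(offsets)) {
    k <- which(pt$op == "=~" & pt$rhs == v)
    if (length(k) != 1L) stop(sprintf("'%s' is not a single-factor indicator", v), call. = FALSE)
    if (!pt$free[k]) stop(sprintf("cannot offset the fixed marker loading of '%s'", v), call. = FALSE)
    i <- match(pt$row[k], vars); j <- match(pt$col[k], vars)
    stdOld <- theta[pt$id[k]] * sdAll[j] / sdAll[i]
    stdNew <- stdOld + offsets[[v]]
    theta[pt$id[k]] <- stdNew * sdAll[i] / sdAll[j]
    kv <- which(pt$op == "~~" & pt$row == v & pt$col == v)
    residNew <- sdAll[i]^2 - theta[pt$id[k]]^2 * sdAll[j]^2
    if (residNew <= 0) stop(sprintf("offset for '%s' implies nonpositive residual variance", v),
                            call. = FALSE)
    theta[pt$id[kv]] <- residNew
  }
  impliedCov(spec, theta)
}
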