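# ML estimation of covariance-structure models.

#' Construct sample moments
#'
#' Builds a [SampleMoments-class] from a covariance matrix, or from a
#' correlation matrix plus standard deviations (the form in which published
#' moment tables are usually printed).
#'
#' @param S covariance matrix (mutually exclusive with \code{R}/\code{sd}).
#' @param n sample size.
#' @param R correlation matrix.
#' @param sd standard deviations matching \code{R}.
#' @param means optional variable means.
#' @param source moment provenance tag; inferred when missing.
#' @return a [SampleMoments-class].
#' @export
sampleMoments <- function(S = NULL, n, R = NULL, sd = NULL, means = numeric(0),
                          source = NULL) {
  if (is.null(S)) {
    if (is.null(R) || is.null(sd)) stop("supply S, or R plus sd", call. = FALSE)
    S <- covFromCor(R, sd)
    if (is.null(source)) source <- "correlation+sd"
  } else if (is.null(source)) source <- "raw"
  if (is.null(colnames(S))) colnames(S) <- rownames(S) <- paste0("V", seq_len(nrow(S)))
  new("SampleMoments", S = symmetrize(S), n = as.numeric(n),
      means = as.numeric(means), source = source)
}

#' Sample moments from a raw score table
#'
#' @param X numeric matrix or data.frame (subjects x variables), complete cases.
#' @return a [SampleMoments-class] with means filled in.
#' @export
momentsFromRaw <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("raw score table must be complete; listwise-delete upstream", call. = FALSE)
  sampleMoments(S = stats::cov(X), n = nrow(X), means = colMeans(X), source = "raw")
}

#' Covariance from correlation and standard deviations
#'
#' \code{diag(sd) \%*\% R \%*\% diag(sd)}, with input validation; warns when
#' the result is not positive definite (published correlation matrices are
#' rounded and can be near-singular).
#'
#' @param R correlation matrix: symmetric, unit diagonal, entries in [-1, 1].
#' @param sd strictly positive standard deviations.
#' @return covariance matrix with the dimnames of \code{R}.
#' @export
covFromCor <- function(R, sd) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || length(sd) != nrow(R)) {
    stop("R must be square with one sd per variable", call. = FALSE)
  }
  if (any(abs(diag(R) - 1) > 1e-8)) stop("correlation matrix must have unit diagonal", call. = FALSE)
  if (any(abs(R) > 1 + 1e-8)) stop("correlations must lie in [-1, 1]", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix must be symmetric", call. = FALSE)
  if (any(sd <= 0)) stop("standard deviations must be strictly positive", call. = FALSE)
  S <- symmetrize(R * tcrossprod(sd))
  dimnames(S) <- dimnames(R)
  if (!isPositiveDefinite(S)) warning("resulting covariance matrix is not positive definite")
  S
}

#' Maximum-likelihood discrepancy
#'
#' \code{F = log|Sigma| + tr(S Sigma^-1) - log|S| - p}; zero iff the two
#' matrices coincide.
#'
#' @param S observed covariance matrix (symmetric positive definite).
#' @param sigma implied covariance matrix of the same order.
#' @return nonnegative scalar.
#' @export
fmlDiscrepancy <- function(S, sigma) {
  S <- as.matrix(S); sigma <- as.matrix(sigma)
  p <- nrow(S)
  if (!all(dim(sigma) == dim(S))) stop("dimension mismatch", call. = FALSE)
  if (!isPositiveDefinite(S) || !isPositiveDefinite(sigma)) {
    stop("both matrices must be symmetric positive definite", call. = FALSE)
  }
  sigInv <- chol2inv(chol(sigma))
  val <- logDetPD(sigma) + sum(S * sigInv) - logDetPD(S) - p
  max(val, 0)
}

# start values: residual variances at half the sample variance, marker-scaled
# or unit-variance-scaled loadings at 0.7 of the indicator SD, paths and
# covariances at zero; observed-observed covariances at the sample value.
semStartValues <- function(spec, skel, Sobs) {
  pt <- spec@ptable
  vars <- skel$vars
  q <- skel$q
  start <- numeric(q)
  sdv <- rep(1, skel$t)
  sdv[seq_len(skel$p)] <- sqrt(diag(Sobs))
  names(sdv) <- vars

  # factor scale: fixed variance value, or marker SD
  facScale <- stats::setNames(rep(1, length(spec@latents)), spec@latents)
  for (f in spec@latents) {
    vrow <- pt[pt$mat == "S" & pt$row == f & pt$col == f, ]
    mk <- pt[pt$op == "=~" & pt$col == f & !pt$free, ]
    if (nrow(mk)) {
      facScale[f] <- sdv[mk$row[1]] / abs(mk$value[1])
    } else if (nrow(vrow) && !vrow$free[1]) {
      facScale[f] <- sqrt(abs(vrow$value[1]))
    }
  }

  done <- logical(q)
  for (k in seq_len(nrow(pt))) {
    r <- pt[k, ]
    if (!r$free || done[r$id]) next
    val <- 0
    if (r$op == "=~") {
      val <- 0.7 * sdv[r$row] / facScale[r$col]
    } else if (r$op == "~~" && r$row == r$col) {
      v <- r$row
      val <- if (v %in% spec@observed) 0.5 * Sobs[v, v] else 0.5 * facScale[v]^2
    } else if (r$op == "~~" && r$row %in% spec@observed && r$col %in% spec@observed) {
      val <- 0.5 * Sobs[r$row, r$col]
    } else if (r$op == "~~" && r$row %in% spec@latents && r$col %in% spec@latents) {
      # nonzero start keeps two-indicator factors locally identified
      val <- 0.3 * facScale[r$row] * facScale[r$col]
    }
    start[r$id] <- val
    done[r$id] <- TRUE
  }
  start
}

semObjective <- function(skel, slots, Sobs, logDetS) {
  p <- skel$p
  obj <- function(theta) {
    sa <- tryCatch(ramSigmaAll(skel, theta), error = function(e) NULL)
    if (is.null(sa)) return(1e10)
    Sigma <- sa$sigmaAll[seq_len(p), seq_len(p), drop = FALSE]
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    sigInv <- chol2inv(ch)
    2 * sum(log(diag(ch))) + sum(Sobs * sigInv) - logDetS - p
  }
  grad <- function(theta) {
    d <- tryCatch(ramDifferentials(skel, slots, theta, Sobs = Sobs),
                  error = function(e) NULL)
    if (is.null(d) || anyNA(d$grad)) return(rep(0, skel$q))
    d$grad
  }
  list(obj = obj, grad = grad)
}

#' Fit a covariance-structure model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the sample covariance matrix and the
#' model-implied covariance with a quasi-Newton optimizer and the analytic
#' gradient, then populates normal-theory standard errors and the
#' standardized solution. Negative variance estimates (Heywood cases) are
#' flagged, never truncated.
#'
#' @param model a [ModelSpec-class] or model-syntax text.
#' @param moments a [SampleMoments-class] (or a covariance matrix, with
#'   \code{n} given).
#' @param n sample size when \code{moments} is a plain matrix.
#' @param start optional start values for the free parameters.
#' @param check run [checkIdentification()] first (default TRUE).
#' @param control optimizer control overrides passed to [stats::nlminb()].
#' @return a [SemFit-class].
#' @examples
#' fit <- semFit(modelASyntax(), table1Moments())
#' latentRsquared(fit, "Severity")
#' @export
semFit <- function(model, moments, n = NULL, start = NULL, check = TRUE,
                   control = list()) {
  spec <- if (is.character(model)) parseModel(model) else model
  if (is.matrix(moments)) {
    if (is.null(n)) stop("supply n with a plain covariance matrix", call. = FALSE)
    moments <- sampleMoments(S = moments, n = n)
  }
  vars <- spec@observed
  if (!all(vars %in% colnames(moments@S))) {
    stop("moments are missing model variables: ",
         paste(setdiff(vars, colnames(moments@S)), collapse = ", "), call. = FALSE)
  }
  Sobs <- moments@S[vars, vars, drop = FALSE]

  if (check) {
    idc <- checkIdentification(spec)
    if (!idc$identified) {
      stop("model not identified: ", paste(idc$problems, collapse = "; "), call. = FALSE)
    }
  }

  skel <- ramSkeleton(spec)
  slots <- ramDerivSlots(skel)
  if (is.null(start)) start <- semStartValues(spec, skel, Sobs)
  if (length(start) != skel$q) stop("start has wrong length", call. = FALSE)

  # identification via Jacobian column rank at the start values
  if (check && skel$q > 0) {
    J0 <- ramDifferentials(skel, slots, start, jacobian = TRUE)$jacobian
    if (qr(J0)$rank < skel$q) {
      stop("model not identified: moment Jacobian is rank-deficient at the start values",
           call. = FALSE)
    }
  }

  logDetS <- logDetPD(Sobs)
  fo <- semObjective(skel, slots, Sobs, logDetS)
  ctrl <- utils::modifyList(list(iter.max = 10000, eval.max = 20000,
                                 rel.tol = 1e-12, abs.tol = 0), control)
  # parameter scaling keeps the quasi-Newton steps well-conditioned when the
  # observed variables live on very different scales
  pscale <- function(s) 1 / pmax(abs(s), 1e-2)
  opt <- stats::nlminb(start, fo$obj, gradient = fo$grad, scale = pscale(start),
                       control = ctrl)
  iterations <- opt$iterations
  # polish / rescue: restart from perturbed points if the gradient is not flat
  gnorm <- max(abs(fo$grad(opt$par)))
  tries <- 0
  while (gnorm > 1e-6 && tries < 5) {
    jitter <- if (tries == 0) 0 else 0.05 * tries
    st <- opt$par * (1 + jitter * (tries %% 2 == 0)) +
      jitter * (seq_along(opt$par) %% 3 - 1) * 0.01
    o2 <- stats::nlminb(st, fo$obj, gradient = fo$grad, scale = pscale(st),
                        control = ctrl)
    if (o2$objective <= opt$objective + 1e-12) opt <- o2
    gnorm <- max(abs(fo$grad(opt$par)))
    iterations <- iterations + o2$iterations
    tries <- tries + 1
  }

  theta <- opt$par
  # Newton polish with the expected information pushes the gradient to
  # machine precision so independent routes to the same optimum agree
  for (it in seq_len(10)) {
    dd <- ramDifferentials(skel, slots, theta, Sobs = Sobs, jacobian = TRUE)
    if (max(abs(dd$grad)) < 1e-10) break
    H <- 2 * symmetrize(crossprod(dd$jacobian, normalTheoryWeight(dd$sigma) %*% dd$jacobian))
    step <- tryCatch(solve(H, dd$grad), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta - step
    if (fo$obj(cand) <= fo$obj(theta) + 1e-12) theta <- cand else break
  }
  gnorm <- max(abs(fo$grad(theta)))

  d <- ramDifferentials(skel, slots, theta, Sobs = Sobs, jacobian = TRUE)
  Sigma <- d$sigma
  fml <- max(fo$obj(theta), 0)
  nS <- moments@n
  df <- degreesOfFreedom(spec)
  converged <- isPositiveDefinite(Sigma) && gnorm <= 1e-4
  heywood <- any(diag(d$S)[diag(skel$Sid) > 0] < 0)
  if (heywood) warning("Heywood case: negative variance estimate (reported, not truncated)")

  # normal-theory SEs: acov = (Delta' W Delta)^-1 / (n - 1)
  vcovTheta <- matrix(NA_real_, skel$q, skel$q)
  if (skel$q > 0 && converged) {
    W <- normalTheoryWeight(Sigma)
    DWD <- crossprod(d$jacobian, W %*% d$jacobian)
    vcovTheta <- tryCatch(chol2inv(chol(symmetrize(DWD))) / (nS - 1),
                          error = function(e) matrix(NA_real_, skel$q, skel$q))
  }

  params <- buildParameterTable(spec, skel, theta, vcovTheta, d$sigmaAll)
  names(theta) <- paramNames(spec)[seq_len(skel$q)]

  fit <- new("SemFit", spec = spec, moments = moments, theta = theta,
             sigma = Sigma, fml = fml, tml = (nS - 1) * fml, df = df,
             params = params, vcov = vcovTheta, converged = converged,
             iterations = as.numeric(iterations), gradNorm = gnorm,
             heywood = heywood)
  if (!converged) {
    warning(sprintf("optimizer did not reach the gradient tolerance (max |g| = %.2e)", gnorm))
  }
  fit
}

paramNames <- function(spec) {
  pt <- spec@ptable
  nm <- character(countFreeParameters(spec))
  for (k in seq_len(nrow(pt))) {
    if (pt$free[k] && nm[pt$id[k]] == "") {
      nm[pt$id[k]] <- paste0(pt$lhs[k], pt$op[k], pt$rhs[k])
    }
  }
  nm
}

# parameter table with estimates, SEs, z, standardized solution
buildParameterTable <- function(spec, skel, theta, vcovTheta, sigmaAll) {
  pt <- spec@ptable
  vars <- skel$vars
  sdAll <- sqrt(pmax(diag(sigmaAll), 0))
  est <- se <- std <- rep(NA_real_, nrow(pt))
  for (k in seq_len(nrow(pt))) {
    r <- pt[k, ]
    est[k] <- if (r$free) theta[r$id] else r$value
    if (r$free && !anyNA(vcovTheta)) se[k] <- sqrt(max(vcovTheta[r$id, r$id], 0))
    i <- match(r$row, vars); j <- match(r$col, vars)
    if (r$mat == "A") {
      std[k] <- if (sdAll[i] > 0) est[k] * sdAll[j] / sdAll[i] else NA_real_
    } else if (r$row == r$col) {
      std[k] <- if (sdAll[i] > 0) est[k] / sdAll[i]^2 else NA_real_
    } else {
      std[k] <- if (sdAll[i] > 0 && sdAll[j] > 0) est[k] / (sdAll[i] * sdAll[j]) else NA_real_
    }
  }
  out <- pt[, c("lhs", "op", "rhs", "free", "id", "label")]
  out$est <- est
  out$se <- se
  out$z <- ifelse(is.na(se) | se == 0, NA_real_, est / se)
  out$std <- std
  out
}

#' Standardized solution
#'
#' Loadings and paths rescaled by the implied standard deviations of source
#' and target, covariances turned into correlations, variances into
#' proportions of the corresponding total variance.
#'
#' @param fit a converged [SemFit-class].
#' @return data.frame: the parameter table restricted to the standardized
#'   column plus identifiers.
#' @export
standardizedSolution <- function(fit) {
  if (!fit@converged) stop("standardization requires a converged fit", call. = FALSE)
  fit@params[, c("lhs", "op", "rhs", "est", "std")]
}

#' Variance explained for an endogenous latent factor
#'
#' One minus the standardized disturbance variance: the proportion of the
#' factor's implied variance accounted for by its predictors.
#'
#' @param fit a converged [SemFit-class].
#' @param latent name of an endogenous latent factor.
#' @return proportion in [0, 1] (outside only in Heywood cases).
#' @export
latentRsquared <- function(fit, latent) {
  if (!latent %in% fit@spec@endogenous) {
    stop(sprintf("'%s' is not an endogenous latent factor", latent), call. = FALSE)
  }
  pt <- fit@params
  k <- which(pt$op == "~~" & pt$lhs == latent & pt$rhs == latent)
  1 - pt$std[k]
}

# implied moments (covariance over observed vars) at the fitted parameters,
# packaged for reuse e.g. as a synthetic-data target
impliedMoments <- function(fit, n = fit@moments@n) {
  sampleMoments(S = fit@sigma, n = n, source = "raw")
}
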