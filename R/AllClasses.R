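#' @import methods
NULL

#' Covariance-structure model specification
#'
#' A parsed latent-variable model: ordered observed and latent variable names,
#' and a parameter table mapping each loading, structural path, variance and
#' covariance to a slot of the RAM matrices (asymmetric path matrix \code{A},
#' symmetric covariance matrix \code{S}). Free parameters carry integer ids;
#' parameters sharing a user label share one id (equality constraint).
#'
#' @slot observed character vector of observed-variable names, in order.
#' @slot latents character vector of latent factor names, in order.
#' @slot endogenous character vector: latents appearing as regression targets.
#' @slot ptable data.frame with columns \code{lhs, op, rhs, mat, row, col,
#'   free, value, label, id}. \code{value} is the fixed value (NA when free)
#'   and doubles as the start-value override when supplied.
#' @slot syntax the canonical model-syntax text.
#' @export
setClass("ModelSpec", representation(
  observed = "character",
  latents = "character",
  endogenous = "character",
  ptable = "data.frame",
  syntax = "character"
))

setValidity("ModelSpec", function(object) {
  pt <- object@ptable
  msgs <- character()
  need <- c("lhs", "op", "rhs", "mat", "row", "col", "free", "value", "label", "id")
  if (!all(need %in% names(pt))) {
    return(paste("ptable must have columns", paste(need, collapse = ", ")))
  }
  allv <- c(object@observed, object@latents)
  if (anyDuplicated(allv)) msgs <- c(msgs, "observed and latent names must be distinct")
  if (!all(pt$row %in% allv) || !all(pt$col %in% allv)) {
    msgs <- c(msgs, "parameter table references undeclared variables")
  }
  load <- pt[pt$op == "=~", ]
  if (nrow(load) && !all(load$rhs %in% object@observed)) {
    msgs <- c(msgs, "every indicator must appear in observed")
  }
  reg <- pt[pt$op == "~", ]
  if (nrow(reg) && !(all(reg$lhs %in% object@latents) && all(reg$rhs %in% object@latents))) {
    msgs <- c(msgs, "structural path endpoints must be declared latents")
  }
  key <- paste(pt$mat, pmin(match(pt$row, allv), match(pt$col, allv)),
               pmax(match(pt$row, allv), match(pt$col, allv)),
               ifelse(pt$mat == "A", paste(pt$row, pt$col), ""))
  if (anyDuplicated(key[pt$mat == "S"]) || anyDuplicated(paste(pt$row, pt$col)[pt$mat == "A"])) {
    msgs <- c(msgs, "duplicate parameter entries")
  }
  ids <- pt$id[pt$free]
  if (length(ids) && !setequal(unique(ids), seq_len(max(ids)))) {
    msgs <- c(msgs, "free-parameter ids must be 1..q")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Sample moments for covariance-structure estimation
#'
#' Holds the observed covariance matrix, the sample size and (optionally) the
#' variable means. Construct with [sampleMoments()] from either a covariance
#' matrix or a correlation matrix plus standard deviations.
#'
#' @slot S covariance matrix (symmetric, positive definite).
#' @slot n sample size.
#' @slot means variable means (may be empty).
#' @slot source either \code{"raw"} or \code{"correlation+sd"}.
#' @export
setClass("SampleMoments", representation(
  S = "matrix",
  n = "numeric",
  means = "numeric",
  source = "character"
))

setValidity("SampleMoments", function(object) {
  S <- object@S
  p <- nrow(S)
  if (is.null(colnames(S))) return("covariance matrix must carry variable names")
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) return("covariance matrix must be symmetric")
  if (!isPositiveDefinite(symmetrize(S))) return("covariance matrix must be positive definite")
  if (object@n < p + 1) return("n must be at least p + 1")
  if (length(object@means) && length(object@means) != p) return("means length must match p")
  TRUE
})

#' Fitted covariance-structure model
#'
#' Result of [semFit()]: parameter estimates, the implied covariance matrix,
#' the ML discrepancy and chi-square statistic, standard errors and the
#' standardized solution, plus convergence diagnostics.
#'
#' @slot spec the [ModelSpec-class] that was fitted.
#' @slot moments the [SampleMoments-class] used.
#' @slot theta named vector of free-parameter estimates.
#' @slot sigma implied covariance matrix at the optimum.
#' @slot fml minimized ML discrepancy.
#' @slot tml chi-square statistic \code{(n - 1) * fml}.
#' @slot df model degrees of freedom.
#' @slot params parameter table with estimates, SEs, z and standardized values.
#' @slot vcov normal-theory asymptotic covariance of the estimates.
#' @slot converged logical convergence flag.
#' @slot iterations optimizer iteration count.
#' @slot gradNorm infinity norm of the discrepancy gradient at the optimum.
#' @slot heywood logical: any negative variance estimate.
#' @export
setClass("SemFit", representation(
  spec = "ModelSpec",
  moments = "SampleMoments",
  theta = "numeric",
  sigma = "matrix",
  fml = "numeric",
  tml = "numeric",
  df = "numeric",
  params = "data.frame",
  vcov = "matrix",
  converged = "logical",
  iterations = "numeric",
  gradNorm = "numeric",
  heywood = "logical"
))

setValidity("SemFit", function(object) {
  if (object@fml < -1e-10) return("discrepancy must be nonnegative")
  if (abs(object@tml - (object@moments@n - 1) * object@fml) > 1e-6 * (1 + object@tml)) {
    return("tml must equal (n - 1) * fml")
  }
  TRUE
})

#' Simultaneous multi-group model fit
#'
#' Result of [fitMultigroup()]: a joint fit of one model in several groups
#' with selected parameters constrained equal across groups.
#'
#' @slot spec shared [ModelSpec-class].
#' @slot groups named list of [SampleMoments-class], one per group.
#' @slot theta joint free-parameter vector.
#' @slot map integer matrix (q x G): joint index of each within-group
#'   parameter in each group.
#' @slot constrained integer vector of within-group parameter ids that are
#'   equality-constrained across groups.
#' @slot tml total chi-square (sum over groups of \code{(n_g - 1) F_g}).
#' @slot df total degrees of freedom.
#' @slot perGroup list of per-group detail (theta, sigma, fml).
#' @slot converged logical.
#' @slot gradNorm gradient infinity norm at the optimum.
#' @export
setClass("MultiGroupFit", representation(
  spec = "ModelSpec",
  groups = "list",
  theta = "numeric",
  map = "matrix",
  constrained = "integer",
  tml = "numeric",
  df = "numeric",
  perGroup = "list",
  converged = "logical",
  gradNorm = "numeric"
))

#' Specification for a non-normal synthetic sample
#'
#' Targets for the Vale-Maurelli generator: a correlation structure, per
#' variable mean/SD and third/fourth standardized moments, a sample size and
#' one seed through which all randomness flows.
#'
#' @slot R target correlation matrix.
#' @slot sds target standard deviations.
#' @slot means target means.
#' @slot skew per-variable skewness.
#' @slot kurtosis per-variable excess kurtosis.
#' @slot n sample size.
#' @slot seed integer seed.
#' @export
setClass("SyntheticSpec", representation(
  R = "matrix",
  sds = "numeric",
  means = "numeric",
  skew = "numeric",
  kurtosis = "numeric",
  n = "numeric",
  seed = "numeric"
))

setValidity("SyntheticSpec", function(object) {
  p <- nrow(object@R)
  if (!isTRUE(all.equal(diag(object@R), rep(1, p), check.attributes = FALSE))) {
    return("target correlation matrix must have unit diagonal")
  }
  if (!isTRUE(all.equal(object@R, t(object@R), tolerance = 1e-8))) {
    return("target correlation matrix must be symmetric")
  }
  if (!isPositiveDefinite(symmetrize(object@R))) return("target correlation matrix must be positive definite")
  if (any(object@sds <= 0)) return("sds must be strictly positive")
  if (!all(lengths(list(object@sds, object@means, object@skew, object@kurtosis)) == p)) {
    return("sds, means, skew, kurtosis must all have length p")
  }
  bad <- object@kurtosis < object@skew^2 - 2
  if (any(bad)) {
    return(sprintf("infeasible margin: excess kurtosis must be >= skew^2 - 2 (variable %d)",
                   which(bad)[1]))
  }
  if (object@n < 2) return("n must be at least 2")
  TRUE
})
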