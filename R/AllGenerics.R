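#' @include AllClasses.R
NULL

#' Observed-variable names
#' @param object a ModelSpec, SampleMoments or SemFit.
#' @return character vector.
#' @export
setGeneric("observedVars", function(object) standardGeneric("observedVars"))

#' Latent-factor names
#' @param object a ModelSpec or SemFit.
#' @return character vector.
#' @export
setGeneric("latentVars", function(object) standardGeneric("latentVars"))

#' Sample size
#' @param object a SampleMoments, SemFit or MultiGroupFit.
#' @return numeric scalar (total n for multi-group fits).
#' @export
setGeneric("sampleSize", function(object) standardGeneric("sampleSize"))

#' Observed covariance matrix
#' @param object a SampleMoments or SemFit.
#' @return symmetric matrix.
#' @export
setGeneric("momentsCov", function(object) standardGeneric("momentsCov"))

#' Parameter table of a fitted model
#' @param object a SemFit or MultiGroupFit.
#' @param ... unused.
#' @return data.frame with estimates, standard errors and standardized values.
#' @export
setGeneric("parameterTable", function(object, ...) standardGeneric("parameterTable"))

#' @describeIn ModelSpec-class observed variables
#' @param object object to query.
#' @export
setMethod("observedVars", "ModelSpec", function(object) object@observed)
#' @describeIn SampleMoments-class observed variables
#' @export
setMethod("observedVars", "SampleMoments", function(object) colnames(object@S))
#' @describeIn SemFit-class observed variables
#' @export
setMethod("observedVars", "SemFit", function(object) object@spec@observed)

#' @describeIn ModelSpec-class latent factors
#' @export
setMethod("latentVars", "ModelSpec", function(object) object@latents)
#' @describeIn SemFit-class latent factors
#' @export
setMethod("latentVars", "SemFit", function(object) object@spec@latents)

#' @describeIn SampleMoments-class sample size
#' @export
setMethod("sampleSize", "SampleMoments", function(object) object@n)
#' @describeIn SemFit-class sample size
#' @export
setMethod("sampleSize", "SemFit", function(object) object@moments@n)
#' @describeIn MultiGroupFit-class total sample size
#' @export
setMethod("sampleSize", "MultiGroupFit", function(object) {
  sum(vapply(object@groups, function(g) g@n, numeric(1)))
})

#' @describeIn SampleMoments-class covariance matrix
#' @export
setMethod("momentsCov", "SampleMoments", function(object) object@S)
#' @describeIn SemFit-class observed covariance used in the fit
#' @export
setMethod("momentsCov", "SemFit", function(object) object@moments@S)

#' @describeIn SemFit-class full parameter table
#' @export
setMethod("parameterTable", "SemFit", function(object, ...) object@params)

#' @describeIn SemFit-class named free-parameter estimates
#' @param object fitted model.
#' @param ... unused.
#' @export
setMethod("coef", "SemFit", function(object, ...) object@theta)

#' @describeIn SemFit-class model-implied covariance matrix
#' @param object fitted model.
#' @param use.fallback,... unused.
#' @importFrom stats sigma nobs
#' @export
setMethod("sigma", "SemFit", function(object, ...) object@sigma)

#' @describeIn SemFit-class sample size
#' @export
setMethod("nobs", "SemFit", function(object, use.fallback = FALSE, ...) object@moments@n)

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", length(object@observed), "observed variables,",
      length(object@latents), "latent factors\n")
  cat("  observed:", paste(object@observed, collapse = ", "), "\n")
  if (length(object@latents)) {
    cat("  latents: ", paste(object@latents, collapse = ", "), "\n")
  }
  cat("  free parameters:", countFreeParameters(object),
      " df:", degreesOfFreedom(object), "\n")
})

setMethod("show", "SampleMoments", function(object) {
  cat("SampleMoments:", nrow(object@S), "variables, n =", object@n,
      sprintf("(source: %s)\n", object@source))
})

setMethod("show", "SemFit", function(object) {
  cat("SemFit:", length(object@theta), "free parameters, df =", object@df, "\n")
  cat(sprintf("  chi-square (ML) = %.3f, F_ML = %.6f, n = %d\n",
              object@tml, object@fml, as.integer(object@moments@n)))
  cat("  converged:", object@converged,
      sprintf(" (grad max %.2e, %d iterations)\n", object@gradNorm,
              as.integer(object@iterations)))
  if (object@heywood) cat("  WARNING: Heywood case (negative variance estimate)\n")
})

setMethod("show", "MultiGroupFit", function(object) {
  cat("MultiGroupFit:", length(object@groups), "groups,",
      length(object@theta), "joint free parameters, df =", object@df, "\n")
  cat(sprintf("  total chi-square = %.3f, converged: %s\n", object@tml, object@converged))
  cat("  constrained within-group parameter ids:",
      paste(object@constrained, collapse = ", "), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", nrow(object@R), "variables, n =", object@n,
      ", seed =", object@seed, "\n")
})
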