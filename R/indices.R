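# Chi-square based fit statistics.

#' Relative chi-square
#'
#' The ratio of the chi-square statistic to its degrees of freedom; values
#' below 2 are conventionally read as adequate fit.
#'
#' @param t chi-square value.
#' @param df positive degrees of freedom.
#' @return \code{t/df}.
#' @export
relativeChiSquare <- function(t, df) {
  if (df == 0) stop("relative chi-square is undefined for a saturated model (df = 0)",
                    call. = FALSE)
  t / df
}

#' Independence (baseline) model fit
#'
#' Fits the diagonal-covariance null model with free variances. Its ML
#' discrepancy has the closed form \code{-log|R|} where \code{R} is the
#' sample correlation matrix; \code{df = p(p-1)/2}.
#'
#' @param moments a [SampleMoments-class].
#' @return list with \code{fml}, \code{tml}, \code{df}, \code{sigma}
#'   (the fitted diagonal covariance matrix).
#' @export
baselineFit <- function(moments) {
  S <- moments@S
  p <- nrow(S)
  R <- stats::cov2cor(S)
  fml <- -logDetPD(R)
  list(fml = fml, tml = (moments@n - 1) * fml, df = p * (p - 1) / 2,
       sigma = diag(diag(S), p))
}

#' Comparative fit index
#'
#' Incremental fit relative to the independence baseline:
#' \code{1 - max(t - df, 0) / max(t - df, t_b - df_b, 0)}, defined as 1 when
#' both excesses are nonpositive.
#'
#' @param t model chi-square.
#' @param df model degrees of freedom.
#' @param t_b baseline chi-square.
#' @param df_b baseline degrees of freedom (must be >= \code{df}).
#' @return value in [0, 1].
#' @export
cfi <- function(t, df, t_b, df_b) {
  if (df_b < df) stop("baseline df must be at least the model df", call. = FALSE)
  num <- max(t - df, 0)
  den <- max(t - df, t_b - df_b, 0)
  if (den == 0) return(1)
  1 - num / den
}

#' Root mean square error of approximation
#'
#' Per-degree-of-freedom misfit, \code{sqrt(max(0, (t - df) / (df (n - 1))))},
#' using the \code{(n - 1)} chi-square convention.
#'
#' @param t model chi-square.
#' @param df positive degrees of freedom.
#' @param n sample size (> 1).
#' @return nonnegative value.
#' @export
rmsea <- function(t, df, n) {
  if (df == 0) stop("RMSEA is undefined for a saturated model (df = 0)", call. = FALSE)
  if (n <= 1) stop("n must exceed 1", call. = FALSE)
  sqrt(max(0, (t - df) / (df * (n - 1))))
}

#' Fit-index report for a fitted model
#'
#' Combines the chi-square, relative chi-square, baseline model, CFI and
#' RMSEA into one named vector.
#'
#' @param fit a [SemFit-class].
#' @return named numeric vector with elements \code{chisq, df, pvalue,
#'   rel.chisq, baseline.chisq, baseline.df, cfi, rmsea, fml, n}.
#' @export
fitMeasures <- function(fit) {
  b <- baselineFit(fit@moments)
  t <- fit@tml; df <- fit@df; n <- fit@moments@n
  c(chisq = t, df = df,
    pvalue = if (df > 0) stats::pchisq(t, df, lower.tail = FALSE) else NA_real_,
    rel.chisq = if (df > 0) relativeChiSquare(t, df) else NA_real_,
    baseline.chisq = b$tml, baseline.df = b$df,
    cfi = cfi(t, df, b$tml, b$df),
    rmsea = if (df > 0) rmsea(t, df, n) else NA_real_,
    fml = fit@fml, n = n)
}
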