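# Shared fixtures and independent oracles, all built in code.

oneFactorSyntax <- "
F =~ 1*x1 + x2 + x3
"

twoFactorSyntax <- "
F1 =~ y1 + y2 + y3
F2 =~ y4 + y5 + y6
F1 ~~ 1*F1
F2 ~~ 1*F2
F1 ~~ F2
"

# generating values for the two-factor model (standardized metric)
twoFactorTheta <- function() {
  spec <- parseModel(twoFactorSyntax)
  lam <- c(0.7, 0.8, 0.6, 0.75, 0.65, 0.8)
  th <- numeric(countFreeParameters(spec))
  pt <- spec@ptable
  for (k in which(pt$free)) {
    r <- pt[k, ]
    th[r$id] <- if (r$op == "=~") lam[match(r$rhs, paste0("y", 1:6))]
    else if (r$op == "~~" && r$row == r$col) 1 - lam[match(r$row, paste0("y", 1:6))]^2
    else 0.3   # factor correlation
  }
  th
}

# independent implied-covariance oracle: nilpotent series for (I - A)^-1
# (total-effect accumulation over paths), assembled directly from the
# parameter table without the package's RAM solver
oracleImpliedCov <- function(spec, theta) {
  vars <- c(spec@observed, spec@latents)
  t <- length(vars)
  A <- S <- matrix(0, t, t, dimnames = list(vars, vars))
  pt <- spec@ptable
  for (k in seq_len(nrow(pt))) {
    r <- pt[k, ]
    val <- if (r$free) theta[r$id] else r$value
    if (r$mat == "A") A[r$row, r$col] <- val
    else { S[r$row, r$col] <- val; S[r$col, r$row] <- val }
  }
  B <- diag(t); term <- diag(t)
  for (i in seq_len(t)) {           # A is nilpotent for recursive models
    term <- term %*% A
    if (all(term == 0)) break
    B <- B + term
  }
  full <- B %*% S %*% t(B)
  dimnames(full) <- list(vars, vars)
  full[spec@observed, spec@observed, drop = FALSE]
}

sampleSkewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
sampleExKurtosis <- function(x) mean((x - mean(x))^4) / stats::sd(x)^4 - 3

# multivariate normal sample via Cholesky (test-local, seeded by caller)
rmvn <- function(n, Sigma) {
  Z <- matrix(stats::rnorm(n * ncol(Sigma)), n)
  X <- Z %*% chol(Sigma)
  colnames(X) <- colnames(Sigma)
  X
}

# named PD correlation matrix helper
namedCor <- function(R, nms) {
  dimnames(R) <- list(nms, nms)
  R
}
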