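test_that("the fourth-moment matrix reduces correctly in edge cases", {
  set.seed(11)
  x <- stats::rnorm(400, sd = 2)
  g1 <- adfGamma(matrix(x, ncol = 1))
  xc <- x - mean(x)
  expect_equal(as.numeric(g1), mean(xc^4) - mean(xc^2)^2)   # m4 - m2^2

  X <- cbind(a = stats::rnorm(300), b = 1)                   # constant column
  g2 <- adfGamma(X)
  expect_equal(g2[2:3, ], matrix(0, 2, 3), ignore_attr = TRUE)
  expect_equal(g2[, 2:3], matrix(0, 3, 2), ignore_attr = TRUE)

  expect_error(adfGamma(matrix(stats::rnorm(20), ncol = 4)), "too small")
})

test_that("the fourth-moment matrix is permutation invariant and quartic in scale", {
  set.seed(12)
  X <- matrix(stats::rnorm(600), ncol = 3)
  g <- adfGamma(X)
  expect_equal(adfGamma(X[sample(nrow(X)), ]), g)
  X2 <- X; X2[, 1] <- 2 * X2[, 1]
  g2 <- adfGamma(X2)
  expect_equal(g2[1, 1], 16 * g[1, 1])    # (1,1) element scales as c^4
})

test_that("under normality the fourth-moment matrix approaches normal theory", {
  Sigma <- matrix(c(2, .7, .3, .7, 1.5, .5, .3, .5, 1), 3)
  set.seed(13)
  X <- rmvn(50000, namedCor(stats::cov2cor(Sigma), c("a", "b", "c")) *
              tcrossprod(sqrt(diag(Sigma))))
  g <- adfGamma(X)
  S <- stats::cov(X)
  Dp <- duplicationMatrix(3)
  Dplus <- solve(crossprod(Dp), t(Dp))
  gNT <- 2 * Dplus %*% kronecker(S, S) %*% t(Dplus)
  expect_true(max(abs(g - gNT) / (abs(gNT) + 0.05)) < 0.05)
})

test_that("Satorra-Bentler scaling is exact under normal-theory weights", {
  fit <- semFit(modelASyntax(), table1Moments())
  W <- sevsem:::normalTheoryWeight(fit@sigma)
  gNT <- chol2inv(chol(W))
  sb <- satorraBentler(fit, gamma = gNT)
  expect_equal(sb$c, 1, tolerance = 1e-8)
  expect_equal(sb$t_sb, fit@tml, tolerance = 1e-6)

  # projection-rank identity tr(U W^-1) = df
  expect_equal(sum(sb$u * t(gNT)), fit@df, tolerance = 1e-8)

  # robust SEs collapse onto the ML SEs
  seML <- fit@params$se[fit@params$free][order(fit@params$id[fit@params$free])]
  expect_equal(unname(robustSE(fit, gamma = gNT)), seML, tolerance = 1e-8)
})

test_that("leptokurtic data inflate the scaling factor and the variance SEs", {
  spec <- parseModel(twoFactorSyntax)
  th <- twoFactorTheta()
  Sig <- impliedCov(spec, th)
  raw <- generateSample(syntheticSpec(R = stats::cov2cor(Sig), sds = sqrt(diag(Sig)),
                                      skew = 0, kurtosis = 6, n = 4000, seed = 77))
  fit <- semFit(spec, momentsFromRaw(raw))
  sb <- satorraBentler(fit, raw = raw)
  expect_gt(sb$c, 1)
  expect_lt(sb$t_sb, fit@tml)

  seR <- robustSE(fit, raw = raw)
  seML <- fit@params$se[fit@params$free][order(fit@params$id[fit@params$free])]
  pt <- spec@ptable
  varIds <- pt$id[pt$free & pt$op == "~~" & pt$row == pt$col]
  expect_true(all(seR[varIds] >= seML[varIds]))
})

test_that("loadings stay significant under robust errors on study-like data", {
  mom <- table1Moments()
  marg <- sevsem:::defaultMargins(colnames(mom@S))
  raw <- generateSample(syntheticSpec(R = stats::cov2cor(mom@S), sds = sqrt(diag(mom@S)),
                                      means = mom@means, skew = marg$skew,
                                      kurtosis = marg$kurtosis, n = 283, seed = 21))
  fit <- semFit(modelASyntax(), momentsFromRaw(raw))
  seR <- robustSE(fit, raw = raw)
  pt <- fit@params
  free <- pt[pt$free & pt$op == "=~", ]
  z <- abs(free$est / seR[free$id])
  expect_true(all(z > 1.96))
})

test_that("robust indices equal the plain ones when scaling is trivial", {
  fit <- semFit(modelASyntax(), table1Moments())
  idx <- fitMeasures(fit)
  # identical scaled and unscaled statistics give identical CFI/RMSEA
  expect_equal(cfi(fit@tml, fit@df, idx[["baseline.chisq"]], idx[["baseline.df"]]),
               idx[["cfi"]])
  expect_equal(rmsea(fit@tml, fit@df, fit@moments@n), idx[["rmsea"]])

  # published robust arithmetic: scaled statistics through the same formulas
  expect_equal(round(rmsea(103.73, 48, 283), 3), 0.064)
  expect_equal(round(rmsea(105.40, 48, 271), 3), 0.067)
})

test_that("robustFitIndices runs end to end on raw synthetic data", {
  spec <- parseModel(twoFactorSyntax)
  th <- twoFactorTheta()
  Sig <- impliedCov(spec, th)
  raw <- generateSample(syntheticSpec(R = stats::cov2cor(Sig), sds = sqrt(diag(Sig)),
                                      skew = 1, kurtosis = 3, n = 1500, seed = 5))
  fit <- semFit(spec, momentsFromRaw(raw))
  ri <- robustFitIndices(fit, raw)
  expect_true(ri[["c"]] > 0 && ri[["baseline.c"]] > 0)
  expect_true(ri[["cfi.robust"]] >= 0 && ri[["cfi.robust"]] <= 1)
  expect_true(ri[["rmsea.robust"]] >= 0)
  expect_equal(ri[["chisq.scaled"]], fit@tml / ri[["c"]])
})
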