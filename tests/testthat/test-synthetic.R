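test_that("Fleishman coefficients honor their symmetries and feasibility bound", {
  expect_equal(fleishmanCoefficients(0, 0), c(a = 0, b = 1, c = 0, d = 0))

  cf <- fleishmanCoefficients(1.5, 3.5)
  mir <- fleishmanCoefficients(-1.5, 3.5)
  expect_equal(unname(mir), unname(cf * c(-1, 1, -1, 1)), tolerance = 1e-8)

  expect_error(fleishmanCoefficients(2, 1), "infeasible")   # kurt < skew^2 - 2
})

test_that("Fleishman margins hit their target moments in Monte Carlo", {
  cf <- fleishmanCoefficients(1.5, 3.5)
  set.seed(3)
  z <- stats::rnorm(2e5)
  y <- cf["a"] + cf["b"] * z + cf["c"] * z^2 + cf["d"] * z^3
  expect_equal(mean(y), 0, tolerance = 0.01)
  expect_equal(stats::sd(y), 1, tolerance = 0.01)
  expect_equal(sampleSkewness(y), 1.5, tolerance = 0.05)
  expect_equal(sampleExKurtosis(y), 3.5, tolerance = 0.2)
})

test_that("intermediate correlations collapse to the target for normal margins", {
  nrm <- fleishmanCoefficients(0, 0)
  expect_equal(intermediateCorrelation(0.37, nrm, nrm), 0.37, tolerance = 1e-12)
  skw <- fleishmanCoefficients(1.5, 3.5)
  expect_identical(intermediateCorrelation(0, nrm, skw), 0)
  expect_error(intermediateCorrelation(1, nrm, nrm), "below 1")

  # skewed pair: the adjusted normal correlation delivers the target
  rho <- intermediateCorrelation(0.5, skw, skw)
  expect_gt(rho, 0.5)   # the cubic transform attenuates, so rho over-corrects
  x <- generateSample(syntheticSpec(namedCor(matrix(c(1, .5, .5, 1), 2), c("u", "v")),
                                    skew = 1.5, kurtosis = 3.5, n = 1e5, seed = 8))
  expect_equal(stats::cor(x$u, x$v), 0.5, tolerance = 0.01)
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  sp <- syntheticSpec(namedCor(diag(2), c("a", "b")), n = 100, seed = 42)
  x1 <- generateSample(sp)
  set.seed(999); before <- stats::runif(1)
  set.seed(999); x2 <- generateSample(sp); after <- stats::runif(1)
  expect_identical(x1, x2)
  expect_identical(before, after)
})

test_that("study-like margins converge to the published means and SDs", {
  mom <- table1Moments()
  marg <- sevsem:::defaultMargins(colnames(mom@S))
  sp <- syntheticSpec(R = stats::cov2cor(mom@S), sds = sqrt(diag(mom@S)),
                      means = mom@means, skew = marg$skew,
                      kurtosis = marg$kurtosis, n = 1e5, seed = 2)
  x <- generateSample(sp)
  expect_equal(mean(x$ADS), 40.25, tolerance = 40.25 * 0.005)
  expect_equal(stats::sd(x$ADS), 7.31, tolerance = 7.31 * 0.005)
  # alcohol margins are right-skewed, affect margins are not
  expect_gt(sampleSkewness(x$DRINC), 0.8)
  expect_lt(abs(sampleSkewness(x$BDI)), 0.1)
})

test_that("infeasible margins are rejected at spec construction", {
  expect_error(syntheticSpec(namedCor(diag(2), c("a", "b")), skew = 3, kurtosis = 1,
                             n = 100),
               "kurtosis")
})

test_that("two-group generation preserves the study design", {
  g <- generateStudyGroups(seed = 4)     # default 75 women, 205 men
  expect_identical(as.integer(table(g$group)), c(75L, 205L))
  expect_identical(ncol(g), 13L)

  # zero offsets: both groups share one implied covariance; pooled moments
  # approach the model-implied matrix
  g2 <- generateStudyGroups(nWomen = 2000, nMen = 2000, seed = 5)
  fit <- semFit(modelASyntax(), table1Moments())
  pooled <- stats::cov(as.matrix(g2[, -1]))
  expect_lt(max(abs(stats::cov2cor(pooled) - stats::cov2cor(fit@sigma))), 0.05)

  expect_error(generateStudyGroups(nWomen = 5, nMen = 205), "exceed")
})
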