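test_that("covariance reconstruction from correlations and SDs is exact", {
  R <- namedCor(diag(3), c("a", "b", "c"))
  expect_equal(covFromCor(R, c(1, 2, 3)), namedCor(diag(c(1, 4, 9)), c("a", "b", "c")))

  mom <- table1Moments()
  expect_equal(unname(mom@S["ADS", "ADS"]), 7.31^2)
  expect_equal(round(unname(mom@S["ADS", "PACS"]), 2), 24.16)

  badR <- namedCor(matrix(c(1.1, .2, .2, 1), 2), c("a", "b"))
  expect_error(covFromCor(badR, c(1, 1)), "unit diagonal")
})

test_that("implied covariance matches RAM algebra and the path-tracing oracle", {
  # loadings of 0.6 and 0.8 on a unit-variance factor: off-diagonal 0.48
  spec <- parseModel("F =~ a*x1 + b*x2\nF ~~ 1*F")
  pt <- spec@ptable
  th <- numeric(4)
  th[pt$id[pt$rhs == "x1" & pt$op == "=~"]] <- 0.6
  th[pt$id[pt$rhs == "x2" & pt$op == "=~"]] <- 0.8
  th[pt$id[pt$row == "x1" & pt$op == "~~"]] <- 0.64
  th[pt$id[pt$row == "x2" & pt$op == "~~"]] <- 0.36
  Sig <- impliedCov(spec, th)
  expect_equal(unname(Sig["x1", "x2"]), 0.48)
  expect_equal(unname(diag(Sig)), c(1, 1))

  # zero loadings leave a diagonal of residual variances
  th0 <- th; th0[1:2] <- 0
  expect_equal(impliedCov(spec, th0), diag(c(0.64, 0.36)), ignore_attr = TRUE)

  # nilpotent-series oracle agreement on recursive fixtures (<= 6 variables)
  fixtures <- list(
    list(spec = parseModel(oneFactorSyntax)),
    list(spec = parseModel(twoFactorSyntax)),
    list(spec = parseModel("E =~ 1*x1 + x2 + x3\nD =~ 1*x4 + x5\nE ~ D\nD ~~ 1*D"))
  )
  set.seed(42)
  for (fx in fixtures) {
    q <- countFreeParameters(fx$spec)
    for (rep in 1:5) {
      th <- stats::runif(q, 0.2, 1.2)
      expect_equal(impliedCov(fx$spec, th), oracleImpliedCov(fx$spec, th),
                   tolerance = 1e-10)
    }
  }
})

test_that("ML discrepancy has its closed-form and divergence properties", {
  S <- matrix(c(4, 1, 1, 2), 2)
  expect_identical(fmlDiscrepancy(S, S), 0)
  expect_equal(fmlDiscrepancy(matrix(2), matrix(1)), log(1) + 2 - log(2) - 1)
  expect_equal(round(fmlDiscrepancy(matrix(2), matrix(1)), 4), 0.3069)
  set.seed(5)
  for (i in 1:10) {
    A <- crossprod(matrix(stats::rnorm(9), 3)) + diag(3)
    B <- crossprod(matrix(stats::rnorm(9), 3)) + diag(3)
    expect_gt(fmlDiscrepancy(A, B), 0)
  }
  expect_error(fmlDiscrepancy(diag(2), -diag(2)), "positive definite")
})

test_that("a saturated model fits perfectly and an analytic-free optimizer agrees", {
  mom <- table1Moments()
  sat3 <- parseModel("ADS ~~ PACS\nADS ~~ COUNT\nPACS ~~ COUNT")
  fit <- semFit(sat3, mom)
  expect_equal(fit@fml, 0, tolerance = 1e-10)
  expect_equal(fit@tml, 0, tolerance = 1e-7)
  expect_identical(fit@df, 0L)

  # independent optimizer route: numeric-gradient BFGS reaches the same
  # minimum of the severity model
  spec <- parseModel(modelASyntax())
  fitA <- semFit(spec, mom)
  skel <- sevsem:::ramSkeleton(spec)
  slots <- sevsem:::ramDerivSlots(skel)
  Sobs <- mom@S[spec@observed, spec@observed]
  fo <- sevsem:::semObjective(skel, slots, Sobs, sevsem:::logDetPD(Sobs))
  st <- sevsem:::semStartValues(spec, skel, Sobs)
  bfgs <- stats::optim(st, fo$obj, method = "BFGS",
                       control = list(maxit = 5000, reltol = 1e-15,
                                      parscale = pmax(abs(st), 1e-2)))
  expect_equal(bfgs$value, fitA@fml, tolerance = 1e-6)
  expect_gte(bfgs$value, fitA@fml - 1e-8)
})

test_that("refits from perturbed starts reach the same discrepancy", {
  mom <- table1Moments()
  spec <- parseModel(modelASyntax())
  fit <- semFit(spec, mom)
  set.seed(9)
  for (rep in 1:3) {
    st <- fit@theta * stats::runif(length(fit@theta), 0.6, 1.6)
    refit <- semFit(spec, mom, start = unname(st))
    expect_equal(refit@fml, fit@fml, tolerance = 1e-6)
  }
})

test_that("the standardized solution is invariant to observed-variable rescaling", {
  mom <- table1Moments()
  spec <- parseModel(modelASyntax())
  fit <- semFit(spec, mom)

  S2 <- mom@S
  S2["DRINC", ] <- S2["DRINC", ] * 10
  S2[, "DRINC"] <- S2[, "DRINC"] * 10
  fit2 <- semFit(spec, sampleMoments(S = S2, n = mom@n))
  expect_equal(fit2@params$std, fit@params$std, tolerance = 1e-6)
  expect_equal(fit2@fml, fit@fml, tolerance = 1e-8)
})

test_that("latent R-squared follows the standardized disturbance", {
  fit <- semFit(modelASyntax(), table1Moments())
  r2 <- latentRsquared(fit, "Severity")
  expect_true(r2 > 0 && r2 < 1)
  pt <- fit@params
  dist <- pt$std[pt$op == "~~" & pt$lhs == "Severity" & pt$rhs == "Severity"]
  expect_equal(r2, 1 - dist)
  expect_error(latentRsquared(fit, "Motivation"), "endogenous")

  # single-predictor latent regression with standardized path 0.5: R2 = 0.25
  spec <- parseModel("A =~ a1 + a2 + a3\nB =~ 1*b1 + b2 + b3\nB ~ A\nA ~~ 1*A")
  fitA <- semFit(spec, momentsFromRaw({
    set.seed(31)
    f <- stats::rnorm(4000); e <- stats::rnorm(4000)
    b <- (0.5 * f + sqrt(0.75) * e)
    cbind(a1 = f + stats::rnorm(4000, sd = .5), a2 = f + stats::rnorm(4000, sd = .5),
          a3 = f + stats::rnorm(4000, sd = .5), b1 = b + stats::rnorm(4000, sd = .5),
          b2 = b + stats::rnorm(4000, sd = .5), b3 = b + stats::rnorm(4000, sd = .5))
  }))
  path <- fitA@params$std[fitA@params$op == "~"]
  expect_equal(latentRsquared(fitA, "B"), path^2, tolerance = 1e-8)
})

test_that("Heywood cases are flagged, never truncated", {
  R <- namedCor(matrix(c(1, .8, .82, .8, 1, .5, .82, .5, 1), 3), c("x1", "x2", "x3"))
  mom <- sampleMoments(R = R, sd = rep(1, 3), n = 200)
  expect_warning(fit <- semFit("F =~ x1 + x2 + x3\nF ~~ 1*F", mom), "Heywood")
  expect_true(fit@heywood)
  expect_lt(min(fit@params$est[fit@params$op == "~~"]), 0)
})
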