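test_that("the severity model parses with the documented free-parameter structure", {
  spec <- parseModel(modelASyntax())
  expect_s4_class(spec, "ModelSpec")
  expect_identical(length(spec@observed), 12L)
  expect_identical(spec@latents, c("Severity", "AlcoholUse", "Affective", "Motivation"))

  pt <- spec@ptable
  marker <- pt[pt$op == "=~" & pt$rhs == "ADS", ]
  expect_false(marker$free)
  expect_identical(marker$value, 1)
  expect_identical(sum(pt$free & pt$op == "=~" & pt$lhs == "Severity"), 4L)

  expect_identical(countFreeParameters(spec), 30L)
  expect_identical(degreesOfFreedom(spec), 48L)
  expect_true(checkIdentification(spec)$identified)
})

test_that("degrees of freedom follow the moment-count arithmetic", {
  # saturated covariance model on 3 variables: 6 free moments, df 0
  sat <- parseModel("x1 ~~ x2\nx1 ~~ x3\nx2 ~~ x3")
  expect_identical(countFreeParameters(sat), 6L)
  expect_identical(degreesOfFreedom(sat), 0L)

  # one factor, 3 indicators, marker fixed: 2 loadings + 3 residuals + 1 variance
  onef <- parseModel(oneFactorSyntax)
  expect_identical(countFreeParameters(onef), 6L)
  expect_identical(degreesOfFreedom(onef), 0L)

  # df is invariant under reordering of the observed variables
  reord <- parseModel("Severity =~ 1*ADS + CIWA + DRINC + COUNT + PACS
                       AlcoholUse =~ BINGE_PCT + DPDD
                       Affective =~ BDI + BAI
                       Motivation =~ AMBIV + RECOG + STEPS
                       Severity ~ Motivation + Affective + AlcoholUse
                       AlcoholUse ~~ 1*AlcoholUse
                       Affective ~~ 1*Affective
                       Motivation ~~ 1*Motivation
                       AlcoholUse ~~ Affective
                       AlcoholUse ~~ Motivation
                       Affective ~~ Motivation")
  expect_identical(degreesOfFreedom(reord), 48L)

  # freeing one more parameter drops df by exactly 1
  plus <- parseModel(paste(modelASyntax(), "BAI ~~ BDI", sep = "\n"))
  expect_identical(degreesOfFreedom(plus), 47L)
})

test_that("serialization round-trips the parsed model", {
  for (txt in list(modelASyntax(), modelBSyntax(), oneFactorSyntax, twoFactorSyntax)) {
    spec <- parseModel(txt)
    back <- parseModel(modelSyntax(spec))
    expect_identical(back@observed, spec@observed)
    expect_identical(back@latents, spec@latents)
    expect_equal(back@ptable, spec@ptable)
  }
})

test_that("identification rules flag scale-less and doubly-scaled factors", {
  single <- parseModel("F =~ x1")
  chk <- checkIdentification(single)
  expect_false(chk$identified)
  expect_match(paste(chk$problems, collapse = " "), "no scale|free parameters")

  both <- parseModel("F =~ 1*x1 + x2 + x3\nF ~~ 1*F")
  chk2 <- checkIdentification(both)
  expect_false(chk2$identified)
  expect_match(paste(chk2$problems, collapse = " "), "both")
})

test_that("malformed syntax raises named errors", {
  expect_error(parseModel("F =~ x1 + 2x"), "line 1")
  expect_error(parseModel("F =~ 1*x1 + x2 + x3\nF =~ 2*x1"), "contradictory")
  expect_error(parseModel("F =~ x1 + x2\nF =~ x1"), "duplicate")
  expect_error(parseModel("F =~ x1 + x2 + x3\nF ~ x1"), "not a declared latent")
})

test_that("shared labels collapse to one free parameter", {
  spec <- parseModel("F =~ 1*x1 + lam*x2 + lam*x3")
  expect_identical(countFreeParameters(spec), 5L)  # 1 shared loading + 3 resid + 1 var
  spec2 <- parseModel("F =~ 1*x1 + a*x2 + b*x3")
  expect_identical(countFreeParameters(spec2), 6L)
  expect_identical(degreesOfFreedom(spec2) - degreesOfFreedom(spec), -1L)
})

test_that("YAML model descriptions parse to the same spec as the text grammar", {
  ytxt <- "
loadings:
  F:
    - 1*x1
    - x2
    - x3
"
  expect_equal(parseModelYAML(ytxt)@ptable, parseModel(oneFactorSyntax)@ptable)
})
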