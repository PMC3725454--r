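test_that("the bundled moment table loads with its published values", {
  mom <- table1Moments()
  expect_s4_class(mom, "SampleMoments")
  expect_identical(ncol(mom@S), 12L)
  expect_identical(mom@n, 283)
  expect_equal(unname(mom@means[1]), 40.25)
  expect_identical(colnames(mom@S)[12], "BINGE_PCT")
  expect_true(isTRUE(all.equal(mom@S, t(mom@S))))
})

test_that("moment CSV validation names the offending cell", {
  one <- tempfile(fileext = ".csv")
  writeLines(c("# n = 50", "var,X", "mean,1.5", "sd,2", "X,1"), one)
  m1 <- readMomentsCSV(one)
  expect_identical(ncol(m1@S), 1L)
  expect_equal(unname(m1@S[1, 1]), 4)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("# n = 50", "var,X,Y", "mean,0,0", "sd,1,1", "X,1,1.2", "Y,1.2,1"), bad)
  expect_error(readMomentsCSV(bad), "out of range at \\((X, Y|Y, X)\\)")

  nonsq <- tempfile(fileext = ".csv")
  writeLines(c("# n = 50", "var,X,Y", "mean,0,0", "sd,1,1", "X,1,0.2"), nonsq)
  expect_error(readMomentsCSV(nonsq), "not square")

  noN <- tempfile(fileext = ".csv")
  writeLines(c("var,X", "mean,0", "sd,1", "X,1"), noN)
  expect_error(readMomentsCSV(noN), "sample size")
  expect_identical(readMomentsCSV(noN, n = 40)@n, 40)
})

test_that("raw CSV round-trips moments and listwise-deletes with a logged count", {
  sp <- syntheticSpec(namedCor(matrix(c(1, .4, .4, 1), 2), c("a", "b")),
                      sds = c(2, 3), means = c(10, 20), n = 294, seed = 17)
  x <- generateSample(sp)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(x, f, row.names = FALSE)
  y <- readRawCSV(f)
  expect_equal(as.matrix(y), as.matrix(x), tolerance = 1e-12, ignore_attr = TRUE)

  # punch 11 incomplete rows into 294: 283 retained, count reported
  x2 <- x
  x2$a[seq_len(11)] <- NA
  utils::write.csv(x2, f, row.names = FALSE)
  expect_message(y2 <- readRawCSV(f), "11 of 294 rows dropped.*283 retained")
  expect_identical(nrow(y2), 283L)

  # a single nonempty group level is a grouping error
  x3 <- cbind(g = "only", x)
  utils::write.csv(x3, f, row.names = FALSE)
  expect_error(suppressMessages(readRawCSV(f, groupColumn = "g")), "group levels")
  expect_error(readRawCSV(f, groupColumn = "missing"), "not found")

  xbad <- x
  xbad$a <- as.character(xbad$a); xbad$a[3] <- "oops"
  utils::write.csv(xbad, f, row.names = FALSE)
  expect_error(readRawCSV(f), "non-numeric cell at row 3")
})

test_that("fit artifacts serialize to JSON and TSV", {
  fit <- semFit(modelASyntax(), table1Moments())
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".tsv")
  writeFitJSON(fit, jf)
  writeParameterTSV(fit, tf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$df, 48)
  expect_equal(parsed$n, 283)
  expect_identical(length(parsed$theta), 30L)
  tab <- utils::read.delim(tf)
  expect_identical(nrow(tab), nrow(fit@params))
})

test_that("the command line dispatches, validates and reports status codes", {
  expect_identical(cliMain(character(0)), 0L)                 # usage text
  expect_identical(suppressMessages(cliMain("nonsense")), 2L)
  # invariance without raw data is a usage error
  expect_identical(suppressMessages(cliMain(c("invariance", "--moments", "x.csv"))), 2L)

  out <- tempfile()
  mfile <- system.file("extdata", "table1_moments.csv", package = "sevsem")
  amodel <- system.file("extdata", "model_a.txt", package = "sevsem")
  st <- suppressMessages(cliMain(c("fit", "--moments", mfile, "--model", amodel,
                                   "--out", out)))
  expect_identical(st, 0L)
  expect_true(file.exists(file.path(out, "fit.json")))
  expect_true(file.exists(file.path(out, "parameters.tsv")))

  # simulate writes a reproducible CSV
  sf1 <- tempfile(fileext = ".csv"); sf2 <- tempfile(fileext = ".csv")
  expect_identical(suppressMessages(cliMain(c("simulate", "--moments", mfile,
                                              "--n", "60", "--seed", "9",
                                              "--out", sf1))), 0L)
  expect_identical(suppressMessages(cliMain(c("simulate", "--moments", mfile,
                                              "--n", "60", "--seed", "9",
                                              "--out", sf2))), 0L)
  expect_identical(readLines(sf1), readLines(sf2))
})
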