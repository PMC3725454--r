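# CSV readers for moment tables and raw score tables; JSON/TSV writers.
# One dialect throughout: comma separator, "." decimal, UTF-8.

#' Read a moment table (correlation + SD + mean) from CSV
#'
#' Layout: an optional leading comment line \code{# n = <int>}; a header row
#' whose first cell is a row-label column followed by the variable names;
#' a \code{mean} row; an \code{sd} row; then the square correlation block,
#' one labelled row per variable. The bundled study table ships in this
#' layout.
#'
#' @param path CSV file path.
#' @param n sample size; overrides any \code{# n = ...} header line.
#' @return a [SampleMoments-class] built from the correlations and SDs.
#' @export
readMomentsCSV <- function(path, n = NULL) {
  lines <- readLines(path)
  nHeader <- grep("^#\\s*n\\s*=\\s*[0-9]+", lines, value = TRUE)
  if (is.null(n)) {
    if (!length(nHeader)) stop("sample size not given: add '# n = <int>' or pass n", call. = FALSE)
    n <- as.integer(sub("^#\\s*n\\s*=\\s*([0-9]+).*$", "\\1", nHeader[1]))
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  rlab <- as.character(tab[[1]])
  vars <- names(tab)[-1]
  p <- length(vars)
  num <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(num)) stop("non-numeric cell in moment table", call. = FALSE)

  mi <- match("mean", rlab); si <- match("sd", rlab)
  if (is.na(mi) || is.na(si)) stop("moment table must contain 'mean' and 'sd' rows", call. = FALSE)
  means <- num[mi, ]; sds <- num[si, ]
  corRows <- setdiff(seq_along(rlab), c(mi, si))
  if (length(corRows) != p) {
    stop(sprintf("correlation block is not square: %d rows for %d variables",
                 length(corRows), p), call. = FALSE)
  }
  R <- num[corRows, , drop = FALSE]
  rownames(R) <- rlab[corRows]
  if (!identical(rownames(R), vars)) {
    stop("correlation block row labels must match the header variables, in order", call. = FALSE)
  }
  for (j in seq_len(p)) {
    if (abs(R[j, j] - 1) > 1e-8) {
      stop(sprintf("non-unit diagonal at (%s, %s)", vars[j], vars[j]), call. = FALSE)
    }
  }
  bad <- which(abs(R) > 1 + 1e-8, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("correlation out of range at (%s, %s)",
                 vars[bad[1, 1]], vars[bad[1, 2]]), call. = FALSE)
  }
  if (any(sds <= 0)) {
    stop(sprintf("nonpositive SD for %s", vars[which(sds <= 0)[1]]), call. = FALSE)
  }
  asym <- max(abs(R - t(R)))
  if (asym > 1e-12) {
    if (asym > 1e-8) stop("correlation block asymmetric beyond tolerance", call. = FALSE)
    R <- symmetrize(R)
  }
  dimnames(R) <- list(vars, vars)
  sampleMoments(R = R, sd = sds, n = n, means = means)
}

#' Read a raw score table from CSV
#'
#' Expects a header row and a numeric body; incomplete rows are
#' listwise-deleted with a message reporting the count. An optional group
#' column is split off and returned alongside the scores.
#'
#' @param path CSV file path.
#' @param groupColumn optional name of a grouping column.
#' @return data.frame of complete-case scores; when \code{groupColumn} is
#'   given, a list with elements \code{data} and \code{groups}.
#' @export
readRawCSV <- function(path, groupColumn = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  grp <- NULL
  if (!is.null(groupColumn)) {
    if (!groupColumn %in% names(tab)) {
      stop(sprintf("group column '%s' not found", groupColumn), call. = FALSE)
    }
    grp <- as.character(tab[[groupColumn]])
    tab[[groupColumn]] <- NULL
  }
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))) & !is.na(tab[[j]]))[1]
      stop(sprintf("non-numeric cell at row %d, column '%s'", bad, names(tab)[j]),
           call. = FALSE)
    }
  }
  complete <- stats::complete.cases(tab)
  if (!is.null(grp)) complete <- complete & !is.na(grp) & nzchar(grp)
  nDropped <- sum(!complete)
  if (nDropped > 0) {
    message(sprintf("listwise deletion: %d of %d rows dropped (incomplete), %d retained",
                    nDropped, nrow(tab), sum(complete)))
  }
  tab <- tab[complete, , drop = FALSE]
  if (!is.null(grp)) {
    grp <- grp[complete]
    if (length(unique(grp)) < 2L) stop("grouping error: fewer than two nonempty group levels",
                                       call. = FALSE)
    return(list(data = tab, groups = grp))
  }
  tab
}

#' Write a fitted model as JSON
#'
#' Serializes the estimates, implied covariance, discrepancy, chi-square,
#' df, fit indices, convergence diagnostics and the parameter table.
#'
#' @param fit a [SemFit-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFitJSON <- function(fit, path) {
  idx <- fitMeasures(fit)
  obj <- list(
    observed = fit@spec@observed,
    latents = fit@spec@latents,
    n = fit@moments@n,
    theta = as.list(fit@theta),
    fml = fit@fml, chisq = fit@tml, df = fit@df,
    fitIndices = as.list(idx),
    converged = fit@converged, iterations = fit@iterations,
    gradNorm = fit@gradNorm, heywood = fit@heywood,
    impliedCov = fit@sigma,
    parameters = fit@params
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the parameter table as TSV
#'
#' @param fit a [SemFit-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeParameterTSV <- function(fit, path) {
  utils::write.table(fit@params, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
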