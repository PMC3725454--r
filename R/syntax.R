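# Model-syntax parser. Grammar (one statement per line, "#" comments):
#   factor =~ ind1 + ind2 + 1*ind3     loadings; numeric*var fixes the value
#   target ~ pred1 + pred2             structural regressions among latents
#   a ~~ b                             (co)variance; a ~~ 1*a fixes a variance
#   label*var                          non-numeric prefix = shared-label equality
# Residual/disturbance variances are added automatically (free) for every
# observed variable and every latent without an explicit variance entry.

.parseToken <- function(tok, lineno) {
  tok <- trimws(tok)
  m <- regmatches(tok, regexec("^(?:([^*[:space:]]+)\\*)?\\s*([A-Za-z._][A-Za-z0-9._]*)$",
                               tok, perl = TRUE))[[1]]
  if (length(m) == 0L || m[3] == "") {
    stop(sprintf("parse error on line %d: bad token '%s'", lineno, tok), call. = FALSE)
  }
  mod <- m[2]
  if (mod == "") return(list(var = m[3], fixed = NA_real_, label = NA_character_))
  val <- suppressWarnings(as.numeric(mod))
  if (!is.na(val)) list(var = m[3], fixed = val, label = NA_character_)
  else list(var = m[3], fixed = NA_real_, label = mod)
}

#' Parse model syntax into a ModelSpec
#'
#' Parses a lavaan-style model definition (see the package README for the
#' grammar) into a [ModelSpec-class]. Latents are the left-hand sides of
#' \code{=~} statements; every other mentioned name is an observed variable.
#' Residual variances for observed variables and variances/disturbances for
#' latents are added as free parameters unless the text fixes them.
#'
#' @param text a model-definition string (or character vector of lines).
#' @return a validated [ModelSpec-class].
#' @examples
#' spec <- parseModel("
#'   F =~ x1 + x2 + x3
#'   F ~~ 1*F")
#' countFreeParameters(spec)
#' @export
parseModel <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))

  rows <- list()
  addRow <- function(op, lhs, rhs, fixed, label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      lhs = lhs, op = op, rhs = rhs,
      value = fixed, label = label, stringsAsFactors = FALSE)
  }

  for (i in keep) {
    line <- trimws(lines[i])
    op <- if (grepl("=~", line, fixed = TRUE)) "=~"
          else if (grepl("~~", line, fixed = TRUE)) "~~"
          else if (grepl("~", line, fixed = TRUE)) "~"
          else stop(sprintf("parse error on line %d: no operator in '%s'", i, line), call. = FALSE)
    parts <- strsplit(line, op, fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("parse error on line %d: expected 'lhs %s rhs'", i, op), call. = FALSE)
    }
    lhsTok <- .parseToken(parts[1], i)
    if (!is.na(lhsTok$fixed) || !is.na(lhsTok$label)) {
      stop(sprintf("parse error on line %d: left-hand side cannot carry a modifier", i), call. = FALSE)
    }
    for (rtok in strsplit(parts[2], "+", fixed = TRUE)[[1]]) {
      tk <- .parseToken(rtok, i)
      addRow(op, lhsTok$var, tk$var, tk$fixed, tk$label)
    }
  }
  if (!length(rows)) stop("empty model syntax", call. = FALSE)
  tab <- do.call(rbind, rows)

  latents <- unique(tab$lhs[tab$op == "=~"])
  mentioned <- unique(c(tab$lhs, tab$rhs))
  observed <- setdiff(unique(c(tab$rhs[tab$op == "=~"],
                               mentioned)), latents)
  allv <- c(observed, latents)

  reg <- tab[tab$op == "~", , drop = FALSE]
  if (nrow(reg)) {
    bad <- setdiff(c(reg$lhs, reg$rhs), latents)
    if (length(bad)) {
      stop(sprintf("specification error: structural path endpoint '%s' is not a declared latent",
                   bad[1]), call. = FALSE)
    }
  }
  endogenous <- unique(reg$lhs)

  # assemble RAM-slot entries
  ent <- list()
  addEnt <- function(lhs, op, rhs, mat, row, col, value, label) {
    ent[[length(ent) + 1L]] <<- data.frame(
      lhs = lhs, op = op, rhs = rhs, mat = mat, row = row, col = col,
      free = is.na(value), value = value, label = label, stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(tab))) {
    r <- tab[k, ]
    if (r$op == "=~") addEnt(r$lhs, "=~", r$rhs, "A", r$rhs, r$lhs, r$value, r$label)
    else if (r$op == "~") addEnt(r$lhs, "~", r$rhs, "A", r$lhs, r$rhs, r$value, r$label)
    else {
      a <- r$lhs; b <- r$rhs
      ord <- order(match(c(a, b), allv))
      pair <- c(a, b)[ord]
      addEnt(pair[1], "~~", pair[2], "S", pair[1], pair[2], r$value, r$label)
    }
  }
  pt <- do.call(rbind, ent)

  # duplicate / contradiction checks
  key <- paste(pt$mat, pt$row, pt$col)
  if (anyDuplicated(key)) {
    dups <- key[duplicated(key)]
    fixvals <- pt$value[key %in% dups & !pt$free]
    if (length(unique(stats::na.omit(fixvals))) > 1L) {
      stop(sprintf("specification error: contradictory fixed values for %s", dups[1]),
           call. = FALSE)
    }
    stop(sprintf("specification error: duplicate parameter entry %s", dups[1]), call. = FALSE)
  }

  # auto variances
  for (v in allv) {
    if (!any(pt$mat == "S" & pt$row == v & pt$col == v)) {
      pt <- rbind(pt, data.frame(lhs = v, op = "~~", rhs = v, mat = "S",
                                 row = v, col = v, free = TRUE,
                                 value = NA_real_, label = NA_character_,
                                 stringsAsFactors = FALSE))
    }
  }

  # canonical ordering: loadings (latent order, indicator order), regressions,
  # then S entries by (col, row) variable order
  vidx <- function(x) match(x, allv)
  ptA1 <- pt[pt$op == "=~", , drop = FALSE]
  ptA1 <- ptA1[order(match(ptA1$col, latents), vidx(ptA1$row)), , drop = FALSE]
  ptA2 <- pt[pt$op == "~", , drop = FALSE]
  ptA2 <- ptA2[order(vidx(ptA2$row), vidx(ptA2$col)), , drop = FALSE]
  ptS <- pt[pt$op == "~~", , drop = FALSE]
  ptS <- ptS[order(vidx(ptS$col), vidx(ptS$row)), , drop = FALSE]
  pt <- rbind(ptA1, ptA2, ptS)
  rownames(pt) <- NULL

  # free-parameter ids; shared labels share an id
  pt$id <- 0L
  nextId <- 0L
  lab2id <- list()
  for (k in seq_len(nrow(pt))) {
    if (!pt$free[k]) next
    lb <- pt$label[k]
    if (!is.na(lb) && !is.null(lab2id[[lb]])) {
      pt$id[k] <- lab2id[[lb]]
    } else {
      nextId <- nextId + 1L
      pt$id[k] <- nextId
      if (!is.na(lb)) lab2id[[lb]] <- nextId
    }
  }

  spec <- new("ModelSpec", observed = observed, latents = latents,
              endogenous = as.character(endogenous), ptable = pt, syntax = "")
  spec@syntax <- modelSyntax(spec)
  validObject(spec)
  spec
}

#' Serialize a ModelSpec back to model syntax
#'
#' Produces canonical model-definition text; \code{parseModel(modelSyntax(x))}
#' reproduces \code{x} exactly.
#'
#' @param spec a [ModelSpec-class].
#' @return a single string.
#' @export
modelSyntax <- function(spec) {
  pt <- spec@ptable
  tok <- function(r) {
    pre <- if (!r$free) paste0(format(r$value, trim = TRUE), "*")
           else if (!is.na(r$label)) paste0(r$label, "*")
           else ""
    paste0(pre, if (r$op == "=~") r$row else r$col)
  }
  out <- character()
  for (f in spec@latents) {
    rowsk <- which(pt$op == "=~" & pt$col == f)
    if (length(rowsk)) {
      out <- c(out, paste(f, "=~", paste(vapply(rowsk, function(k) tok(pt[k, ]), ""),
                                         collapse = " + ")))
    }
  }
  for (tgt in unique(pt$row[pt$op == "~"])) {
    rowsk <- which(pt$op == "~" & pt$row == tgt)
    out <- c(out, paste(tgt, "~", paste(vapply(rowsk, function(k) tok(pt[k, ]), ""),
                                        collapse = " + ")))
  }
  for (k in which(pt$op == "~~")) {
    r <- pt[k, ]
    pre <- if (!r$free) paste0(format(r$value, trim = TRUE), "*")
           else if (!is.na(r$label)) paste0(r$label, "*")
           else ""
    out <- c(out, paste(r$row, "~~", paste0(pre, r$col)))
  }
  paste(out, collapse = "\n")
}

#' Identification check
#'
#' Applies the scale-setting rule: every latent factor must fix either one
#' loading (marker) or its own variance — at least one and never both — and
#' the model must not have more free parameters than sample moments.
#'
#' @param spec a [ModelSpec-class].
#' @return list with elements \code{identified} (logical) and
#'   \code{problems} (character vector).
#' @export
checkIdentification <- function(spec) {
  pt <- spec@ptable
  problems <- character()
  for (f in spec@latents) {
    markerFixed <- any(pt$op == "=~" & pt$col == f & !pt$free)
    varFixed <- any(pt$mat == "S" & pt$row == f & pt$col == f & !pt$free)
    if (markerFixed && varFixed) {
      problems <- c(problems, sprintf("latent '%s' fixes both a marker loading and its variance", f))
    }
    if (!markerFixed && !varFixed) {
      problems <- c(problems, sprintf("latent '%s' has no scale: fix a marker loading or its variance", f))
    }
    nind <- sum(pt$op == "=~" & pt$col == f)
    if (nind == 1L && !(f %in% spec@endogenous) && markerFixed == FALSE) {
      problems <- c(problems, sprintf("latent '%s' is a single-indicator factor without fixed scale", f))
    }
  }
  if (degreesOfFreedom(spec, stop.on.negative = FALSE) < 0) {
    problems <- c(problems, "more free parameters than sample moments (df < 0)")
  }
  list(identified = length(problems) == 0L, problems = problems)
}

#' Number of distinct free parameters
#'
#' Counts free parameters after collapsing shared-label equality constraints.
#'
#' @param spec a [ModelSpec-class].
#' @return nonnegative integer.
#' @export
countFreeParameters <- function(spec) {
  ids <- spec@ptable$id[spec@ptable$free]
  if (!length(ids)) 0L else max(ids)
}

#' Model degrees of freedom
#'
#' \code{p(p+1)/2} sample moments minus the number of distinct free
#' parameters.
#'
#' @param spec a [ModelSpec-class].
#' @param p number of observed variables; defaults to the spec's count.
#' @param stop.on.negative error on over-parameterized models (default TRUE).
#' @return nonnegative integer.
#' @export
degreesOfFreedom <- function(spec, p = length(spec@observed), stop.on.negative = TRUE) {
  if (p != length(spec@observed)) {
    stop("p must equal the model's observed-variable count", call. = FALSE)
  }
  df <- p * (p + 1) / 2 - countFreeParameters(spec)
  if (df < 0 && stop.on.negative) {
    stop("over-parameterized model: negative degrees of freedom", call. = FALSE)
  }
  as.integer(df)
}

#' Parse a YAML model description
#'
#' Accepts the same model as [parseModel()] in YAML form: top-level keys
#' \code{loadings} (factor -> list of indicator tokens), \code{regressions}
#' (target -> list of predictors) and \code{covariances} (list of
#' \code{[a, b]} or \code{[a, "1*b"]} pairs). Tokens use the same
#' \code{value*name} / \code{label*name} convention as the text grammar.
#'
#' @param x YAML text or a file path.
#' @return a [ModelSpec-class].
#' @export
parseModelYAML <- function(x) {
  y <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  out <- character()
  for (f in names(y$loadings)) {
    out <- c(out, paste(f, "=~", paste(unlist(y$loadings[[f]]), collapse = " + ")))
  }
  for (tgt in names(y$regressions)) {
    out <- c(out, paste(tgt, "~", paste(unlist(y$regressions[[tgt]]), collapse = " + ")))
  }
  for (pair in y$covariances) {
    out <- c(out, paste(pair[[1]], "~~", pair[[2]]))
  }
  parseModel(paste(out, collapse = "\n"))
}
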