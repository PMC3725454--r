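# Simultaneous multi-group estimation with cross-group equality constraints
# and Lagrange-multiplier release tests.

# which within-group free-parameter ids fall in each constrainable family
constrainableIds <- function(spec, constrain) {
  pt <- spec@ptable
  ids <- integer(0)
  if ("loadings" %in% constrain) ids <- c(ids, pt$id[pt$free & pt$op == "=~"])
  if ("regressions" %in% constrain) ids <- c(ids, pt$id[pt$free & pt$op == "~"])
  if ("factor_covariances" %in% constrain) {
    ids <- c(ids, pt$id[pt$free & pt$op == "~~" & pt$row != pt$col &
                          pt$row %in% spec@latents & pt$col %in% spec@latents])
  }
  if ("variances" %in% constrain) ids <- c(ids, pt$id[pt$free & pt$op == "~~" & pt$row == pt$col])
  sort(unique(ids))
}

#' Fit one model simultaneously in several groups
#'
#' Minimizes the sample-size-weighted sum of per-group ML discrepancies,
#' \code{sum_g (n_g - 1) F_g}, with selected parameter families constrained
#' equal across groups. By default all free loadings, structural paths and
#' factor covariances are constrained; residual variances stay
#' group-specific.
#'
#' @param spec a [ModelSpec-class] shared by all groups.
#' @param groups named list of [SampleMoments-class] (two or more), identical
#'   variable sets.
#' @param constrain character subset of \code{c("loadings", "regressions",
#'   "factor_covariances", "variances")}, or an integer vector of
#'   within-group free-parameter ids.
#' @param control optimizer control overrides.
#' @return a [MultiGroupFit-class].
#' @export
fitMultigroup <- function(spec, groups,
                          constrain = c("loadings", "regressions", "factor_covariances"),
                          control = list()) {
  if (length(groups) < 1L) stop("at least one group required", call. = FALSE)
  G <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(G))
  vars <- spec@observed
  for (g in groups) {
    if (!all(vars %in% colnames(g@S))) stop("all groups must contain the model variables", call. = FALSE)
    if (g@n <= length(vars)) stop("insufficient data: a group has n <= p", call. = FALSE)
  }
  idc <- checkIdentification(spec)
  if (!idc$identified) stop("model not identified: ", paste(idc$problems, collapse = "; "), call. = FALSE)

  skel <- ramSkeleton(spec)
  slots <- ramDerivSlots(skel)
  q <- skel$q
  conIds <- if (is.numeric(constrain)) sort(unique(as.integer(constrain)))
            else constrainableIds(spec, constrain)
  conIds <- conIds[conIds >= 1L & conIds <= q]

  # joint index map: constrained ids share one joint slot across groups
  map <- matrix(0L, q, G)
  nextJ <- 0L
  shared <- integer(q)
  for (k in seq_len(q)) {
    if (k %in% conIds) { nextJ <- nextJ + 1L; shared[k] <- nextJ }
  }
  for (g in seq_len(G)) {
    for (k in seq_len(q)) {
      if (shared[k] > 0L) map[k, g] <- shared[k]
      else { nextJ <- nextJ + 1L; map[k, g] <- nextJ }
    }
  }
  qJ <- nextJ
  nVec <- unname(vapply(groups, function(g) g@n, numeric(1)))
  N <- sum(nVec)
  wts <- (nVec - 1) / (N - G)

  Slist <- lapply(groups, function(g) g@S[vars, vars, drop = FALSE])
  fos <- lapply(Slist, function(S) semObjective(skel, slots, S, logDetPD(S)))

  # start: group-specific from each group's moments, shared slots averaged
  startJ <- numeric(qJ)
  cnt <- numeric(qJ)
  for (g in seq_len(G)) {
    st <- semStartValues(spec, skel, Slist[[g]])
    startJ[map[, g]] <- startJ[map[, g]] + st
    cnt[map[, g]] <- cnt[map[, g]] + 1
  }
  startJ <- startJ / pmax(cnt, 1)

  fo <- function(thJ) {
    v <- 0
    for (g in seq_len(G)) v <- v + wts[g] * fos[[g]]$obj(thJ[map[, g]])
    v
  }
  gro <- function(thJ) {
    gr <- numeric(qJ)
    for (g in seq_len(G)) {
      gg <- fos[[g]]$grad(thJ[map[, g]])
      gr[map[, g]] <- gr[map[, g]] + wts[g] * gg
    }
    gr
  }
  ctrl <- utils::modifyList(list(iter.max = 10000, eval.max = 20000,
                                 rel.tol = 1e-12, abs.tol = 0), control)
  pscale <- function(s) 1 / pmax(abs(s), 1e-2)
  opt <- stats::nlminb(startJ, fo, gradient = gro, scale = pscale(startJ),
                       control = ctrl)
  gnorm <- max(abs(gro(opt$par)))
  if (gnorm > 1e-6) {
    o2 <- stats::nlminb(opt$par, fo, gradient = gro, scale = pscale(opt$par),
                        control = ctrl)
    if (o2$objective <= opt$objective + 1e-12) opt <- o2
    gnorm <- max(abs(gro(opt$par)))
  }
  thetaJ <- opt$par
  # Newton polish on the joint expected information
  for (it in seq_len(10)) {
    gr <- gro(thetaJ)
    if (max(abs(gr)) < 1e-10) break
    HJ <- matrix(0, qJ, qJ)
    ok <- TRUE
    for (g in seq_len(G)) {
      dd <- tryCatch(ramDifferentials(skel, slots, thetaJ[map[, g]],
                                      Sobs = Slist[[g]], jacobian = TRUE),
                     error = function(e) NULL)
      if (is.null(dd) || !isPositiveDefinite(dd$sigma)) { ok <- FALSE; break }
      Hg <- 2 * wts[g] * symmetrize(crossprod(dd$jacobian,
                                              normalTheoryWeight(dd$sigma) %*% dd$jacobian))
      HJ[map[, g], map[, g]] <- HJ[map[, g], map[, g]] + Hg
    }
    if (!ok) break
    step <- tryCatch(solve(symmetrize(HJ), gr), error = function(e) NULL)
    if (is.null(step)) break
    cand <- thetaJ - step
    if (fo(cand) <= fo(thetaJ) + 1e-12) thetaJ <- cand else break
  }
  gnorm <- max(abs(gro(thetaJ)))

  perGroup <- vector("list", G)
  tml <- 0
  converged <- gnorm <= 1e-4
  for (g in seq_len(G)) {
    th <- thetaJ[map[, g]]
    d <- ramDifferentials(skel, slots, th, Sobs = Slist[[g]], jacobian = TRUE)
    fml_g <- fos[[g]]$obj(th)
    tml <- tml + (nVec[g] - 1) * fml_g
    converged <- converged && isPositiveDefinite(d$sigma)
    perGroup[[g]] <- list(theta = th, sigma = d$sigma, fml = fml_g,
                          delta = d$jacobian, w = normalTheoryWeight(d$sigma))
  }
  names(perGroup) <- names(groups)
  p <- length(vars)
  dfTotal <- G * p * (p + 1) / 2 - qJ

  new("MultiGroupFit", spec = spec, groups = groups, theta = thetaJ,
      map = map, constrained = as.integer(conIds), tml = tml,
      df = as.numeric(dfTotal), perGroup = perGroup,
      converged = converged, gradNorm = gnorm)
}

#' Lagrange multiplier test for releasing an equality constraint
#'
#' Score test at the constrained optimum: for each cross-group equality
#' class, the predicted chi-square drop from letting that parameter differ
#' between groups, computed from the gradient and expected information of
#' the weighted discrepancy without refitting. Asymptotically equal to the
#' likelihood-ratio drop from the explicit release.
#'
#' @param fit a converged [MultiGroupFit-class].
#' @param ids within-group parameter ids to test; defaults to every
#'   constrained class.
#' @return data.frame with columns \code{id, parameter, lm, df, pvalue}.
#' @export
lmReleaseTest <- function(fit, ids = fit@constrained) {
  if (!length(fit@constrained)) stop("no active equality constraints", call. = FALSE)
  if (!all(ids %in% fit@constrained)) stop("constraint not active", call. = FALSE)
  G <- length(fit@groups)
  q <- nrow(fit@map)
  nVec <- vapply(fit@groups, function(g) g@n, numeric(1))
  qJ <- length(fit@theta)

  # unconstrained space: q parameters per group; chi-square-scale gradient
  # and expected information
  skel <- ramSkeleton(fit@spec)
  slots <- ramDerivSlots(skel)
  vars <- fit@spec@observed
  gU <- numeric(q * G)
  Hblocks <- vector("list", G)
  for (g in seq_len(G)) {
    pg <- fit@perGroup[[g]]
    Sg <- fit@groups[[g]]@S[vars, vars, drop = FALSE]
    d <- ramDifferentials(skel, slots, pg$theta, Sobs = Sg)
    gU[(g - 1) * q + seq_len(q)] <- (nVec[g] - 1) * d$grad
    Hblocks[[g]] <- 2 * (nVec[g] - 1) * symmetrize(crossprod(pg$delta, pg$w %*% pg$delta))
  }

  # base mapping: unconstrained coordinates as a linear image of the joint
  # parameters; released classes add difference directions for groups 2..G
  Mbase <- matrix(0, q * G, qJ)
  for (g in seq_len(G)) for (k in seq_len(q)) {
    Mbase[(g - 1) * q + k, fit@map[k, g]] <- 1
  }

  out <- data.frame(id = integer(0), parameter = character(0),
                    lm = numeric(0), df = integer(0), pvalue = numeric(0))
  pnames <- paramNames(fit@spec)
  for (k in ids) {
    Mrel <- matrix(0, q * G, G - 1)
    for (g in 2:G) Mrel[(g - 1) * q + k, g - 1] <- 1
    M <- cbind(Mbase, Mrel)
    gA <- crossprod(M, gU)
    # H_u is block diagonal over groups; assemble M' H M blockwise
    HA <- matrix(0, ncol(M), ncol(M))
    for (g in seq_len(G)) {
      rows <- (g - 1) * q + seq_len(q)
      Mg <- M[rows, , drop = FALSE]
      HA <- HA + crossprod(Mg, Hblocks[[g]] %*% Mg)
    }
    lmStat <- tryCatch(
      0.5 * drop(crossprod(gA, solve(symmetrize(HA), gA))),
      error = function(e) NA_real_)
    lmStat <- max(lmStat, 0)
    out <- rbind(out, data.frame(
      id = k, parameter = pnames[k], lm = lmStat, df = G - 1L,
      pvalue = stats::pchisq(lmStat, G - 1L, lower.tail = FALSE)))
  }
  rownames(out) <- NULL
  out
}

#' Constraint-release recommendations
#'
#' Orders the active cross-group equality constraints by their Lagrange
#' multiplier statistics and flags those significant at \code{alpha}.
#'
#' @param fit a converged [MultiGroupFit-class].
#' @param alpha significance level (default 0.05).
#' @return data.frame sorted by decreasing LM with a logical \code{release}
#'   column.
#' @export
invarianceReport <- function(fit, alpha = 0.05) {
  lm <- lmReleaseTest(fit)
  lm <- lm[order(-lm$lm), ]
  lm$release <- lm$pvalue < alpha
  rownames(lm) <- NULL
  lm
}
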