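# Bayesian posterior score: psi-parameterised cross-link likelihood plus
# excluded-volume and sequence-connectivity priors. The numerics live in
# src/sampler.cpp; these wrappers build the index context and expose the
# components individually.

#' Scoring configuration
#'
#' Bundles the tunable scoring constants: the forward-model switching
#' distance \code{d0} (Angstrom; the distance at which the probability of
#' observing a cross-link falls to one half), its steepness \code{alpha}
#' (1/Angstrom), the excluded-volume and connectivity weights, and the
#' connectivity slack \code{dConn} (consecutive beads outside a common rigid
#' body are penalised quadratically beyond this distance).
#'
#' @param d0 cross-link switching distance, Angstrom. Either a single value
#'   applied to every link (default 20) or a named vector of per-linker
#'   values (e.g. \code{c(DSS = 30, DSG = 25)}, optionally with a
#'   \code{default} entry for unmatched chemistries), since the appropriate
#'   threshold depends on the cross-linker spacer length.
#' @param alpha forward-model steepness, 1/Angstrom (default 0.3)
#' @param kEv excluded-volume weight (default 1)
#' @param kC connectivity weight (default 1)
#' @param dConn connectivity slack, Angstrom (default 4)
#' @return named list of scoring constants
#' @export
scoringConfig <- function(d0 = 20, alpha = 0.3, kEv = 1, kC = 1, dConn = 4) {
  stopifnot(all(d0 > 0), alpha > 0, kEv >= 0, kC >= 0, dConn > 0)
  if (length(d0) > 1 && is.null(names(d0)))
    stop("a vector d0 must be named by linker type")
  list(d0 = d0, alpha = alpha, kEv = kEv, kC = kC, dConn = dConn)
}

# per-link switching distance from a scalar or linker-named d0
.linkD0 <- function(d0, linkers) {
  if (length(d0) == 1 && is.null(names(d0))) return(rep(d0, length(linkers)))
  out <- unname(d0[linkers])
  if (anyNA(out)) {
    if ("default" %in% names(d0)) out[is.na(out)] <- d0[["default"]]
    else stop("no d0 for linker(s): ",
              paste(unique(linkers[is.na(out)]), collapse = ", "))
  }
  out
}

#' Probability of observing a cross-link at a given distance
#'
#' The forward model is a logistic switch \code{f(d) = 1 / (1 +
#' exp(alpha (d - d0)))}; folding in the uncertainty parameter psi gives the
#' observation probability \code{p = psi + (1 - 2 psi) f(d)}. At \code{d =
#' d0} the probability is exactly 0.5 for every psi; p always lies between
#' \code{min(psi, 1 - psi)} and \code{max(psi, 1 - psi)}.
#'
#' @param d distance(s), Angstrom
#' @param psi uncertainty parameter in (0, 0.5]
#' @param d0 switching distance, Angstrom
#' @param alpha steepness, 1/Angstrom
#' @return observation probabilities, same length as \code{d}
#' @export
linkObservationProbability <- function(d, psi, d0 = 20, alpha = 0.3) {
  if (any(psi <= 0) || any(psi > 0.5))
    stop("psi must lie in (0, 0.5]")
  psi + (1 - 2 * psi) / (1 + exp(alpha * (d - d0)))
}

# map each cross-link to its psi class; linker-specific class when present
# in the psi vector, otherwise the "global" fallback
.psiClassOf <- function(psiPar, xls) {
  stopifnot(is(psiPar, "PsiParameters"), is(xls, "CrossLinkSet"))
  classes <- names(psiValues(psiPar))
  lk <- crossLinks(xls)$linker
  cls <- ifelse(lk %in% classes, lk,
                if ("global" %in% classes) "global" else NA_character_)
  if (anyNA(cls))
    stop("no psi class for linker(s): ",
         paste(unique(lk[is.na(cls)]), collapse = ", "),
         " (add them to PsiParameters or provide a 'global' class)")
  match(cls, classes)
}

# index context shared by the scoring wrappers and the sampler
.scoringContext <- function(model, xls = NULL, psiPar = NULL,
                            scoring = scoringConfig()) {
  stopifnot(is(model, "SystemModel"))
  n <- nBeads(model)
  compIdx <- match(model@component, unique(model@component))
  # sequence-consecutive pairs not inside one rigid body
  key <- paste0(model@component, ":", model@residue)
  nxt <- match(paste0(model@component, ":", model@residue + 1L), key)
  i <- which(!is.na(nxt))
  j <- nxt[i]
  cross <- !(model@bodyId[i] > 0L & model@bodyId[i] == model@bodyId[j])
  connPairs <- cbind(i[cross], j[cross])
  if (!nrow(connPairs)) connPairs <- matrix(integer(0), 0, 2)

  if (is.null(xls) || length(xls) == 0) {
    xlPairs <- matrix(integer(0), 0, 2)
    xlClass <- integer(0)
    xlD0 <- numeric(0)
  } else {
    df <- crossLinks(xls)
    xlPairs <- cbind(beadIndex(model, df$protein1, df$residue1),
                     beadIndex(model, df$protein2, df$residue2))
    xlClass <- .psiClassOf(psiPar, xls)
    xlD0 <- .linkD0(scoring$d0, df$linker)
  }
  list(coords = model@coords, radii = model@radii,
       comp = as.integer(compIdx), resid = model@residue,
       body = model@bodyId,
       bodyBeads = lapply(model@bodies, function(b) as.integer(b$beads)),
       flexBeads = as.integer(which(model@bodyId == 0L)),
       connPairs = connPairs, xlPairs = xlPairs,
       xlClass = as.integer(xlClass), xlD0 = xlD0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cppPar <- function(scoring, sampler = NULL, psiPar = NULL) {
  list(d0 = scoring$d0[[1]], alpha = scoring$alpha, kEv = scoring$kEv,
       kC = scoring$kC, dConn = scoring$dConn,
       maxTrans = sampler$maxTransRigid %||% 4,
       maxRot = sampler$maxRotRigid %||% 0.03,
       maxTransBead = sampler$maxTransBead %||% 5,
       psiSigma = sampler$psiMoveSigma %||% 0.02,
       psiMin = if (is.null(psiPar)) 0.01 else psiPar@psiMin,
       psiMax = 0.5,
       bodyRepeats = sampler$bodyRepeats %||% 1L)
}

.scoreComponents <- function(model, xls, psiPar, scoring, coords = NULL) {
  ctx <- .scoringContext(model, xls, psiPar, scoring)
  if (!is.null(coords)) ctx$coords <- coords
  cpp_score_full(ctx$coords, ctx$radii, ctx$comp, ctx$resid, ctx$body,
                 ctx$bodyBeads, ctx$flexBeads, ctx$connPairs, ctx$xlPairs,
                 ctx$xlClass, ctx$xlD0, psiValues(psiPar),
                 .cppPar(scoring, psiPar = psiPar))
}

#' Cross-link negative log likelihood
#'
#' For each cross-link n with bead distance d_n, the observation probability
#' is \code{p_n = psi + (1 - 2 psi) f(d_n)} with the logistic forward model
#' of [linkObservationProbability()]; the score is \code{-sum(log p_n)}.
#' Each link uses the psi value of its class (linker chemistry, or the
#' \code{global} fallback).
#'
#' @param model a [SystemModel-class]; all cross-linked residues must be housed
#' @param xls a non-empty [CrossLinkSet-class]
#' @param psi a [PsiParameters-class]
#' @param d0 switching distance, Angstrom
#' @param alpha steepness, 1/Angstrom
#' @return negative log likelihood (unitless)
#' @export
crosslinkNegLogLik <- function(model, xls, psi = PsiParameters(), d0 = 20,
                               alpha = 0.3) {
  if (length(xls) == 0) stop("cross-link set is empty")
  .scoreComponents(model, xls, psi,
                   scoringConfig(d0 = d0, alpha = alpha))[["xl_negloglik"]]
}

#' Excluded-volume penalty
#'
#' Soft-sphere penalty \code{kEv * sum(max(0, r_i + r_j - d_ij)^2)} over all
#' non-bonded bead pairs: pairs in different rigid units that are not
#' sequence-adjacent. Zero when no beads overlap.
#'
#' @param model a [SystemModel-class]
#' @param kEv weight
#' @return penalty (>= 0)
#' @export
excludedVolume <- function(model, kEv = 1.0) {
  .scoreComponents(model, NULL, PsiParameters(),
                   scoringConfig(kEv = kEv))[["excluded_volume"]]
}

#' Sequence-connectivity penalty
#'
#' For every pair of sequence-consecutive residues not housed in the same
#' rigid body, penalises separations beyond \code{dMax} as
#' \code{kC * max(0, d - dMax)^2}.
#'
#' @param model a [SystemModel-class]
#' @param dMax slack distance, Angstrom (default 4)
#' @param kC weight
#' @return penalty (>= 0)
#' @export
connectivityScore <- function(model, dMax = 4.0, kC = 1.0) {
  .scoreComponents(model, NULL, PsiParameters(),
                   scoringConfig(dConn = dMax, kC = kC))[["connectivity"]]
}

#' Total posterior score of a configuration
#'
#' Negative log posterior: cross-link negative log likelihood plus
#' excluded-volume and connectivity priors plus the psi negative log prior.
#' The psi prior is uniform on \code{(psiMin, 0.5]}, so its negative log is a
#' constant, reported as 0; psi values outside the support are an error at
#' [PsiParameters()] construction.
#'
#' @param model a [SystemModel-class]
#' @param xls a non-empty [CrossLinkSet-class]
#' @param psi a [PsiParameters-class]
#' @param scoring a [scoringConfig()] list
#' @return a [ScoreBreakdown-class]
#' @export
totalScore <- function(model, xls, psi = PsiParameters(),
                       scoring = scoringConfig()) {
  if (length(xls) == 0) stop("cross-link set is empty")
  s <- .scoreComponents(model, xls, psi, scoring)
  new("ScoreBreakdown",
      xlNegLogLik = s[["xl_negloglik"]],
      excludedVolume = s[["excluded_volume"]],
      connectivity = s[["connectivity"]],
      psiNegLogPrior = 0.0,
      total = s[["xl_negloglik"]] + s[["excluded_volume"]] +
        s[["connectivity"]] + 0.0)
}
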