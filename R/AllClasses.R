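#' @import methods
NULL

#' Quality-annotated chemical cross-link set
#'
#' Container for residue-pair records identified by cross-linking mass
#' spectrometry. Each record names two linked residues (component identifier
#' plus 1-based sequence position), the cross-linker chemistry, and the
#' identification quality scores used for filtering (id score, deltaS, FDR).
#' Records are deduplicated so that each unordered residue pair appears once.
#'
#' @slot records data.frame with columns \code{protein1}, \code{residue1},
#'   \code{protein2}, \code{residue2}, \code{linker}, \code{id_score},
#'   \code{delta_s}, \code{fdr}, \code{link_class}.
#' @slot provenance list describing the source file, parse log and any filter
#'   settings applied.
#'
#' @seealso [readCrossLinks()], [filterCrossLinks()]
#' @export
setClass("CrossLinkSet",
  representation(records = "data.frame", provenance = "list"),
  prototype(records = data.frame(), provenance = list()))

.xlCanonicalCols <- c("protein1", "residue1", "protein2", "residue2",
                      "linker", "id_score", "delta_s", "fdr", "link_class")

setValidity("CrossLinkSet", function(object) {
  df <- object@records
  msg <- character()
  missing <- setdiff(.xlCanonicalCols, names(df))
  if (length(missing))
    msg <- c(msg, paste("records missing columns:", paste(missing, collapse = ", ")))
  if (nrow(df) > 0 && !length(missing)) {
    if (any(df$residue1 < 1L) || any(df$residue2 < 1L))
      msg <- c(msg, "residue positions must be >= 1")
    if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE))
      msg <- c(msg, "fdr must lie in [0, 1]")
    same <- df$protein1 == df$protein2 & df$residue1 == df$residue2
    if (any(same))
      msg <- c(msg, "self-links (identical endpoints) are not allowed")
    key <- .xlPairKey(df)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate unordered residue pairs present")
  }
  if (length(msg)) msg else TRUE
})

# canonical unordered-pair key
.xlPairKey <- function(df) {
  a <- paste0(df$protein1, ":", df$residue1)
  b <- paste0(df$protein2, ":", df$residue2)
  ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Coarse-grained bead representation of a multidomain protein
#'
#' One bead per residue, placed at the C-alpha position for residues covered
#' by a crystallographic rigid body and on an interpolated path for flexible
#' segments. Rigid bodies move as units (their internal geometry is fixed);
#' flexible beads move independently.
#'
#' @slot coords numeric matrix (n beads x 3), Angstrom.
#' @slot radii numeric vector of per-bead radii, Angstrom.
#' @slot component character vector, component (chain/protein) id per bead.
#' @slot residue integer vector, 1-based residue number per bead.
#' @slot bodyId integer vector, rigid-body id per bead (0 for flexible beads).
#' @slot bodies list of rigid-body descriptors: \code{name}, \code{beads}
#'   (indices), \code{rotation} (3x3), \code{translation} (length 3) giving the
#'   cumulative pose relative to the build coordinates.
#' @slot segments list of flexible-segment descriptors: \code{name},
#'   \code{beads}.
#'
#' @seealso [buildSystem()], [applyTransform()], [caDistance()]
#' @export
setClass("SystemModel",
  representation(coords = "matrix", radii = "numeric", component = "character",
                 residue = "integer", bodyId = "integer",
                 bodies = "list", segments = "list"))

setValidity("SystemModel", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must have 3 columns")
  if (length(object@radii) != n || length(object@component) != n ||
      length(object@residue) != n || length(object@bodyId) != n)
    msg <- c(msg, "per-bead slots must match nrow(coords)")
  if (anyDuplicated(paste0(object@component, ":", object@residue)))
    msg <- c(msg, "a (component, residue) pair is housed more than once")
  housed <- integer(n)
  for (b in object@bodies) housed[b$beads] <- housed[b$beads] + 1L
  for (s in object@segments) housed[s$beads] <- housed[s$beads] + 1L
  if (n > 0 && any(housed != 1L))
    msg <- c(msg, "every bead must belong to exactly one rigid body or flexible segment")
  for (b in object@bodies) {
    R <- b$rotation
    if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
      msg <- c(msg, sprintf("pose rotation of body '%s' is not a proper rotation", b$name))
  }
  if (length(msg)) msg else TRUE
})

#' Posterior score decomposition for one configuration
#'
#' Components of the negative log posterior: cross-link negative log
#' likelihood, excluded-volume penalty, sequence-connectivity penalty, and the
#' (constant, hence zero) negative log prior of the psi uncertainty
#' parameters. \code{total} is their sum.
#'
#' @slot xlNegLogLik numeric scalar.
#' @slot excludedVolume numeric scalar.
#' @slot connectivity numeric scalar.
#' @slot psiNegLogPrior numeric scalar.
#' @slot total numeric scalar, sum of the four components.
#' @seealso [totalScore()]
#' @export
setClass("ScoreBreakdown",
  representation(xlNegLogLik = "numeric", excludedVolume = "numeric",
                 connectivity = "numeric", psiNegLogPrior = "numeric",
                 total = "numeric"))

setValidity("ScoreBreakdown", function(object) {
  comps <- c(object@xlNegLogLik, object@excludedVolume, object@connectivity,
             object@psiNegLogPrior)
  if (length(comps) != 4 || !all(is.finite(comps)))
    return("all components must be finite scalars")
  if (abs(object@total - sum(comps)) > 1e-12)
    return("total must equal the sum of the components (1e-12)")
  TRUE
})

#' Psi uncertainty parameters for the cross-link likelihood
#'
#' One psi value per cross-link class (by default one class per linker
#' chemistry, with a \code{global} fallback). Psi is the probability that an
#' observed cross-link is spurious; values live in (psiMin, 0.5].
#'
#' @slot psi named numeric vector of class values.
#' @slot psiMin numeric scalar, lower bound of the uniform prior support.
#' @seealso [PsiParameters()], [crosslinkNegLogLik()]
#' @export
setClass("PsiParameters",
  representation(psi = "numeric", psiMin = "numeric"),
  prototype(psi = c(global = 0.25), psiMin = 0.01))

setValidity("PsiParameters", function(object) {
  if (is.null(names(object@psi)) || any(!nzchar(names(object@psi))))
    return("psi values must be named by cross-link class")
  if (any(object@psi <= object@psiMin) || any(object@psi > 0.5))
    return(sprintf("psi values must lie in (%g, 0.5]", object@psiMin))
  TRUE
})

#' Ensemble of sampled, scored configurations
#'
#' Output of [runSampling()]: per saved model the score breakdown, the sampled
#' psi values, and bookkeeping (start, sweep, rung), plus the full bead
#' coordinates and the system template they refer to.
#'
#' @slot records data.frame, one row per saved model (columns \code{start},
#'   \code{sweep}, \code{replica}, score components, \code{total}, and one
#'   \code{psi_*} column per psi class).
#' @slot coords numeric array (n beads x 3 x n models), Angstrom.
#' @slot system the [SystemModel-class] template (bead bookkeeping).
#' @slot metadata list: sampler configuration, scoring configuration,
#'   acceptance statistics.
#' @export
setClass("ScoredEnsemble",
  representation(records = "data.frame", coords = "array",
                 system = "SystemModel", metadata = "list"))

setValidity("ScoredEnsemble", function(object) {
  m <- nrow(object@records)
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an (n beads x 3 x n models) array")
  if (d[3] != m)
    return("number of coordinate slabs must equal nrow(records)")
  if (m > 0 && !all(is.finite(object@records$total)))
    return("all model scores must be finite")
  TRUE
})

#' Cluster analysis of a model ensemble
#'
#' k-means clustering of superposed configurations, with per-cluster center
#' (the member with the lowest mean RMSD to its co-members), precision (mean
#' RMSD of members to the center) and population, and optionally cross-link
#' satisfaction summaries.
#'
#' @slot k integer, number of clusters.
#' @slot assignments integer vector, cluster id per clustered model.
#' @slot centers integer vector, per cluster the index (into the clustered
#'   models) of the medoid.
#' @slot precision numeric vector, Angstrom, per cluster.
#' @slot populations integer vector, members per cluster.
#' @slot satisfaction list, per cluster the three satisfaction fractions
#'   (filled by [satisfactionReport()] via [clusterSatisfaction()]).
#' @seealso [clusterModels()]
#' @export
setClass("ClusterReport",
  representation(k = "integer", assignments = "integer", centers = "integer",
                 precision = "numeric", populations = "integer",
                 satisfaction = "list"))

setValidity("ClusterReport", function(object) {
  if (length(object@precision) != object@k || length(object@populations) != object@k)
    return("precision and populations must have one entry per cluster")
  if (sum(object@populations) != length(object@assignments))
    return("populations must sum to the number of clustered models")
  if (any(object@precision < 0)) return("precision must be >= 0")
  fr <- unlist(object@satisfaction)
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    return("satisfaction fractions must lie in [0, 1]")
  TRUE
})

#' One-phase decay fit of a nucleotide-release fluorescence trace
#'
#' @slot kObs numeric, observed pseudo-first-order rate constant (1/s).
#' @slot y0 numeric, fitted signal at t = 0.
#' @slot plateau numeric, fitted asymptote.
#' @slot amplitude numeric, \code{y0 - plateau}.
#' @slot se named numeric vector of parameter standard errors.
#' @slot rSquared numeric, 1 - SS_res/SS_tot.
#' @slot reliable logical, FALSE when the fit failed to converge, the
#'   amplitude is degenerate, or SE(kObs) exceeds kObs.
#' @seealso [fitOnePhaseDecay()]
#' @export
setClass("KineticsFit",
  representation(kObs = "numeric", y0 = "numeric", plateau = "numeric",
                 amplitude = "numeric", se = "numeric", rSquared = "numeric",
                 reliable = "logical"))
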