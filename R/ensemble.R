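# Ensemble analysis: top-model selection, Kabsch superposition, k-means
# clustering with medoid precision, cross-link satisfaction, split-half
# convergence diagnostics.

#' Select the best-scoring models of an ensemble
#'
#' Returns the \code{n} records with the smallest total score; ties are
#' broken deterministically by sweep index, then start, then replica, so the
#' selection is invariant to the storage order of the ensemble.
#'
#' @param ensemble a [ScoredEnsemble-class]
#' @param n number of models (default 200)
#' @return the selected models as a [ScoredEnsemble-class], best first
#' @export
selectTopModels <- function(ensemble, n = 200) {
  stopifnot(is(ensemble, "ScoredEnsemble"))
  m <- length(ensemble)
  if (m < n)
    stop("ensemble has ", m, " models, fewer than the requested ", n)
  r <- ensembleRecords(ensemble)
  ord <- order(r$total, r$sweep, r$start, r$replica)
  ensemble[ord[seq_len(n)]]
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det +1, never a reflection) and translation
#' minimising the RMSD between \code{x[subset, ]} and
#' \code{reference[subset, ]}, via the SVD of the cross-covariance matrix.
#'
#' @param x numeric matrix (n x 3) to move
#' @param reference numeric matrix (n x 3) to match
#' @param subset indices of the rows used to fit the superposition (default
#'   all); at least 3 non-collinear points
#' @return \code{list(rotation, translation, rmsd, coords)} where
#'   \code{coords} is all of \code{x} transformed and \code{rmsd} is over the
#'   subset
#' @export
superpose <- function(x, reference, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(x))
  xs <- x[subset, , drop = FALSE]
  rs <- reference[subset, , drop = FALSE]
  if (nrow(xs) < 3 || nrow(xs) != nrow(rs))
    stop("superposition needs at least 3 matched points")
  cx <- colMeans(xs); cr <- colMeans(rs)
  xc <- sweep(xs, 2, cx); rc <- sweep(rs, 2, cr)
  sv <- svd(crossprod(xc, rc))  # H = t(xc) %*% rc
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set; superposition is ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tv <- cr - as.numeric(R %*% cx)
  moved <- sweep(x %*% t(R), 2, tv, "+")
  rmsd <- sqrt(mean(rowSums((moved[subset, , drop = FALSE] - rs)^2)))
  list(rotation = R, translation = tv, rmsd = rmsd, coords = moved)
}

#' Coordinate RMSD between two configurations
#'
#' Plain root-mean-square deviation without superposition (the
#' configurations are assumed to be in a common frame, e.g. after
#' [superpose()]).
#'
#' @param a,b numeric matrices (n x 3)
#' @param subset optional row indices
#' @return RMSD in Angstrom
#' @export
coordRMSD <- function(a, b, subset = NULL) {
  if (!is.null(subset)) {
    a <- a[subset, , drop = FALSE]
    b <- b[subset, , drop = FALSE]
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Cluster ensemble models by RMSD after reference-domain superposition
#'
#' Every model is superposed onto a common reference (by default the
#' best-scoring model) using the beads of a reference domain, then k-means is
#' run on the flattened coordinates of the clustered beads (Euclidean metric,
#' proportional to coordinate RMSD), taking the best of \code{nstart} seeded
#' restarts by within-cluster sum of squares. Afterwards each cluster's
#' center is re-extracted as the medoid - the member with the lowest mean
#' RMSD to its co-members - and the cluster precision is the mean RMSD of the
#' members to that center (0 for singletons).
#'
#' @param ensemble a [ScoredEnsemble-class] (typically [selectTopModels()]
#'   output)
#' @param k number of clusters (default 3)
#' @param referenceBeads bead indices used for the superposition fit
#'   (e.g. the catalytic reference domain); default: beads of the first rigid
#'   body
#' @param clusterBeads bead indices whose coordinates are clustered; default:
#'   all rigid-body beads
#' @param reference coordinates (n x 3) of the common reference frame;
#'   default: the best-scoring member
#' @param seed seed for the k-means restarts
#' @param nstart k-means restarts (default 10)
#' @return a [ClusterReport-class]
#' @export
clusterModels <- function(ensemble, k = 3, referenceBeads = NULL,
                          clusterBeads = NULL, reference = NULL, seed = 1,
                          nstart = 10) {
  stopifnot(is(ensemble, "ScoredEnsemble"))
  m <- length(ensemble)
  if (k > m) stop("k = ", k, " exceeds the number of models (", m, ")")
  sys <- ensembleSystem(ensemble)
  if (is.null(referenceBeads))
    referenceBeads <- sys@bodies[[1]]$beads
  if (is.null(clusterBeads)) clusterBeads <- rigidBeads(sys)
  if (is.null(reference)) {
    r <- ensembleRecords(ensemble)
    best <- order(r$total, r$sweep, r$start, r$replica)[1]
    reference <- modelCoords(ensemble, best)
  }
  nb <- length(clusterBeads)
  X <- matrix(NA_real_, m, 3 * nb)
  for (i in seq_len(m)) {
    sup <- superpose(modelCoords(ensemble, i), reference, referenceBeads)
    X[i, ] <- as.numeric(sup$coords[clusterBeads, ])
  }
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = nstart))
  assign <- as.integer(km$cluster)
  centers <- integer(k); precision <- numeric(k)
  for (cl in seq_len(k)) {
    members <- which(assign == cl)
    if (length(members) == 1) {
      centers[cl] <- members
      precision[cl] <- 0
      next
    }
    D <- as.matrix(stats::dist(X[members, , drop = FALSE])) / sqrt(nb)
    medoid <- which.min(rowMeans(D))
    centers[cl] <- members[medoid]
    precision[cl] <- mean(D[medoid, -medoid])
  }
  new("ClusterReport", k = as.integer(k), assignments = assign,
      centers = centers, precision = precision,
      populations = as.integer(tabulate(assign, k)), satisfaction = list())
}

#' Fraction of cross-links satisfied by a configuration
#'
#' A cross-link is satisfied when the C-alpha (bead) distance of its residue
#' pair is strictly shorter than the cutoff (34 Angstrom by default, the
#' span compatible with lysine-reactive cross-linkers).
#'
#' @param x a [SystemModel-class], or a coordinate matrix (n x 3) with
#'   \code{system} supplying the bead bookkeeping
#' @param xls a non-empty [CrossLinkSet-class]
#' @param cutoff satisfaction cutoff, Angstrom
#' @param system a [SystemModel-class] template (required when \code{x} is a
#'   matrix)
#' @return fraction in [0, 1]
#' @export
satisfactionFraction <- function(x, xls, cutoff = 34, system = NULL) {
  if (is(x, "SystemModel")) {
    system <- x
    x <- x@coords
  }
  if (is.null(system)) stop("a system template is required for raw coordinates")
  if (length(xls) == 0) stop("satisfaction is undefined for an empty cross-link set")
  d <- .xlDistances(x, xls, system)
  mean(d < cutoff)
}

.xlDistances <- function(coords, xls, system) {
  df <- crossLinks(xls)
  i <- beadIndex(system, df$protein1, df$residue1)
  j <- beadIndex(system, df$protein2, df$residue2)
  sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
}

#' Per-cross-link satisfaction table
#'
#' One row per cross-link: its distance in a reference model (typically the
#' best-scoring one), whether that satisfies the cutoff, and — when cluster
#' members are supplied — how many members satisfy it.
#'
#' @param model reference coordinates: a [SystemModel-class] or an (n x 3)
#'   matrix
#' @param xls a non-empty [CrossLinkSet-class]
#' @param cutoff satisfaction cutoff, Angstrom
#' @param system a [SystemModel-class] template (required for raw matrices)
#' @param members optional member coordinates: list of matrices or an
#'   (n x 3 x m) array
#' @return data.frame with the link identity columns plus \code{distance},
#'   \code{satisfied} and (optionally) \code{n_members_satisfying}
#' @export
satisfactionTable <- function(model, xls, cutoff = 34, system = NULL,
                              members = NULL) {
  if (is(model, "SystemModel")) {
    system <- model
    model <- model@coords
  }
  if (length(xls) == 0) stop("satisfaction is undefined for an empty cross-link set")
  df <- crossLinks(xls)[, c("protein1", "residue1", "protein2", "residue2",
                            "linker")]
  df$distance <- .xlDistances(model, xls, system)
  df$satisfied <- df$distance < cutoff
  if (!is.null(members)) {
    if (is.array(members) && length(dim(members)) == 3)
      members <- lapply(seq_len(dim(members)[3]), function(i) members[, , i])
    df$n_members_satisfying <- Reduce(`+`, lapply(members, function(cc)
      as.integer(.xlDistances(cc, xls, system) < cutoff)))
  }
  df
}

#' Cross-link satisfaction report for a cluster
#'
#' The three fractions reported per cluster: the satisfaction of the overall
#' best-scoring solution, the maximum satisfaction over the individual
#' cluster members, and the aggregate fraction of cross-links satisfied by
#' at least one member.
#'
#' @param members coordinates of the cluster members: an (n x 3 x m) array or
#'   a list of (n x 3) matrices
#' @param bestScoring coordinates (n x 3) of the overall best-scoring model
#' @param xls a non-empty [CrossLinkSet-class]
#' @param system a [SystemModel-class] template
#' @param cutoff satisfaction cutoff, Angstrom
#' @return \code{list(best_scoring_fraction, max_single_conformer_fraction,
#'   aggregate_fraction)}
#' @export
satisfactionReport <- function(members, bestScoring, xls, system,
                               cutoff = 34) {
  if (is.array(members) && length(dim(members)) == 3)
    members <- lapply(seq_len(dim(members)[3]), function(i) members[, , i])
  if (!length(members)) stop("cluster has no members")
  if (length(xls) == 0) stop("satisfaction is undefined for an empty cross-link set")
  perMember <- vapply(members, function(cc)
    satisfactionFraction(cc, xls, cutoff, system), numeric(1))
  satisfiedByAny <- Reduce(`|`, lapply(members, function(cc)
    .xlDistances(cc, xls, system) < cutoff))
  list(best_scoring_fraction =
         satisfactionFraction(bestScoring, xls, cutoff, system),
       max_single_conformer_fraction = max(perMember),
       aggregate_fraction = mean(satisfiedByAny))
}

#' Fill per-cluster satisfaction into a cluster report
#'
#' @param report a [ClusterReport-class] from [clusterModels()]
#' @param ensemble the clustered [ScoredEnsemble-class] (same model order)
#' @param xls a non-empty [CrossLinkSet-class]
#' @param cutoff satisfaction cutoff, Angstrom
#' @return the report with its \code{satisfaction} slot populated
#' @export
clusterSatisfaction <- function(report, ensemble, xls, cutoff = 34) {
  stopifnot(is(report, "ClusterReport"), is(ensemble, "ScoredEnsemble"))
  r <- ensembleRecords(ensemble)
  best <- order(r$total, r$sweep, r$start, r$replica)[1]
  sys <- ensembleSystem(ensemble)
  sat <- lapply(seq_len(report@k), function(cl) {
    members <- which(report@assignments == cl)
    satisfactionReport(modelCoords(ensemble)[, , members, drop = FALSE],
                       modelCoords(ensemble, best), xls, sys, cutoff)
  })
  report@satisfaction <- sat
  validObject(report)
  report
}

#' Split-half convergence diagnostic
#'
#' Randomly splits the ensemble into two equal halves and compares them:
#' per-half best total score, the two-sample Kolmogorov-Smirnov statistic of
#' the score distributions, and (optionally) the top-cluster populations of
#' each half's best models. The run is flagged non-converged when the KS
#' statistic exceeds the threshold.
#'
#' @param ensemble a [ScoredEnsemble-class] with at least 2 models
#' @param seed seed for the random split
#' @param ksThreshold convergence flag threshold on the KS statistic
#' @param k clusters per half (NULL skips the clustering summary)
#' @param topN models clustered per half (capped at the half size)
#' @return \code{list(best_scores, ks_statistic, converged, populations)}
#' @export
convergenceSplit <- function(ensemble, seed = 1, ksThreshold = 0.1, k = NULL,
                             topN = 200) {
  stopifnot(is(ensemble, "ScoredEnsemble"))
  m <- length(ensemble)
  if (m < 2) stop("need at least 2 models to split")
  set.seed(seed)
  half <- sample.int(m, m %/% 2)
  halves <- list(ensemble[half], ensemble[setdiff(seq_len(m), half)])
  totals <- lapply(halves, function(h) ensembleRecords(h)$total)
  ks <- suppressWarnings(stats::ks.test(totals[[1]], totals[[2]]))
  populations <- NULL
  if (!is.null(k)) {
    populations <- lapply(halves, function(h) {
      top <- selectTopModels(h, min(topN, length(h)))
      rep <- clusterModels(top, k = min(k, length(top)), seed = seed)
      sort(rep@populations, decreasing = TRUE)
    })
  }
  list(best_scores = vapply(totals, min, numeric(1)),
       ks_statistic = unname(ks$statistic),
       converged = unname(ks$statistic) <= ksThreshold,
       populations = populations)
}
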