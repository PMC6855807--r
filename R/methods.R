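#' @describeIn CrossLinkSet-class number of cross-link records
#' @param x a \code{CrossLinkSet}
#' @export
setMethod("length", "CrossLinkSet", function(x) nrow(x@records))

#' Extract the record table of a cross-link set
#'
#' @param x a [CrossLinkSet-class]
#' @return data.frame of records in the canonical column layout.
#' @export
crossLinks <- function(x) {
  stopifnot(is(x, "CrossLinkSet"))
  x@records
}

#' Provenance of a cross-link set or ensemble
#'
#' @param x a [CrossLinkSet-class]
#' @return list of provenance entries (source, parse log, filter settings).
#' @export
provenance <- function(x) {
  stopifnot(is(x, "CrossLinkSet"))
  x@provenance
}

#' @export
setMethod("as.data.frame", "CrossLinkSet",
          function(x, ...) x@records)

#' @export
setMethod("[", "CrossLinkSet", function(x, i, j, ..., drop = TRUE) {
  new("CrossLinkSet", records = x@records[i, , drop = FALSE],
      provenance = c(x@provenance, list(subset = TRUE)))
})

setMethod("show", "CrossLinkSet", function(object) {
  df <- object@records
  cat("CrossLinkSet with", nrow(df), "records\n")
  if (nrow(df)) {
    cat("  linkers:", paste(names(table(df$linker)), table(df$linker),
                            sep = ":", collapse = ", "), "\n")
    cat("  classes:", paste(names(table(df$link_class)), table(df$link_class),
                            sep = ":", collapse = ", "), "\n")
  }
  if (!is.null(object@provenance$filter))
    cat("  filtered:", object@provenance$filter$n_in, "->",
        object@provenance$filter$n_out, "records\n")
})

# ---- SystemModel accessors ----

#' Number of beads in a system model
#' @param x a [SystemModel-class]
#' @export
nBeads <- function(x) {
  stopifnot(is(x, "SystemModel"))
  nrow(x@coords)
}

#' Bead coordinates of a system model
#' @param x a [SystemModel-class]
#' @return numeric matrix (n x 3), Angstrom.
#' @export
beadCoords <- function(x) {
  stopifnot(is(x, "SystemModel"))
  x@coords
}

#' Per-bead radii
#' @param x a [SystemModel-class]
#' @export
beadRadii <- function(x) {
  stopifnot(is(x, "SystemModel"))
  x@radii
}

#' Rigid-body names of a system model
#' @param x a [SystemModel-class]
#' @export
bodyNames <- function(x) {
  stopifnot(is(x, "SystemModel"))
  vapply(x@bodies, `[[`, character(1), "name")
}

#' Bead indices of one rigid body
#' @param x a [SystemModel-class]
#' @param name rigid-body name
#' @export
bodyBeads <- function(x, name) {
  stopifnot(is(x, "SystemModel"))
  i <- match(name, bodyNames(x))
  if (is.na(i)) stop("unknown rigid body: ", name)
  x@bodies[[i]]$beads
}

#' Indices of all beads housed in rigid bodies
#' @param x a [SystemModel-class]
#' @export
rigidBeads <- function(x) {
  stopifnot(is(x, "SystemModel"))
  which(x@bodyId > 0L)
}

#' Map (component, residue) pairs to bead indices
#'
#' @param x a [SystemModel-class]
#' @param component character vector of component ids
#' @param residue integer vector of 1-based residue numbers (recycled against
#'   \code{component})
#' @return integer vector of bead indices; errors if any residue is not housed.
#' @export
beadIndex <- function(x, component, residue) {
  stopifnot(is(x, "SystemModel"))
  n <- max(length(component), length(residue))
  component <- rep_len(as.character(component), n)
  residue <- rep_len(as.integer(residue), n)
  idx <- match(paste0(component, ":", residue),
               paste0(x@component, ":", x@residue))
  if (anyNA(idx)) {
    bad <- paste0(component[is.na(idx)], ":", residue[is.na(idx)])
    stop("residue(s) not housed in the model: ",
         paste(unique(bad), collapse = ", "))
  }
  idx
}

setMethod("show", "SystemModel", function(object) {
  cat("SystemModel:", nBeads(object), "beads,",
      length(object@bodies), "rigid bodies,",
      length(object@segments), "flexible segments\n")
  for (b in object@bodies)
    cat(sprintf("  body %-12s %4d beads\n", b$name, length(b$beads)))
  for (s in object@segments)
    cat(sprintf("  flex %-12s %4d beads\n", s$name, length(s$beads)))
})

setMethod("show", "ScoreBreakdown", function(object) {
  cat(sprintf(paste0("ScoreBreakdown: total %.4f (xl %.4f, excluded volume",
                     " %.4f, connectivity %.4f, psi prior %.4f)\n"),
              object@total, object@xlNegLogLik, object@excludedVolume,
              object@connectivity, object@psiNegLogPrior))
})

#' @describeIn ScoreBreakdown-class components as a named numeric vector
#' @param x a \code{ScoreBreakdown}
#' @param ... ignored
#' @export
setMethod("as.numeric", "ScoreBreakdown", function(x, ...) {
  c(xl_negloglik = x@xlNegLogLik, excluded_volume = x@excludedVolume,
    connectivity = x@connectivity, psi_neglogprior = x@psiNegLogPrior,
    total = x@total)
})

#' Total posterior score
#' @param x a [ScoreBreakdown-class]
#' @export
scoreTotal <- function(x) {
  stopifnot(is(x, "ScoreBreakdown"))
  x@total
}

# ---- PsiParameters ----

#' Construct psi uncertainty parameters
#'
#' @param psi named numeric vector; names are cross-link classes (linker
#'   chemistries such as \code{DSS}, \code{DSG}, or \code{global}).
#' @param psiMin lower support bound of the uniform prior (default 0.01).
#' @return a [PsiParameters-class]
#' @export
PsiParameters <- function(psi = c(global = 0.25), psiMin = 0.01) {
  new("PsiParameters", psi = psi, psiMin = psiMin)
}

#' Psi values
#' @param x a [PsiParameters-class]
#' @export
psiValues <- function(x) {
  stopifnot(is(x, "PsiParameters"))
  x@psi
}

setMethod("show", "PsiParameters", function(object) {
  cat("PsiParameters:", paste(names(object@psi), sprintf("%.3f", object@psi),
                              sep = "=", collapse = ", "),
      sprintf("(support (%g, 0.5])\n", object@psiMin))
})

# ---- ScoredEnsemble ----

#' @describeIn ScoredEnsemble-class number of saved models
#' @param x a \code{ScoredEnsemble}
#' @export
setMethod("length", "ScoredEnsemble", function(x) nrow(x@records))

#' Score/bookkeeping table of an ensemble
#' @param x a [ScoredEnsemble-class]
#' @export
ensembleRecords <- function(x) {
  stopifnot(is(x, "ScoredEnsemble"))
  x@records
}

#' Coordinates of one or all ensemble models
#' @param x a [ScoredEnsemble-class]
#' @param i model index; if missing, the full (n x 3 x m) array
#' @export
modelCoords <- function(x, i) {
  stopifnot(is(x, "ScoredEnsemble"))
  if (missing(i)) return(x@coords)
  x@coords[, , i, drop = FALSE][, , 1]
}

#' System template of an ensemble
#' @param x a [ScoredEnsemble-class]
#' @export
ensembleSystem <- function(x) {
  stopifnot(is(x, "ScoredEnsemble"))
  x@system
}

#' @export
setMethod("[", "ScoredEnsemble", function(x, i, j, ..., drop = TRUE) {
  new("ScoredEnsemble", records = x@records[i, , drop = FALSE],
      coords = x@coords[, , i, drop = FALSE], system = x@system,
      metadata = x@metadata)
})

setMethod("show", "ScoredEnsemble", function(object) {
  cat("ScoredEnsemble:", nrow(object@records), "models,",
      nrow(object@coords), "beads\n")
  if (nrow(object@records))
    cat(sprintf("  total score: min %.3f, median %.3f, max %.3f\n",
                min(object@records$total), stats::median(object@records$total),
                max(object@records$total)))
})

setMethod("show", "ClusterReport", function(object) {
  cat("ClusterReport: k =", object@k, "\n")
  for (i in seq_len(object@k))
    cat(sprintf("  cluster %d: %d members, precision %.2f A\n",
                i, object@populations[i], object@precision[i]))
})

setMethod("show", "KineticsFit", function(object) {
  cat(sprintf("KineticsFit: kObs %.5g /s (amplitude %.4g, plateau %.4g, R2 %.4f)%s\n",
              object@kObs, object@amplitude, object@plateau, object@rSquared,
              if (object@reliable) "" else " [unreliable]"))
})

#' Observed rate constant of a kinetics fit
#' @param x a [KineticsFit-class]
#' @export
kObs <- function(x) {
  stopifnot(is(x, "KineticsFit"))
  x@kObs
}
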