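# Hydrogen/deuterium-exchange MS: centroid masses from isotope envelopes,
# deuterium uptake against an undeuterated reference, back-exchange
# normalisation against a fully deuterated control, differential-uptake
# classification between states, and structural mapping.

PROTON_MASS <- 1.007276  # Da

#' Neutral centroid mass of an isotope envelope
#'
#' The intensity-weighted average m/z of the envelope, converted to neutral
#' mass: \code{(sum(mz * I) / sum(I) - proton) * charge}.
#'
#' @param mz numeric vector of m/z values, strictly increasing
#' @param intensity non-negative intensities, at least one positive
#' @param charge positive integer charge state
#' @return neutral mass, Da
#' @examples
#' centroidMass(c(500, 501), c(1, 1), charge = 1)  # 499.492724
#' @export
centroidMass <- function(mz, intensity, charge = 1L) {
  stopifnot(length(mz) == length(intensity), charge >= 1)
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (all(intensity == 0)) stop("all-zero intensity envelope")
  if (is.unsorted(mz, strictly = TRUE)) stop("m/z values must be strictly increasing")
  (sum(mz * intensity) / sum(intensity) - PROTON_MASS) * charge
}

#' Centroid masses of a long-form envelope table
#'
#' @param envelopes data.frame with columns \code{peptide}, \code{charge},
#'   \code{mz}, \code{intensity}, \code{state}, \code{timepoint},
#'   \code{replicate} (one row per isotope peak)
#' @return data.frame of centroid masses, one row per (peptide, state,
#'   timepoint, replicate)
#' @export
envelopeCentroids <- function(envelopes) {
  need <- c("peptide", "charge", "mz", "intensity", "state", "timepoint",
            "replicate")
  missing <- setdiff(need, names(envelopes))
  if (length(missing))
    stop("envelope table missing column(s): ", paste(missing, collapse = ", "))
  keys <- c("peptide", "state", "timepoint", "replicate")
  groups <- split(envelopes, envelopes[keys], drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$mz), , drop = FALSE]
    data.frame(g[1, keys, drop = FALSE], charge = g$charge[1],
               centroid_mass = centroidMass(g$mz, g$intensity, g$charge[1]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deuterium uptake against the undeuterated reference
#'
#' For each (peptide, state, timepoint, replicate) the uptake is the centroid
#' mass minus the undeuterated centroid mass of the same peptide (rows with
#' \code{timepoint == 0}, averaged over replicates and states). Peptides
#' without an undeuterated reference are flagged and excluded. Replicate
#' means and SDs are in [summarizeUptake()].
#'
#' @param centroids data.frame as from [envelopeCentroids()] (columns
#'   \code{peptide}, \code{state}, \code{timepoint}, \code{replicate},
#'   \code{centroid_mass}; extra columns are carried through)
#' @return data.frame of deuterated rows with an \code{uptake} column, Da
#' @export
computeUptake <- function(centroids) {
  ref <- centroids[centroids$timepoint == 0, , drop = FALSE]
  if (nrow(ref) == 0) stop("no undeuterated reference rows (timepoint == 0)")
  refMass <- tapply(ref$centroid_mass, ref$peptide, mean)
  deut <- centroids[centroids$timepoint > 0, , drop = FALSE]
  idx <- match(deut$peptide, names(refMass))
  if (anyNA(idx)) {
    missing <- unique(deut$peptide[is.na(idx)])
    warning("no undeuterated reference for peptide(s): ",
            paste(missing, collapse = ", "), "; rows excluded")
    deut <- deut[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  deut$uptake <- deut$centroid_mass - as.numeric(refMass[idx])
  rownames(deut) <- NULL
  deut
}

#' Replicate mean and SD of deuterium uptake
#'
#' @param uptake data.frame from [computeUptake()]
#' @return data.frame with one row per (peptide, state, timepoint):
#'   \code{mean_uptake}, \code{sd_uptake}, \code{n}
#' @export
summarizeUptake <- function(uptake) {
  keys <- interaction(uptake$peptide, uptake$state, uptake$timepoint,
                      drop = TRUE)
  groups <- split(uptake, keys)
  out <- lapply(groups, function(g)
    data.frame(peptide = g$peptide[1], state = g$state[1],
               timepoint = g$timepoint[1], mean_uptake = mean(g$uptake),
               sd_uptake = stats::sd(g$uptake), n = nrow(g)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Back-exchange normalisation against a fully deuterated control
#'
#' Divides the observed uptake by the uptake of a maximally labelled control
#' (e.g. denatured protein incubated in deuterated buffer overnight), giving
#' the labelled fraction; the back-exchange-corrected uptake is that fraction
#' times the number of exchangeable amides.
#'
#' @param uptake observed uptake, Da
#' @param fullyDeuteratedUptake uptake of the fully deuterated control, Da
#'   (> 0)
#' @param nExchangeable number of exchangeable backbone amides (see
#'   [exchangeableAmides()])
#' @return \code{list(fraction, corrected)} - labelled fraction and corrected
#'   uptake in Da
#' @export
normalizeBackexchange <- function(uptake, fullyDeuteratedUptake,
                                  nExchangeable) {
  if (any(fullyDeuteratedUptake <= 0))
    stop("fully deuterated control uptake must be positive")
  fraction <- uptake / fullyDeuteratedUptake
  list(fraction = fraction, corrected = fraction * nExchangeable)
}

#' Exchangeable backbone amides of a peptide
#'
#' Standard HDX counting: peptide length minus one (the N-terminal amide
#' back-exchanges too fast to measure) minus prolines at position 3 or later
#' (prolines have no backbone amide hydrogen).
#'
#' @param sequence character vector of peptide sequences (one-letter code)
#' @return integer vector
#' @export
exchangeableAmides <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(toupper(s), "")[[1]]
    length(aa) - 1L - sum(aa[-(1:2)] == "P")
  }, integer(1), USE.NAMES = FALSE)
}

#' Differential deuterium uptake between two states
#'
#' Per peptide and timepoint, compares replicate uptakes of a state against a
#' reference state with a two-sided Welch t-test. A peptide is
#' \code{protected} when its mean uptake is lower than the reference by at
#' least \code{magnitudeMin} Da with p < alpha, \code{deprotected} for the
#' symmetric increase, and \code{no_change} otherwise. Peptide/timepoint
#' combinations present in only one state are classified \code{missing} -
#' peptides genuinely disappear from exchange experiments when a region
#' becomes rigid or aggregates, so this is a first-class outcome, not an
#' artifact.
#'
#' @param stateA data.frame from [computeUptake()] for the state of interest
#' @param stateB reference-state data.frame
#' @param alpha significance threshold (default 0.05)
#' @param magnitudeMin minimum absolute uptake difference, Da (default 0.5)
#' @return data.frame: \code{peptide}, \code{timepoint}, \code{delta_uptake}
#'   (state minus reference, Da), \code{p_value}, \code{classification}
#' @export
differentialUptake <- function(stateA, stateB, alpha = 0.05,
                               magnitudeMin = 0.5) {
  keyA <- interaction(stateA$peptide, stateA$timepoint, drop = TRUE)
  keyB <- interaction(stateB$peptide, stateB$timepoint, drop = TRUE)
  allKeys <- union(levels(keyA), levels(keyB))
  onlyA <- setdiff(levels(keyA), levels(keyB))
  onlyB <- setdiff(levels(keyB), levels(keyA))
  if (length(onlyA) || length(onlyB))
    warning("peptide/timepoint universes differ: ", length(onlyA),
            " only in state A, ", length(onlyB), " only in reference")
  out <- lapply(allKeys, function(kk) {
    a <- stateA$uptake[keyA == kk]
    b <- stateB$uptake[keyB == kk]
    parts <- strsplit(kk, ".", fixed = TRUE)[[1]]
    pep <- paste(parts[-length(parts)], collapse = ".")
    tp <- as.numeric(parts[length(parts)])
    if (!length(a) || !length(b))
      return(data.frame(peptide = pep, timepoint = tp,
                        delta_uptake = NA_real_, p_value = NA_real_,
                        classification = "missing"))
    if (length(a) < 2 || length(b) < 2)
      stop("need >= 2 replicates per side for peptide ", pep,
           " at timepoint ", tp)
    delta <- mean(a) - mean(b)
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    cls <- if (is.finite(p) && p < alpha && delta < -magnitudeMin) "protected"
      else if (is.finite(p) && p < alpha && delta > magnitudeMin) "deprotected"
      else "no_change"
    data.frame(peptide = pep, timepoint = tp, delta_uptake = delta,
               p_value = p, classification = cls)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$peptide, res$timepoint), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Map differential uptake onto a structural model
#'
#' Averages, per residue, the uptake differences of all peptides covering
#' it (peptide ranges come from the \code{peptides} table), writes the
#' per-residue values into the B-factor field of a bead-model PDB, and marks
#' residues without peptide coverage by zero occupancy (the conventional way
#' to colour them distinctly, e.g. white, in a structure viewer).
#'
#' @param results data.frame from [differentialUptake()] (rows with
#'   \code{missing} or \code{NA} deltas are ignored)
#' @param peptides data.frame mapping \code{peptide} to \code{component},
#'   \code{start}, \code{end} residue ranges
#' @param model a [SystemModel-class]
#' @param file optional output PDB path
#' @return named per-bead numeric vector of mean deltas (NA = no coverage),
#'   invisibly when \code{file} is given
#' @export
mapToStructure <- function(results, peptides, model, file = NULL) {
  stopifnot(is(model, "SystemModel"))
  res <- results[!is.na(results$delta_uptake), , drop = FALSE]
  n <- nBeads(model)
  sums <- numeric(n); counts <- integer(n)
  for (i in seq_len(nrow(res))) {
    p <- peptides[peptides$peptide == res$peptide[i], , drop = FALSE]
    if (nrow(p) == 0) next
    hit <- which(model@component == p$component[1] &
                   model@residue >= p$start[1] & model@residue <= p$end[1])
    sums[hit] <- sums[hit] + res$delta_uptake[i]
    counts[hit] <- counts[hit] + 1L
  }
  values <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  names(values) <- paste0(model@component, ":", model@residue)
  if (!is.null(file)) {
    writeModelPDB(model, file, bFactor = values)
    return(invisible(values))
  }
  values
}
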