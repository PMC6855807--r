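# Seeded ground-truth generators: toy multidomain systems, simulated
# cross-link sets with decoys, two-state HDX tables, and fluorescence decay
# traces. Every generator is deterministic for a fixed seed, so each dataset
# can be regenerated independently from a master seed plus a fixed offset per
# data type.

#' Build a toy multidomain ground-truth system
#'
#' Constructs \code{nBodies} rigid bodies as helical C-alpha traces (3.8
#' Angstrom consecutive spacing), connected by flexible linkers of
#' \code{linkerLength} residues, and freezes a randomized but physically
#' sensible arrangement as the ground truth: each body is placed with a
#' random orientation such that it does not clash with the previous bodies
#' (all inter-body bead distances above the excluded-volume contact), makes
#' enough inter-body contacts for cross-links to form, and leaves its linker
#' bridgeable without strain.
#'
#' @param nBodies number of rigid bodies (>= 1)
#' @param residuesPerBody residues per body
#' @param linkerLength flexible residues between consecutive bodies
#' @param seed integer seed; \code{NULL} uses the current RNG stream
#' @param beadRadius bead radius, Angstrom
#' @return \code{list(system = SystemModel frozen as ground truth, seed,
#'   params)}; total residues are \code{nBodies * residuesPerBody +
#'   (nBodies - 1) * linkerLength}
#' @export
makeToySystem <- function(nBodies = 3, residuesPerBody = 60,
                          linkerLength = 15, seed = NULL, beadRadius = 3.0) {
  stopifnot(nBodies >= 1, residuesPerBody >= 4, linkerLength >= 0)
  if (!is.null(seed)) set.seed(seed)

  # compact helical bundle: ~20-residue helices stacked antiparallel with
  # ~10.5 A lateral spacing, giving a globular body (3.8 A consecutive
  # C-alpha spacing as in a real helix)
  helixBundle <- function(n, perHelix = 20) {
    nHelix <- max(1L, ceiling(n / perHelix))
    xyz <- matrix(NA_real_, n, 3)
    k <- 0L
    for (h in seq_len(nHelix)) {
      nh <- min(perHelix, n - k)
      if (nh <= 0) break
      i <- seq_len(nh) - 1
      th <- i * (100 * pi / 180)
      z <- 1.5 * i
      if (h %% 2 == 0) z <- max(z) - z  # antiparallel
      xyz[k + seq_len(nh), ] <- cbind(2.3 * cos(th) + 10.5 * (h - 1),
                                      2.3 * sin(th) + 4.5 * (h %% 2), z)
      k <- k + nh
    }
    xyz
  }

  comp <- character(); res <- integer(); bodyId <- integer()
  coords <- matrix(numeric(0), 0, 3)
  bodies <- list(); segments <- list()
  nextRes <- 1L
  placed <- list()  # bead coords per placed body

  for (b in seq_len(nBodies)) {
    xyz <- helixBundle(residuesPerBody)
    xyz <- sweep(xyz, 2, colMeans(xyz))
    if (b == 1) {
      placedXyz <- xyz
    } else {
      prev <- placed[[b - 1]]
      prevEnd <- prev[nrow(prev), ]
      maxGap <- max(3.8 * (linkerLength + 1) * 0.75, 12)
      ok <- FALSE
      for (try in 1:2000) {
        R <- randomRotation()
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        ctr <- colMeans(prev) + dir * stats::runif(1, 12, 28)
        cand <- sweep(xyz %*% t(R), 2, ctr, "+")
        dAll <- .crossDistances(cand, do.call(rbind, placed))
        gap <- sqrt(sum((cand[1, ] - prevEnd)^2))
        if (min(dAll) > 2 * beadRadius + 0.5 &&
            sum(.crossDistances(cand, prev) <= 30) >= 30 &&
            gap <= maxGap) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("failed to place body ", b,
                    "; relax the geometry (fewer residues or longer linkers)")
      placedXyz <- cand
    }
    placed[[b]] <- placedXyz
    rng <- seq.int(nextRes, nextRes + residuesPerBody - 1L)
    idx0 <- length(comp)
    comp <- c(comp, rep("toy", residuesPerBody))
    res <- c(res, rng)
    bodyId <- c(bodyId, rep(b, residuesPerBody))
    coords <- rbind(coords, placedXyz)
    bodies[[b]] <- list(name = paste0("body", b),
                        beads = seq.int(idx0 + 1L, length(comp)),
                        rotation = diag(3), translation = c(0, 0, 0))
    nextRes <- nextRes + residuesPerBody
    if (b < nBodies && linkerLength > 0) {
      rng <- seq.int(nextRes, nextRes + linkerLength - 1L)
      idx0 <- length(comp)
      comp <- c(comp, rep("toy", linkerLength))
      res <- c(res, rng)
      bodyId <- c(bodyId, rep(0L, linkerLength))
      coords <- rbind(coords, matrix(NA_real_, linkerLength, 3))
      segments[[length(segments) + 1L]] <-
        list(name = sprintf("linker%d", b),
             beads = seq.int(idx0 + 1L, length(comp)))
      nextRes <- nextRes + linkerLength
    }
  }

  model <- new("SystemModel", coords = coords,
               radii = rep(beadRadius, length(comp)), component = comp,
               residue = res, bodyId = as.integer(bodyId), bodies = bodies,
               segments = segments)
  model <- initializeFlexible(model)
  list(system = model, seed = seed,
       params = list(nBodies = nBodies, residuesPerBody = residuesPerBody,
                     linkerLength = linkerLength, beadRadius = beadRadius))
}

.crossDistances <- function(a, b) {
  # all pairwise distances between two coordinate sets (vectors)
  ax <- outer(a[, 1], b[, 1], "-")
  ay <- outer(a[, 2], b[, 2], "-")
  az <- outer(a[, 3], b[, 3], "-")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Simulate a cross-link set from a ground-truth configuration
#'
#' Samples \code{nTrue} residue pairs among rigid-body beads whose
#' ground-truth C-alpha distance is at most \code{dMax} (30 Angstrom by
#' default, inside the 34 Angstrom satisfaction cutoff so every true link is
#' satisfiable with margin) and \code{nDecoy} pairs with distance above
#' \code{decoyMin} (45 Angstrom, safely beyond the cutoff so decoys are
#' unambiguously unsatisfiable). A configurable fraction of the true links
#' is drawn from inter-body pairs - the informative subset, mirroring real
#' cross-linking-MS where inter-domain links drive docking - and the rest
#' from intra-body pairs. Quality fields are drawn to pass the default
#' [filterCrossLinks()] thresholds; records are shuffled and carry no truth
#' label, which is returned separately.
#'
#' @param truth output of [makeToySystem()]
#' @param nTrue number of true links
#' @param nDecoy number of decoys
#' @param dMax maximum ground-truth distance of true links, Angstrom
#' @param seed integer seed
#' @param interFraction fraction of true links drawn from inter-body pairs
#' @param decoyMin minimum ground-truth distance of decoys, Angstrom
#' @return \code{list(links = CrossLinkSet (shuffled, unlabeled), truth =
#'   data.frame(protein1, residue1, protein2, residue2, label, distance))}
#' @export
simulateCrosslinks <- function(truth, nTrue = 40, nDecoy = 4, dMax = 30,
                               seed = NULL, interFraction = 0.5,
                               decoyMin = 45) {
  if (!is.null(seed)) set.seed(seed)
  model <- truth$system
  rb <- rigidBeads(model)
  D <- .crossDistances(model@coords[rb, ], model@coords[rb, ])
  pairIdx <- which(upper.tri(D), arr.ind = TRUE)
  i <- rb[pairIdx[, 1]]; j <- rb[pairIdx[, 2]]
  d <- D[pairIdx]
  sameBody <- model@bodyId[i] == model@bodyId[j]

  trueInterPool <- which(d <= dMax & !sameBody)
  trueIntraPool <- which(d <= dMax & sameBody)
  decoyPool <- which(d > decoyMin)
  nInter <- min(round(nTrue * interFraction), length(trueInterPool))
  nIntra <- nTrue - nInter
  if (nIntra > length(trueIntraPool) || nInter > length(trueInterPool))
    stop("not enough candidate pairs within ", dMax, " Angstrom (",
         length(trueInterPool), " inter-body, ", length(trueIntraPool),
         " intra-body available)")
  if (nDecoy > length(decoyPool))
    stop("not enough decoy candidates beyond ", decoyMin, " Angstrom (",
         length(decoyPool), " available)")
  pick <- c(sample(trueInterPool, nInter), sample(trueIntraPool, nIntra),
            sample(decoyPool, nDecoy))
  label <- c(rep("true", nTrue), rep("decoy", nDecoy))

  df <- data.frame(protein1 = model@component[i[pick]],
                   residue1 = model@residue[i[pick]],
                   protein2 = model@component[j[pick]],
                   residue2 = model@residue[j[pick]],
                   linker = "DSS",
                   id_score = stats::runif(nTrue + nDecoy, 29, 45),
                   delta_s = stats::runif(nTrue + nDecoy, 0.1, 0.9),
                   fdr = stats::runif(nTrue + nDecoy, 0, 0.049))
  truthDf <- cbind(df[, c("protein1", "residue1", "protein2", "residue2")],
                   label = label, distance = d[pick])
  shuffle <- sample.int(nrow(df))
  list(links = CrossLinkSet(df[shuffle, , drop = FALSE],
                            provenance = list(source = "simulateCrosslinks")),
       truth = truthDf)
}

#' Peptide map tiling a toy sequence
#'
#' Overlapping peptides of fixed length covering residues 1..nResidues, with
#' random proline-free sequences (so the exchangeable-amide count is simply
#' length - 1).
#'
#' @param nResidues residues to tile
#' @param length peptide length
#' @param step start-to-start offset between consecutive peptides
#' @param component component id for structural mapping
#' @param seed integer seed for the sequences
#' @return data.frame: \code{peptide}, \code{sequence}, \code{component},
#'   \code{start}, \code{end}
#' @export
makePeptideMap <- function(nResidues, length = 12, step = 8,
                           component = "toy", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- seq(1, max(nResidues - length + 1, 1), by = step)
  aas <- setdiff(strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]], "P")
  data.frame(peptide = sprintf("pep%03d", seq_along(starts)),
             sequence = vapply(starts, function(s)
               paste(sample(aas, length, replace = TRUE), collapse = ""),
               character(1)),
             component = component, start = starts,
             end = pmin(starts + length - 1, nResidues))
}

#' Simulate two-state HDX centroid tables
#'
#' Reference-state uptake follows a saturating exponential per peptide
#' (random exchange rate, amplitude 80 percent of the exchangeable amides);
#' the variant state is offset by the supplied per-peptide true deltas
#' (clamped to the physical range). Centroid masses are the peptide base
#' mass plus uptake plus Gaussian measurement noise; undeuterated reference
#' rows (timepoint 0) are included for both states. Optional dropout removes
#' a peptide from the variant state entirely, emulating peptides that
#' disappear from exchange experiments.
#'
#' @param peptides data.frame from [makePeptideMap()]
#' @param trueDeltas named numeric vector (Da) of variant-minus-reference
#'   uptake offsets per peptide (default 0 for unnamed peptides)
#' @param noiseSd Gaussian noise SD per centroid measurement, Da
#' @param nReplicates replicates per state/timepoint
#' @param timepoints exchange times, seconds
#' @param seed integer seed
#' @param dropout character vector of peptides absent from the variant state
#' @return \code{list(centroids = long data.frame, truth = trueDeltas used)}
#' @export
simulateHdx <- function(peptides, trueDeltas = NULL, noiseSd = 0.15,
                        nReplicates = 3, timepoints = c(10, 60, 300, 900),
                        seed = NULL, dropout = character()) {
  if (!is.null(seed)) set.seed(seed)
  nEx <- exchangeableAmides(peptides$sequence)
  deltas <- stats::setNames(rep(0, nrow(peptides)), peptides$peptide)
  if (!is.null(trueDeltas)) deltas[names(trueDeltas)] <- trueDeltas
  kex <- stats::runif(nrow(peptides), 0.1, 0.5)
  baseMass <- nchar(peptides$sequence) * 110
  rows <- list()
  for (p in seq_len(nrow(peptides))) {
    pep <- peptides$peptide[p]
    umax <- 0.8 * nEx[p]
    for (state in c("reference", "variant")) {
      if (state == "variant" && pep %in% dropout) next
      for (tp in c(0, timepoints)) {
        up <- if (tp == 0) 0 else {
          u <- umax * (1 - exp(-kex[p] * tp))
          if (state == "variant") u <- u + deltas[pep]
          min(max(u, 0), nEx[p])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, state = state, timepoint = tp,
          replicate = seq_len(nReplicates),
          centroid_mass = baseMass[p] + up +
            stats::rnorm(nReplicates, 0, noiseSd))
      }
    }
  }
  centroids <- do.call(rbind, rows)
  rownames(centroids) <- NULL
  list(centroids = centroids, truth = deltas)
}

#' Simulate isotope envelopes of a labelled peptide and its control
#'
#' Deuteration is binomial over the exchangeable amides with incorporation
#' probability \code{fractionLabeled * (1 - backExchange)}; the fully
#' deuterated control has probability \code{1 - backExchange}. Peak
#' intensities get multiplicative Gaussian noise. Dividing the observed
#' uptake by the control's (see [normalizeBackexchange()]) recovers
#' \code{fractionLabeled} regardless of the back-exchange loss.
#'
#' @param nExchangeable exchangeable amides
#' @param fractionLabeled true labelled fraction
#' @param backExchange fractional deuterium loss during workup
#' @param baseMass undeuterated neutral mass, Da
#' @param charge charge state
#' @param relNoise relative intensity noise SD
#' @param seed integer seed
#' @return \code{list(labeled, control, undeuterated)} - data.frames of
#'   (\code{mz}, \code{intensity}) peaks
#' @export
simulateLabelingEnvelopes <- function(nExchangeable, fractionLabeled = 0.7,
                                      backExchange = 0.2, baseMass = 1200,
                                      charge = 2L, relNoise = 0.01,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dMass <- 1.006277  # deuterium - hydrogen, Da
  mkEnv <- function(p) {
    dcount <- 0:nExchangeable
    inten <- stats::dbinom(dcount, nExchangeable, p)
    inten <- pmax(inten * (1 + stats::rnorm(length(inten), 0, relNoise)), 0)
    keep <- inten > 1e-9
    data.frame(mz = (baseMass + dcount[keep] * dMass) / charge + PROTON_MASS,
               intensity = inten[keep])
  }
  list(labeled = mkEnv(fractionLabeled * (1 - backExchange)),
       control = mkEnv(1 - backExchange),
       undeuterated = mkEnv(0))
}

#' Simulate fluorescence decay traces
#'
#' One-phase decays \code{(y0 - plateau) exp(-k t) + plateau} sampled at
#' uniform times with additive Gaussian noise, for a set of named conditions
#' with per-condition true rate constants and optional metadata.
#'
#' @param trueK named numeric vector of rate constants per condition, 1/s
#' @param y0 initial signal
#' @param plateau final signal
#' @param noiseSd additive noise SD, signal units
#' @param nPoints points per trace
#' @param tMax trace duration, seconds
#' @param nReplicates replicates per condition
#' @param enzymeConc optional named vector, micromolar, per condition
#' @param additive optional named character vector per condition
#' @param seed integer seed
#' @return long data.frame: \code{time_s}, \code{signal}, \code{condition},
#'   \code{replicate} (+ metadata columns)
#' @export
simulateKinetics <- function(trueK, y0 = 100, plateau = 20, noiseSd = 1,
                             nPoints = 60, tMax = 600, nReplicates = 1,
                             enzymeConc = NULL, additive = NULL,
                             seed = NULL) {
  stopifnot(all(trueK > 0), !is.null(names(trueK)))
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, tMax, length.out = nPoints)
  rows <- list()
  for (cond in names(trueK)) {
    for (rep in seq_len(nReplicates)) {
      sig <- (y0 - plateau) * exp(-trueK[[cond]] * tt) + plateau +
        stats::rnorm(nPoints, 0, noiseSd)
      df <- data.frame(time_s = tt, signal = sig, condition = cond,
                       replicate = rep)
      if (!is.null(enzymeConc)) df$enzyme_conc <- enzymeConc[[cond]]
      if (!is.null(additive)) df$additive <- additive[[cond]]
      rows[[length(rows) + 1L]] <- df
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
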