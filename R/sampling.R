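# Replica-exchange Gibbs sampling over rigid-body poses, flexible beads and
# psi uncertainty parameters, built on Metropolis Monte Carlo.

#' Sampler configuration
#'
#' Defaults follow the production regime of the method: 500,000 saved models
#' from 100 independent starts, rigid-body moves of at most 4 Angstrom
#' translation and 0.03 rad rotation, flexible-bead moves of at most 5
#' Angstrom, Gaussian psi perturbations, and a replica ladder spanning
#' temperatures 1.0 to 2.5.
#'
#' @param nModelsTotal total saved models across all starts
#' @param nStarts number of independent runs from random initial poses
#' @param temperatures strictly increasing ladder; default 8 geometrically
#'   spaced rungs on [1.0, 2.5]
#' @param maxTransRigid max rigid-body translation per move, Angstrom
#' @param maxRotRigid max rigid-body rotation per move, rad
#' @param maxTransBead max flexible-bead translation per move, Angstrom
#' @param psiMoveSigma SD of the Gaussian psi perturbation
#' @param psiInit initial psi value for every class
#' @param bodyRepeats rigid-body proposals per body per sweep (the pose
#'   degrees of freedom dominate convergence, so they get extra attempts)
#' @param swapInterval sweeps between replica-exchange attempts
#' @param saveInterval sweeps between saved (coldest-replica) models
#' @param initBox edge length, Angstrom, of the cube in which initial body
#'   centroids are placed uniformly
#' @param seed integer seed; \code{NULL} leaves the RNG stream untouched
#' @return named list, validated
#' @export
samplerConfig <- function(nModelsTotal = 500000, nStarts = 100,
                          temperatures = NULL,
                          maxTransRigid = 4, maxRotRigid = 0.03,
                          maxTransBead = 5, psiMoveSigma = 0.02,
                          psiInit = 0.25, bodyRepeats = 4, swapInterval = 5,
                          saveInterval = 1, initBox = 60, seed = NULL) {
  if (is.null(temperatures))
    temperatures <- exp(seq(log(1.0), log(2.5), length.out = 8))
  stopifnot(nModelsTotal >= 1, nStarts >= 1,
            all(diff(temperatures) > 0), temperatures[1] >= 1.0 - 1e-12,
            maxTransRigid > 0, maxRotRigid > 0, maxTransBead > 0,
            psiMoveSigma > 0, swapInterval >= 1, saveInterval >= 1,
            initBox > 0)
  list(nModelsTotal = as.integer(nModelsTotal), nStarts = as.integer(nStarts),
       temperatures = temperatures, maxTransRigid = maxTransRigid,
       maxRotRigid = maxRotRigid, maxTransBead = maxTransBead,
       psiMoveSigma = psiMoveSigma, psiInit = psiInit,
       bodyRepeats = as.integer(bodyRepeats),
       swapInterval = as.integer(swapInterval),
       saveInterval = as.integer(saveInterval), initBox = initBox,
       seed = seed)
}

.ballVector <- function(rmax) {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  u * rmax * stats::runif(1)^(1 / 3)
}

#' Propose a single Monte Carlo move
#'
#' Applies exactly one mover to a replica state: a uniformly chosen rigid
#' body translated by a vector of norm at most \code{maxTransRigid} and
#' rotated about its centroid by at most \code{maxRotRigid}; or one flexible
#' bead translated by at most \code{maxTransBead}; or one psi class perturbed
#' by Gaussian noise and reflected into \code{(psiMin, 0.5]}. The mover is
#' selected with probability proportional to the count of movable entities of
#' each kind; all proposals are symmetric.
#'
#' @param state replica state: \code{list(model =, psi =, score =,
#'   temperature =)}
#' @param cfg a [samplerConfig()] list
#' @return \code{list(state = candidate state, mover = "body"|"bead"|"psi")}
#' @export
proposeMove <- function(state, cfg = samplerConfig()) {
  model <- state$model
  psi <- state$psi
  nb <- length(model@bodies)
  flex <- which(model@bodyId == 0L)
  np <- length(psiValues(psi))
  pick <- sample.int(nb + length(flex) + np, 1)
  if (pick <= nb) {
    b <- model@bodies[[pick]]
    R <- randomRotation(cfg$maxRotRigid)
    tv <- .ballVector(cfg$maxTransRigid)
    ctr <- colMeans(model@coords[b$beads, , drop = FALSE])
    model <- applyTransform(model, b$name, R,
                            as.numeric(ctr - R %*% ctr) + tv)
    mover <- "body"
  } else if (pick <= nb + length(flex)) {
    i <- flex[pick - nb]
    model@coords[i, ] <- model@coords[i, ] + .ballVector(cfg$maxTransBead)
    mover <- "bead"
  } else {
    k <- pick - nb - length(flex)
    v <- psiValues(psi)
    v[k] <- .reflect(v[k] + stats::rnorm(1, 0, cfg$psiMoveSigma),
                     psi@psiMin, 0.5)
    psi <- PsiParameters(v, psiMin = psi@psiMin)
    mover <- "psi"
  }
  list(state = list(model = model, psi = psi, score = NULL,
                    temperature = state$temperature),
       mover = mover)
}

.reflect <- function(v, lo, hi) {
  for (i in 1:64) {
    if (v >= lo && v <= hi) return(v)
    if (v < lo) v <- 2 * lo - v
    if (v > hi) v <- 2 * hi - v
  }
  (lo + hi) / 2
}

#' Metropolis acceptance decision
#'
#' Accepts a candidate with probability \code{min(1, exp(-(sNew - sOld) /
#' temperature))}; downhill moves are always accepted. A non-finite candidate
#' score is rejected with a warning.
#'
#' @param sOld,sNew total scores of the current and candidate configurations
#' @param temperature replica temperature
#' @return logical, consumes one uniform variate for uphill proposals
#' @export
metropolisAccept <- function(sOld, sNew, temperature = 1.0) {
  if (!is.finite(sNew)) {
    warning("non-finite candidate score; move rejected")
    return(FALSE)
  }
  if (sNew <= sOld) return(TRUE)
  stats::runif(1) < exp(-(sNew - sOld) / temperature)
}

#' One Metropolis Monte Carlo step
#'
#' Proposes a single move with [proposeMove()], scores the candidate with
#' [totalScore()], and accepts or rejects it by the Metropolis criterion at
#' the state's temperature.
#'
#' @param state replica state: \code{list(model =, psi =, score =,
#'   temperature =)}; a missing score is computed on entry
#' @param xls a [CrossLinkSet-class]
#' @param cfg a [samplerConfig()] list
#' @param scoring a [scoringConfig()] list
#' @return the updated state (unchanged configuration on rejection)
#' @export
metropolisStep <- function(state, xls, cfg = samplerConfig(),
                           scoring = scoringConfig()) {
  if (is.null(state$score))
    state$score <- totalScore(state$model, xls, state$psi, scoring)
  cand <- proposeMove(state, cfg)$state
  cand$score <- totalScore(cand$model, xls, cand$psi, scoring)
  if (metropolisAccept(scoreTotal(state$score), scoreTotal(cand$score),
                       state$temperature))
    cand
  else
    state
}

.swapProbability <- function(tA, tB, sA, sB) {
  min(1, exp((1 / tA - 1 / tB) * (sA - sB)))
}

#' Replica-exchange swap attempt
#'
#' Exchanges the configurations (model and psi, with their scores) of two
#' replicas at adjacent ladder temperatures with probability \code{min(1,
#' exp((1/T_a - 1/T_b) (S_a - S_b)))}. Temperatures stay attached to their
#' ladder rungs.
#'
#' @param a,b replica states (\code{list(model =, psi =, score =,
#'   temperature =)}) with scores present
#' @return \code{list(a =, b =, swapped = logical)}
#' @export
replicaExchangeSwap <- function(a, b) {
  sA <- scoreTotal(a$score); sB <- scoreTotal(b$score)
  p <- .swapProbability(a$temperature, b$temperature, sA, sB)
  swapped <- stats::runif(1) < p
  if (swapped) {
    tmp <- a[c("model", "psi", "score")]
    a[c("model", "psi", "score")] <- b[c("model", "psi", "score")]
    b[c("model", "psi", "score")] <- tmp
  }
  list(a = a, b = b, swapped = swapped)
}

#' Run replica-exchange sampling
#'
#' Performs \code{nStarts} independent replica-exchange runs. Each run draws
#' a random initial configuration (every rigid body given a uniformly random
#' orientation and a centroid uniform in a cube of edge \code{initBox};
#' flexible beads re-interpolated between their anchors), then sweeps all
#' parameter classes in turn - every rigid body, every flexible bead, then
#' every psi class, one Metropolis proposal each - at each ladder rung.
#' Replica-exchange swaps between adjacent rungs are attempted every
#' \code{swapInterval} sweeps with alternating pair parity. The coldest
#' rung's configuration is saved every \code{saveInterval} sweeps until the
#' run has produced its share \code{nModelsTotal / nStarts} of models.
#'
#' With a fixed \code{seed} the run is deterministic: identical seeds produce
#' bit-identical ensembles (single-threaded; all randomness is drawn from
#' one R RNG stream in a fixed schedule).
#'
#' @param system a [SystemModel-class]
#' @param xls a non-empty [CrossLinkSet-class]
#' @param cfg a [samplerConfig()] list
#' @param psi a [PsiParameters-class]; its classes define the sampled psi
#'   values and its values are overridden by \code{cfg$psiInit}
#' @param scoring a [scoringConfig()] list
#' @param verbose print per-start progress
#' @return a [ScoredEnsemble-class]
#' @export
runSampling <- function(system, xls, cfg = samplerConfig(),
                        psi = PsiParameters(), scoring = scoringConfig(),
                        verbose = FALSE) {
  stopifnot(is(system, "SystemModel"), is(xls, "CrossLinkSet"))
  if (length(xls) == 0) stop("cross-link set is empty")
  if (cfg$nModelsTotal %% cfg$nStarts != 0)
    stop("nModelsTotal must be divisible by nStarts")
  nSave <- cfg$nModelsTotal %/% cfg$nStarts
  if (nSave < 1)
    stop("configuration saves 0 models per start (nModelsTotal=",
         cfg$nModelsTotal, ", nStarts=", cfg$nStarts, ")")
  nSweeps <- nSave * cfg$saveInterval
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  ctx <- .scoringContext(system, xls, psi, scoring)
  par <- .cppPar(scoring, cfg, psi)
  classes <- names(psiValues(psi))
  nT <- length(cfg$temperatures)
  n <- nBeads(system)

  recs <- vector("list", cfg$nStarts)
  coordsList <- vector("list", cfg$nStarts)
  acc <- c(body_att = 0, body_acc = 0, bead_att = 0, bead_acc = 0,
           psi_att = 0, psi_acc = 0)
  swapAtt <- swapAcc <- numeric(max(nT - 1, 1))

  for (start in seq_len(cfg$nStarts)) {
    init <- .randomizePose(system, cfg$initBox)
    states <- lapply(seq_len(nT), function(r)
      list(coords = init@coords,
           psi = stats::setNames(rep(cfg$psiInit, length(classes)), classes),
           total = NA_real_))
    sweepScores <- matrix(NA_real_, nSweeps, 4)
    sweepPsi <- matrix(NA_real_, nSweeps, length(classes))
    sweepCoords <- array(NA_real_, c(n, 3, nSweeps))
    done <- 0L
    chunkId <- 0L
    while (done < nSweeps) {
      len <- min(cfg$swapInterval, nSweeps - done)
      for (r in seq_len(nT)) {
        out <- cpp_mc_sweeps(states[[r]]$coords, ctx$radii, ctx$comp,
                             ctx$resid, ctx$body, ctx$bodyBeads, ctx$flexBeads,
                             ctx$connPairs, ctx$xlPairs, ctx$xlClass, ctx$xlD0,
                             states[[r]]$psi, cfg$temperatures[r], len, par,
                             r == 1L)
        states[[r]]$coords <- out$coords
        states[[r]]$psi <- stats::setNames(out$psi, classes)
        states[[r]]$total <- sum(out$score)
        if (r == 1L) {
          rows <- done + seq_len(len)
          sweepScores[rows, ] <- out$scores
          sweepPsi[rows, ] <- out$psiTrace
          sweepCoords[, , rows] <- array(out$savedCoords, c(n, 3, len))
          acc <- acc + out$accept
        }
      }
      done <- done + len
      chunkId <- chunkId + 1L
      if (nT > 1) {
        for (k in seq.int(1L + chunkId %% 2L, nT - 1L, by = 2L)) {
          p <- .swapProbability(cfg$temperatures[k], cfg$temperatures[k + 1],
                                states[[k]]$total, states[[k + 1]]$total)
          swapAtt[k] <- swapAtt[k] + 1
          if (stats::runif(1) < p) {
            swapAcc[k] <- swapAcc[k] + 1
            tmp <- states[[k]]
            states[[k]] <- states[[k + 1]]
            states[[k + 1]] <- tmp
          }
        }
      }
    }
    keep <- seq(cfg$saveInterval, nSweeps, by = cfg$saveInterval)
    df <- data.frame(start = start, sweep = keep, replica = 1L,
                     xl_negloglik = sweepScores[keep, 1],
                     excluded_volume = sweepScores[keep, 2],
                     connectivity = sweepScores[keep, 3],
                     psi_neglogprior = 0,
                     total = sweepScores[keep, 4])
    for (ci in seq_along(classes))
      df[[paste0("psi_", classes[ci])]] <- sweepPsi[keep, ci]
    recs[[start]] <- df
    coordsList[[start]] <- sweepCoords[, , keep, drop = FALSE]
    if (verbose)
      message(sprintf("start %d/%d: best score %.3f", start, cfg$nStarts,
                      min(df$total)))
  }

  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  coords <- array(unlist(coordsList, use.names = FALSE),
                  c(n, 3, nrow(records)))
  new("ScoredEnsemble", records = records, coords = coords, system = system,
      metadata = list(config = cfg, scoring = scoring, psiClasses = classes,
                      acceptance = acc,
                      swaps = list(attempted = swapAtt, accepted = swapAcc)))
}

# random initial configuration: uniform body orientations, centroids uniform
# in a cube, flexible beads re-interpolated between the moved anchors
.randomizePose <- function(system, initBox) {
  model <- system
  for (b in model@bodies) {
    R <- randomRotation()
    ctr <- colMeans(model@coords[b$beads, , drop = FALSE])
    target <- stats::runif(3, -initBox / 2, initBox / 2)
    model <- applyTransform(model, b$name, R,
                            target - as.numeric(R %*% ctr))
  }
  initializeFlexible(model)
}
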