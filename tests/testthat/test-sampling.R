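tinyState <- function(model, temperature = 1) {
  list(model = model, psi = PsiParameters(c(global = 0.25)), score = NULL,
       temperature = temperature)
}

test_that("proposals respect the configured move magnitudes", {
  set.seed(1)
  m <- makeTinyModel(2, 5, 3)
  cfg <- samplerConfig(nModelsTotal = 1, nStarts = 1)
  st <- tinyState(m)
  maxTrans <- 0; maxAngle <- 0; maxBead <- 0
  for (i in 1:2000) {
    prop <- proposeMove(st, cfg)
    if (prop$mover == "body") {
      for (b in seq_along(m@bodies)) {
        old <- m@bodies[[b]]; new <- prop$state$model@bodies[[b]]
        dR <- new$rotation %*% t(old$rotation)
        ang <- acos(pmin(pmax((sum(diag(dR)) - 1) / 2, -1), 1))
        maxAngle <- max(maxAngle, ang)
        ctrOld <- colMeans(m@coords[old$beads, ])
        ctrNew <- colMeans(prop$state$model@coords[old$beads, ])
        maxTrans <- max(maxTrans, sqrt(sum((ctrNew - ctrOld)^2)))
      }
    } else if (prop$mover == "bead") {
      shift <- sqrt(rowSums((prop$state$model@coords - m@coords)^2))
      maxBead <- max(maxBead, max(shift))
    } else {
      v <- psiValues(prop$state$psi)
      expect_true(v > 0.01 && v <= 0.5)
    }
  }
  expect_lte(maxTrans, 4 + 1e-9)
  expect_lte(maxAngle, 0.03 + 1e-9)
  expect_gt(maxAngle, 0)
  expect_lte(maxBead, 5 + 1e-9)
})

test_that("systems without flexible beads never receive bead moves", {
  set.seed(2)
  m <- makeTinyModel(2, 5, nFlex = 0)
  st <- tinyState(m)
  cfg <- samplerConfig(nModelsTotal = 1, nStarts = 1)
  movers <- replicate(400, proposeMove(st, cfg)$mover)
  expect_false("bead" %in% movers)
  expect_setequal(unique(movers), c("body", "psi"))
})

test_that("psi proposals reflect into the support from near the boundary", {
  set.seed(3)
  m <- makeTinyModel(1, 4, 0)
  st <- tinyState(m)
  st$psi <- PsiParameters(c(global = 0.499))
  cfg <- samplerConfig(nModelsTotal = 1, nStarts = 1, psiMoveSigma = 0.3)
  for (i in 1:300) {
    prop <- proposeMove(st, cfg)
    if (prop$mover == "psi") {
      v <- unname(psiValues(prop$state$psi))
      expect_gt(v, 0.01); expect_lte(v, 0.5)
    }
  }
})

test_that("the Metropolis rule accepts downhill always and uphill at rate exp(-dS/T)", {
  set.seed(4)
  expect_true(all(replicate(200, metropolisAccept(10, 9.9, 1))))
  expect_true(all(replicate(200, metropolisAccept(10, 10, 1))))
  # dS = T log 2 gives acceptance probability exactly 1/2
  n <- 10000
  acc <- mean(replicate(n, metropolisAccept(0, 2 * log(2), 2)))
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(acc - 0.5), 3 * se)
  expect_warning(bad <- metropolisAccept(1, NaN, 1), "non-finite")
  expect_false(bad)
})

test_that("a discrete two-state chain reaches Boltzmann occupancy", {
  # states with score gap dS at T = 1: occupancy ratio exp(-dS)
  set.seed(5)
  dS <- 1.0
  state <- 0L
  nSteps <- 1e5
  visits <- 0L
  for (i in seq_len(nSteps)) {
    cand <- 1L - state
    sOld <- dS * state; sNew <- dS * cand
    if (metropolisAccept(sOld, sNew, 1)) state <- cand
    visits <- visits + state
  }
  pHigh <- visits / nSteps
  want <- exp(-dS) / (1 + exp(-dS))
  se <- sqrt(want * (1 - want) / nSteps) * 10  # autocorrelated chain
  expect_lt(abs(pHigh - want), 3 * se)
})

test_that("replica exchange swaps follow the analytic probability", {
  m <- makeTinyModel(1, 4, 0)
  mk <- function(total, temp) list(model = m, psi = PsiParameters(),
                                   score = new("ScoreBreakdown",
                                               xlNegLogLik = total,
                                               excludedVolume = 0,
                                               connectivity = 0,
                                               psiNegLogPrior = 0,
                                               total = total),
                                   temperature = temp)
  set.seed(6)
  # equal scores or equal temperatures: always swapped
  expect_true(all(replicate(100, replicaExchangeSwap(mk(5, 1), mk(5, 2.5))$swapped)))
  expect_true(all(replicate(100, replicaExchangeSwap(mk(1, 1.3), mk(9, 1.3))$swapped)))
  # S_a - S_b = 1 at T 1.0/2.5: p = exp(0.6) capped at 1
  expect_true(all(replicate(100, replicaExchangeSwap(mk(6, 1), mk(5, 2.5))$swapped)))
  # S_a - S_b = -1: p = exp(-0.6)
  n <- 4000
  acc <- mean(replicate(n, replicaExchangeSwap(mk(5, 1), mk(6, 2.5))$swapped))
  p <- exp((1 / 1 - 1 / 2.5) * (5 - 6))
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
  # configurations travel, temperatures stay with the rungs
  sw <- replicaExchangeSwap(mk(9, 1), mk(1, 2.5))
  expect_true(sw$swapped)
  expect_equal(sw$a$temperature, 1)
  expect_equal(scoreTotal(sw$a$score), 1)
})

test_that("metropolisStep leaves the state unchanged on rejection", {
  set.seed(7)
  m <- makeTinyModel(2, 5, 2)
  xls <- CrossLinkSet(data.frame(protein1 = "p", residue1 = c(1, 3),
                                 protein2 = "p", residue2 = c(8, 10),
                                 linker = "DSS", id_score = 35,
                                 delta_s = 0.5, fdr = 0.01))
  cfg <- samplerConfig(nModelsTotal = 1, nStarts = 1)
  st <- tinyState(m, temperature = 0.999999999)
  st$temperature <- 1
  st$score <- totalScore(m, xls, st$psi)
  for (i in 1:25) st <- metropolisStep(st, xls, cfg)
  # the cached score always matches a fresh evaluation of the state
  expect_equal(scoreTotal(st$score),
               scoreTotal(totalScore(st$model, xls, st$psi)), tolerance = 1e-9)
})

test_that("run bookkeeping: exact record counts, determinism, cache validity", {
  set.seed(8)
  toy <- makeToySystem(2, 12, 4, seed = 31)
  sim <- simulateCrosslinks(toy, 10, 0, seed = 32)
  cfg <- samplerConfig(nModelsTotal = 200, nStarts = 4, seed = 33,
                       temperatures = c(1, 1.5, 2.5), initBox = 30)
  ens <- runSampling(toy$system, sim$links, cfg, PsiParameters(c(DSS = 0.25)))
  r <- ensembleRecords(ens)
  expect_equal(nrow(r), 200L)
  expect_equal(unname(table(r$start)), rep(50L, 4), ignore_attr = TRUE)
  expect_true(all(is.finite(r$total)))
  expect_equal(dim(modelCoords(ens)), c(nBeads(toy$system), 3, 200))
  # identical seed, identical ensemble
  ens2 <- runSampling(toy$system, sim$links, cfg, PsiParameters(c(DSS = 0.25)))
  expect_identical(ensembleRecords(ens2), r)
  expect_identical(modelCoords(ens2), modelCoords(ens))
  # cached sweep scores equal full re-evaluation of the stored coordinates
  sys <- ensembleSystem(ens)
  for (i in c(1, 97, 200)) {
    mdl <- sys
    mdl@coords <- modelCoords(ens, i)
    psiI <- PsiParameters(c(DSS = max(r$psi_DSS[i], 0.0101)))
    expect_equal(scoreTotal(totalScore(mdl, sim$links, psiI)), r$total[i],
                 tolerance = 1e-9)
  }
  # swap acceptance on the ladder is neither 0 nor 1
  sw <- ens@metadata$swaps
  rate <- sw$accepted / pmax(sw$attempted, 1)
  expect_true(all(rate > 0 & rate < 1))
})

test_that("configurations that would save zero models are rejected", {
  toy <- makeToySystem(2, 10, 3, seed = 41)
  sim <- simulateCrosslinks(toy, 8, 0, seed = 42)
  cfg <- samplerConfig(nModelsTotal = 10, nStarts = 20)
  expect_error(runSampling(toy$system, sim$links, cfg), "divisible")
})

test_that("sampling a small two-body problem reaches the ground-truth score", {
  toy <- makeToySystem(2, 20, 6, seed = 51)
  sim <- simulateCrosslinks(toy, 20, 0, seed = 52)
  cfg <- samplerConfig(nModelsTotal = 5000, nStarts = 1, seed = 53,
                       initBox = 30)
  sc <- scoringConfig(d0 = c(DSS = 30))
  ens <- runSampling(toy$system, sim$links, cfg, PsiParameters(c(DSS = 0.05)),
                     sc)
  r <- ensembleRecords(ens)
  best <- which.min(r$total)
  truthScore <- scoreTotal(totalScore(
    toy$system, sim$links,
    PsiParameters(c(DSS = max(r$psi_DSS[best], 0.0101))), sc))
  expect_lte(min(r$total), truthScore + 1.0)
})

test_that("split halves of one run have matching score distributions", {
  toy <- makeToySystem(2, 12, 4, seed = 61)
  sim <- simulateCrosslinks(toy, 10, 0, seed = 62)
  cfg <- samplerConfig(nModelsTotal = 1000, nStarts = 2, seed = 63,
                       temperatures = c(1, 1.6, 2.5), initBox = 30)
  ens <- runSampling(toy$system, sim$links, cfg, PsiParameters(c(DSS = 0.25)))
  # drop the burn-in transient before the equilibrium comparison
  eq <- ens[which(ensembleRecords(ens)$sweep > 100)]
  div <- convergenceSplit(eq, seed = 1)
  expect_gte(div$ks_statistic, 0)
  expect_length(div$best_scores, 2L)
  # the two halves share the distribution; best scores agree within 5% of IQR
  iqr <- stats::IQR(ensembleRecords(eq)$total)
  expect_lt(abs(diff(div$best_scores)), max(0.05 * iqr, 0.5))
})
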