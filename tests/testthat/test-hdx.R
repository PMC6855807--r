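test_that("centroid masses follow the intensity-weighted average", {
  expect_equal(centroidMass(500.0, 1, charge = 1), 498.992724)
  expect_equal(centroidMass(c(500, 501), c(1, 1), charge = 1), 499.492724)
  # five-peak envelope at charge 2 against an explicit hand computation
  mz <- c(600.1, 600.6, 601.1, 601.6, 602.1)
  I <- c(10, 40, 30, 15, 5)
  hand <- (sum(mz * I) / sum(I) - 1.007276) * 2
  expect_equal(centroidMass(mz, I, charge = 2), hand, tolerance = 1e-12)
  expect_error(centroidMass(c(500, 501), c(0, 0)), "all-zero")
  expect_error(centroidMass(c(501, 500), c(1, 1)), "increasing")
  expect_error(centroidMass(c(500, 501), c(1, -1)), "non-negative")
})

test_that("envelope tables are centroided per peptide/state/timepoint/replicate", {
  env <- rbind(
    data.frame(peptide = "p1", charge = 1, mz = c(500, 501),
               intensity = c(1, 1), state = "apo", timepoint = 60,
               replicate = 1),
    data.frame(peptide = "p1", charge = 1, mz = 500, intensity = 1,
               state = "apo", timepoint = 0, replicate = 1))
  cen <- envelopeCentroids(env)
  expect_equal(nrow(cen), 2L)
  expect_setequal(cen$centroid_mass, c(498.992724, 499.492724))
  expect_error(envelopeCentroids(env[, -3]), "missing")
})

test_that("centroid intensities are scale invariant", {
  mz <- c(700, 701, 702); I <- c(2, 5, 1)
  expect_equal(centroidMass(mz, I, 2), centroidMass(mz, I * 1e4, 2))
})

mkCentroids <- function(uptakes, state = "apo", base = 1000) {
  rows <- list()
  for (pep in names(uptakes)) {
    rows[[length(rows) + 1]] <- data.frame(
      peptide = pep, state = state, timepoint = 0,
      replicate = 1:3, centroid_mass = base)
    u <- uptakes[[pep]]
    rows[[length(rows) + 1]] <- data.frame(
      peptide = pep, state = state, timepoint = 60,
      replicate = seq_along(u), centroid_mass = base + u)
  }
  do.call(rbind, rows)
}

test_that("uptake is the centroid difference to the undeuterated reference", {
  cen <- mkCentroids(list(p1 = c(1.4, 1.5, 1.6), p2 = c(0, 0, 0)))
  up <- computeUptake(cen)
  expect_equal(up$uptake[up$peptide == "p2"], c(0, 0, 0))
  summ <- summarizeUptake(up)
  expect_equal(summ$mean_uptake[summ$peptide == "p1"], 1.5)
  expect_equal(summ$sd_uptake[summ$peptide == "p1"], 0.1)
  expect_equal(summ$n[summ$peptide == "p1"], 3L)
  # a lone 1.5 Da shift
  cen2 <- rbind(data.frame(peptide = "x", state = "apo", timepoint = 0,
                           replicate = 1, centroid_mass = 1000.0),
                data.frame(peptide = "x", state = "apo", timepoint = 60,
                           replicate = 1, centroid_mass = 1001.5))
  expect_equal(computeUptake(cen2)$uptake, 1.5)
  # peptides without a reference are flagged and excluded
  cen3 <- rbind(cen2, data.frame(peptide = "orphan", state = "apo",
                                 timepoint = 60, replicate = 1,
                                 centroid_mass = 1002))
  expect_warning(up3 <- computeUptake(cen3), "orphan")
  expect_false("orphan" %in% up3$peptide)
})

test_that("back-exchange normalisation rescales by the saturated control", {
  expect_equal(normalizeBackexchange(4, 4, 8)$fraction, 1)
  out <- normalizeBackexchange(2, 4, 8)
  expect_equal(out$fraction, 0.5)
  expect_equal(out$corrected, 4)
  expect_error(normalizeBackexchange(2, 0, 8), "positive")
})

test_that("a 70% labelled sample is recovered through simulated envelopes", {
  hits <- replicate(20, {
    env <- simulateLabelingEnvelopes(10, fractionLabeled = 0.7,
                                     backExchange = 0.2, seed = NULL)
    u0 <- centroidMass(env$undeuterated$mz, env$undeuterated$intensity, 2)
    uL <- centroidMass(env$labeled$mz, env$labeled$intensity, 2) - u0
    uC <- centroidMass(env$control$mz, env$control$intensity, 2) - u0
    normalizeBackexchange(uL, uC, 10)$fraction
  })
  expect_true(all(abs(hits - 0.7) < 0.02))
})

test_that("exchangeable amide counting excludes fast positions and prolines", {
  expect_equal(exchangeableAmides("ACDEF"), 4L)
  expect_equal(exchangeableAmides("AAPAA"), 3L)   # P at position 3
  expect_equal(exchangeableAmides("APAAA"), 4L)   # P at position 2 not counted
  expect_equal(exchangeableAmides(c("AA", "AAAA")), c(1L, 3L))
})

test_that("differential classification follows the magnitude + significance rule", {
  a <- mkCentroids(list(p1 = c(1.0, 1.1, 0.9)), state = "A")
  b <- mkCentroids(list(p1 = c(1.0, 1.1, 0.9)), state = "B")
  upA <- computeUptake(a); upB <- computeUptake(b)
  res <- differentialUptake(upA, upB)
  expect_equal(res$classification, "no_change")
  expect_equal(res$delta_uptake, 0)
  # clear protection of -1.5 Da with tight replicates
  set.seed(1)
  a2 <- mkCentroids(list(p1 = 1.0 + rnorm(3, 0, 0.1)), state = "A")
  b2 <- mkCentroids(list(p1 = 2.5 + rnorm(3, 0, 0.1)), state = "B")
  res2 <- differentialUptake(computeUptake(a2), computeUptake(b2))
  expect_equal(res2$classification, "protected")
  expect_lt(abs(res2$delta_uptake + 1.5), 0.2)
  # same magnitude but wild variance: not significant
  a3 <- mkCentroids(list(p1 = c(-2, 1.5, 3.5)), state = "A")
  b3 <- mkCentroids(list(p1 = c(0.5, 6, 0.8)), state = "B")
  res3 <- differentialUptake(computeUptake(a3), computeUptake(b3))
  expect_equal(res3$classification, "no_change")
})

test_that("classification is antisymmetric and missing peptides are first-class", {
  set.seed(2)
  a <- mkCentroids(list(p1 = 1 + rnorm(3, 0, 0.1),
                        p2 = 3 + rnorm(3, 0, 0.1)), state = "A")
  b <- mkCentroids(list(p1 = 3 + rnorm(3, 0, 0.1),
                        p2 = 1 + rnorm(3, 0, 0.1),
                        p3 = 2 + rnorm(3, 0, 0.1)), state = "B")
  upA <- computeUptake(a); upB <- computeUptake(b)
  expect_warning(ab <- differentialUptake(upA, upB), "universes differ")
  expect_warning(ba <- differentialUptake(upB, upA), "universes differ")
  expect_equal(ab$classification[ab$peptide == "p1"], "protected")
  expect_equal(ba$classification[ba$peptide == "p1"], "deprotected")
  expect_equal(ab$classification[ab$peptide == "p2"], "deprotected")
  expect_equal(ba$classification[ba$peptide == "p2"], "protected")
  expect_equal(ab$classification[ab$peptide == "p3"], "missing")
  expect_true(is.na(ab$delta_uptake[ab$peptide == "p3"]))
})

test_that("synthetic two-state HDX recovers its classification ground truth", {
  peps <- makePeptideMap(120, seed = 3)
  set.seed(3)
  deltas <- setNames(sample(c(-2, 0, 2), nrow(peps), replace = TRUE),
                     peps$peptide)
  sim <- simulateHdx(peps, deltas, noiseSd = 0.15, nReplicates = 3, seed = 4)
  ref <- computeUptake(sim$centroids[sim$centroids$state == "reference", ])
  var <- computeUptake(sim$centroids[sim$centroids$state == "variant", ])
  res <- differentialUptake(var, ref)
  truthOf <- function(d) if (d < 0) "protected" else if (d > 0) "deprotected"
    else "no_change"
  want <- vapply(res$peptide, function(p) truthOf(deltas[[p]]), character(1))
  expect_gte(mean(res$classification == want), 0.95)
})

test_that("dropout peptides come back as missing", {
  peps <- makePeptideMap(40, seed = 5)
  sim <- simulateHdx(peps, noiseSd = 0.1, seed = 6,
                     dropout = peps$peptide[2])
  ref <- computeUptake(sim$centroids[sim$centroids$state == "reference", ])
  var <- computeUptake(sim$centroids[sim$centroids$state == "variant", ])
  res <- suppressWarnings(differentialUptake(var, ref))
  expect_true(all(res$classification[res$peptide == peps$peptide[2]] ==
                    "missing"))
})

test_that("uptake differences map onto per-residue structure annotations", {
  set.seed(7)
  toy <- makeToySystem(1, 30, 0, seed = 7)
  sys <- toy$system
  peptides <- data.frame(peptide = c("a", "b"), component = "toy",
                         start = c(5, 10), end = c(14, 20))
  results <- data.frame(peptide = c("a", "b"), timepoint = 60,
                        delta_uptake = c(-1, -2), p_value = 0.01,
                        classification = "protected")
  vals <- mapToStructure(results, peptides, sys)
  expect_equal(unname(vals["toy:6"]), -1)       # covered by a only
  expect_equal(unname(vals["toy:12"]), -1.5)    # overlap: mean of -1 and -2
  expect_equal(unname(vals["toy:18"]), -2)      # covered by b only
  expect_true(is.na(vals["toy:25"]))            # no coverage
  # brute-force per-residue averaging agrees everywhere
  brute <- sapply(seq_len(nBeads(sys)), function(i) {
    r <- sys@residue[i]
    cover <- results$delta_uptake[peptides$start <= r & peptides$end >= r]
    if (length(cover)) mean(cover) else NA_real_
  })
  expect_equal(unname(vals), brute)
  # the PDB annotation round-trips through the B-factor/occupancy fields
  f <- tempfile(fileext = ".pdb")
  mapToStructure(results, peptides, sys, file = f)
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  expect_equal(pdb$atom$b[12], -1.5, tolerance = 1e-2)
  expect_equal(pdb$atom$o[25], 0)               # uncovered: occupancy 0
  expect_equal(pdb$atom$o[12], 1)
})
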