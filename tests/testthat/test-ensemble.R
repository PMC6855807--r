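# hand-built ensemble: model i is the template shifted/perturbed, scores given
syntheticEnsemble <- function(sys, coordsList, totals) {
  m <- length(coordsList)
  rec <- data.frame(start = 1L, sweep = seq_len(m), replica = 1L,
                    xl_negloglik = totals, excluded_volume = 0,
                    connectivity = 0, psi_neglogprior = 0, total = totals,
                    psi_DSS = 0.1)
  arr <- array(unlist(coordsList), c(nrow(coordsList[[1]]), 3, m))
  new("ScoredEnsemble", records = rec, coords = arr, system = sys,
      metadata = list())
}

baseToy <- local({
  set.seed(100)
  makeToySystem(2, 12, 4, seed = 100)
})

test_that("top-model selection is an order statistic, invariant to shuffling", {
  sys <- baseToy$system
  co <- lapply(1:1000, function(i) beadCoords(sys) + i * 1e-3)
  set.seed(1)
  totals <- sample(1:1000)
  ens <- syntheticEnsemble(sys, co, totals)
  top <- selectTopModels(ens, 200)
  expect_equal(length(top), 200L)
  expect_equal(max(ensembleRecords(top)$total), 200)
  # permuting the storage order does not change the selected set
  perm <- sample(1:1000)
  shuffled <- ens[perm]
  top2 <- selectTopModels(shuffled, 200)
  expect_setequal(ensembleRecords(top2)$total, ensembleRecords(top)$total)
  # n = ensemble size returns everything; larger n errors
  expect_equal(length(selectTopModels(ens, 1000)), 1000L)
  expect_error(selectTopModels(ens, 1001), "fewer")
})

test_that("Kabsch superposition recovers exact transforms and rejects degeneracy", {
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  expect_lt(superpose(x, x)$rmsd, 1e-12)
  R <- randomRotation(); tv <- c(4, -2, 7)
  y <- t(R %*% t(x)) + matrix(tv, 20, 3, byrow = TRUE)
  fit <- superpose(y, x)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(fit$coords - x)), 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # degenerate geometry and too-few points are errors
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate|collinear")
  expect_error(superpose(x[1:2, ], x[1:2, ]), "3")
})

test_that("superposition agrees with the independent bio3d fit", {
  set.seed(3)
  for (i in 1:5) {
    a <- matrix(rnorm(12, sd = 5), 4, 3)
    b <- matrix(rnorm(12, sd = 5), 4, 3)
    ours <- superpose(a, b)
    theirs <- bio3d::fit.xyz(fixed = as.numeric(t(b)),
                             mobile = as.numeric(t(a)),
                             fixed.inds = 1:12, mobile.inds = 1:12)
    theirRmsd <- sqrt(mean(rowSums(
      (matrix(theirs, 4, 3, byrow = TRUE) - b)^2)))
    expect_equal(ours$rmsd, theirRmsd, tolerance = 1e-6)
  }
})

test_that("well-separated conformer groups are recovered exactly at k = 3", {
  sys <- baseToy$system
  set.seed(4)
  groups <- list(c(0, 0, 0), c(60, 0, 0), c(0, 70, 0))
  co <- list(); labels <- integer()
  b2 <- bodyBeads(sys, "body2")
  for (g in 1:3) for (i in 1:12) {
    xyz <- beadCoords(sys)
    xyz[b2, ] <- sweep(xyz[b2, ], 2, groups[[g]], "+") +
      matrix(rnorm(length(b2) * 3, 0, 0.2), length(b2), 3)
    co[[length(co) + 1]] <- xyz
    labels <- c(labels, g)
  }
  ens <- syntheticEnsemble(sys, co, seq_along(co))
  rep <- clusterModels(ens, k = 3, seed = 1)
  expect_equal(rep@k, 3L)
  expect_equal(sort(rep@populations), c(12L, 12L, 12L))
  # assignments match the generator labels up to label permutation
  tab <- table(labels, rep@assignments)
  expect_equal(sum(apply(tab, 1, max)), 36)
  expect_true(all(rep@precision < 1))
})

test_that("degenerate clustering cases behave as defined", {
  sys <- baseToy$system
  co <- lapply(1:5, function(i) beadCoords(sys))
  ens <- syntheticEnsemble(sys, co, 1:5)
  # duplicate models: single cluster with zero precision
  rep1 <- clusterModels(ens, k = 1, seed = 1)
  expect_equal(rep1@populations, 5L)
  expect_equal(rep1@precision, 0)
  expect_error(clusterModels(ens, k = 6), "exceeds")
  # k = 1 on distinct models: precision equals mean RMSD to the medoid
  set.seed(5)
  co2 <- lapply(1:4, function(i) beadCoords(sys) +
                  matrix(rnorm(nBeads(sys) * 3, 0, 1), nBeads(sys), 3))
  ens2 <- syntheticEnsemble(sys, co2, 1:4)
  rep2 <- clusterModels(ens2, k = 1, referenceBeads = seq_len(nBeads(sys)),
                        clusterBeads = seq_len(nBeads(sys)), seed = 1)
  sup <- lapply(co2, function(cc) superpose(cc, co2[[1]])$coords)
  D <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) D[i, j] <- coordRMSD(sup[[i]], sup[[j]])
  med <- which.min(rowMeans(D))
  expect_equal(rep2@centers, med)
  expect_equal(rep2@precision, mean(D[med, -med]), tolerance = 1e-6)
})

test_that("satisfaction counts strict sub-cutoff distances only", {
  sys <- baseToy$system
  df <- crossLinks(simulateCrosslinks(baseToy, 4, 0, seed = 6)$links)
  # place four links at controlled distances using a two-bead stub model
  co <- matrix(0, 8, 3)
  co[c(2, 4, 6, 8), 1] <- c(10, 10, 10, 40)
  stub <- new("SystemModel", coords = co, radii = rep(3, 8),
              component = rep("p", 8), residue = 1:8,
              bodyId = rep(0L, 8),
              segments = list(list(name = "s", beads = 1:8)), bodies = list())
  links4 <- CrossLinkSet(data.frame(protein1 = "p", residue1 = c(1, 3, 5, 7),
                                    protein2 = "p", residue2 = c(2, 4, 6, 8),
                                    linker = "DSS", id_score = 35,
                                    delta_s = 0.5, fdr = 0.01))
  expect_equal(satisfactionFraction(stub, links4), 0.75)
  stub@coords[8, 1] <- 10
  expect_equal(satisfactionFraction(stub, links4), 1.0)
  stub@coords[8, 1] <- 34
  expect_equal(satisfactionFraction(stub, links4), 0.75)  # exactly 34: unsatisfied
  # invariant under a global rigid motion
  R <- randomRotation()
  stub2 <- stub
  stub2@coords <- t(R %*% t(stub@coords)) + 11
  expect_equal(satisfactionFraction(stub2, links4),
               satisfactionFraction(stub, links4))
  expect_error(satisfactionFraction(stub, links4[0]), "empty")
})

test_that("cluster satisfaction reports best, max-single and aggregate", {
  co <- matrix(0, 4, 3)
  sys <- new("SystemModel", coords = co, radii = rep(3, 4),
             component = rep("p", 4), residue = 1:4, bodyId = rep(0L, 4),
             segments = list(list(name = "s", beads = 1:4)), bodies = list())
  links <- CrossLinkSet(data.frame(protein1 = "p", residue1 = c(1, 3),
                                   protein2 = "p", residue2 = c(2, 4),
                                   linker = "DSS", id_score = 35,
                                   delta_s = 0.5, fdr = 0.01))
  # member A satisfies link 1 only, member B satisfies link 2 only
  a <- co; a[2, 1] <- 10; a[4, 1] <- 100
  b <- co; b[2, 1] <- 100; b[4, 1] <- 10
  rep <- satisfactionReport(list(a, b), bestScoring = a, xls = links,
                            system = sys)
  expect_equal(rep$best_scoring_fraction, 0.5)
  expect_equal(rep$max_single_conformer_fraction, 0.5)
  expect_equal(rep$aggregate_fraction, 1.0)
  # single member: all three fractions coincide
  rep1 <- satisfactionReport(list(a), bestScoring = a, xls = links,
                             system = sys)
  expect_equal(rep1$best_scoring_fraction, rep1$aggregate_fraction)
  expect_equal(rep1$max_single_conformer_fraction, rep1$best_scoring_fraction)
  # aggregate equals a brute-force union count and grows monotonically
  set.seed(7)
  members <- lapply(1:6, function(i) {
    cc <- co; cc[c(2, 4), 1] <- sample(c(10, 100), 2, replace = TRUE); cc
  })
  agg <- sapply(seq_along(members), function(k)
    satisfactionReport(members[seq_len(k)], a, links, sys)$aggregate_fraction)
  expect_true(all(diff(agg) >= 0))
  union <- Reduce(`|`, lapply(members, function(cc)
    c(sqrt(sum((cc[1, ] - cc[2, ])^2)) < 34,
      sqrt(sum((cc[3, ] - cc[4, ])^2)) < 34)))
  expect_equal(agg[6], mean(union))
})

test_that("clusterSatisfaction fills fractions for every cluster", {
  sys <- baseToy$system
  set.seed(8)
  sim <- simulateCrosslinks(baseToy, 8, 0, seed = 8)
  co <- lapply(1:12, function(i) beadCoords(sys) +
                 matrix(rnorm(nBeads(sys) * 3, 0, 0.1), nBeads(sys), 3))
  ens <- syntheticEnsemble(sys, co, 1:12)
  rep <- clusterModels(ens, k = 2, seed = 1)
  rep <- clusterSatisfaction(rep, ens, sim$links)
  expect_length(rep@satisfaction, 2L)
  for (s in rep@satisfaction) {
    expect_gte(s$aggregate_fraction, s$max_single_conformer_fraction)
    expect_true(all(unlist(s) >= 0 & unlist(s) <= 1))
  }
})

test_that("the satisfaction table itemises distances and member counts", {
  co <- matrix(0, 4, 3)
  sys <- new("SystemModel", coords = co, radii = rep(3, 4),
             component = rep("p", 4), residue = 1:4, bodyId = rep(0L, 4),
             segments = list(list(name = "s", beads = 1:4)), bodies = list())
  links <- CrossLinkSet(data.frame(protein1 = "p", residue1 = c(1, 3),
                                   protein2 = "p", residue2 = c(2, 4),
                                   linker = "DSS", id_score = 35,
                                   delta_s = 0.5, fdr = 0.01))
  a <- co; a[2, 1] <- 10; a[4, 1] <- 100
  b <- co; b[2, 1] <- 100; b[4, 1] <- 10
  tab <- satisfactionTable(a, links, system = sys, members = list(a, b))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$distance, c(10, 100))
  expect_equal(tab$satisfied, c(TRUE, FALSE))
  expect_equal(tab$n_members_satisfying, c(1L, 1L))
})

test_that("body poses serialise to JSON with their bead counts", {
  m <- makeTinyModel(2, 5, 0)
  m <- applyTransform(m, "b1", diag(3), c(2, 0, 0))
  f <- tempfile(fileext = ".json")
  writePoses(m, f)
  poses <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(poses$name, c("b1", "b2"))
  expect_equal(poses$n_beads, c(5L, 5L))
  expect_equal(poses$translation[[1]], c(2, 0, 0))
})

test_that("the split-half diagnostic flags gross divergence only", {
  sys <- baseToy$system
  co <- lapply(1:400, function(i) beadCoords(sys))
  # identical halves by construction: KS statistic 0
  ens <- syntheticEnsemble(sys, co, rep(c(5, 7), 200))
  div <- convergenceSplit(ens, seed = 1)
  expect_lt(div$ks_statistic, 0.15)
  # halves five IQRs apart: flagged
  set.seed(9)
  totals <- c(rnorm(200, 0, 1), rnorm(200, 50, 1))
  ens2 <- syntheticEnsemble(sys, co, totals)
  # force the pathological split: first half low, second half high
  div2 <- convergenceSplit(ens2, seed = 1)
  # a random split mixes the modes, so this tests the statistic itself
  ksManual <- suppressWarnings(stats::ks.test(totals[1:200], totals[201:400]))
  expect_gt(unname(ksManual$statistic), 0.9)
  # same-distribution halves rarely exceed the threshold
  set.seed(10)
  hits <- 0
  for (i in 1:40) {
    tot <- rnorm(1000, 10, 2)
    e <- syntheticEnsemble(sys, co[rep(1, 1000)], tot)
    if (convergenceSplit(e, seed = i)$ks_statistic < 0.1) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})
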