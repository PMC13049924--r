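test_that("toy topology advertises counts consistent with selection", {
  toy <- buildToyTopology(2)
  expect_equal(nAtoms(toy$topology), 8L)          # 4 backbone atoms per residue

  cof <- buildToyTopology(5, withCofactors = TRUE)
  at <- atoms(cof$topology)
  expect_equal(sum(at$name == "FE"), 1L)
  expect_true(all(at$hetero[at$resname %in% c("HEM", "PLM")]))

  spec <- selectionSpec(residueRange = c(1, 5), backboneOnly = TRUE,
                        excludeHydrogens = TRUE)
  expect_equal(length(selectAtoms(cof$topology, spec)),
               5L * cof$counts$perResidueBackbone)

  expect_error(buildToyTopology(1), "nResidues")
})

test_that("mode trajectories realize the planted covariance spectrum", {
  toy <- buildToyTopology(8)
  modes <- randomModes(3 * nAtoms(toy$topology), 2, seed = 42)
  mt <- generateModeTrajectory(toy$topology, toy$coords, modes,
                               amplitudes = c(1.0, 0.5), nFrames = 5000,
                               noiseSd = 0, seed = 7)
  # independent oracle: dense covariance eigendecomposition of the frames
  X <- essdyn:::flattenFrames(coords(mt$ensemble))
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev[1], 1.0, tolerance = 0.05)
  expect_equal(ev[2], 0.25, tolerance = 0.05)
  expect_lt(ev[3], 1e-10)

  # two forced frames with scores +1/-1: PC1 is the planted mode up to sign
  mt2 <- generateModeTrajectory(toy$topology, toy$coords, modes[, 1, drop = FALSE],
                                amplitudes = 1, nFrames = 2, seed = 1,
                                scores = matrix(c(1, -1), 2, 1))
  X2 <- essdyn:::flattenFrames(coords(mt2$ensemble))
  v1 <- eigen(stats::cov(X2), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(v1 * modes[, 1])), 1, tolerance = 1e-10)

  # degenerate: zero amplitude, zero noise -> constant trajectory
  mt3 <- generateModeTrajectory(toy$topology, toy$coords, modes[, 1, drop = FALSE],
                                amplitudes = 0, nFrames = 4, seed = 1)
  expect_equal(max(abs(sweep(essdyn:::flattenFrames(coords(mt3$ensemble)), 2,
                             as.numeric(t(toy$coords))))), 0)

  expect_error(generateModeTrajectory(toy$topology, toy$coords,
                                      cbind(modes[, 1], modes[, 1]),
                                      c(1, 0.5), 10, seed = 1),
               "orthonormal")
})

test_that("generators are seed-deterministic and return their ground truth", {
  toy <- buildToyTopology(6)
  modes <- randomModes(3 * nAtoms(toy$topology), 2, seed = 5)
  a <- generateModeTrajectory(toy$topology, toy$coords, modes, c(1, 0.5),
                              nFrames = 20, noiseSd = 0.1, seed = 99)
  b <- generateModeTrajectory(toy$topology, toy$coords, modes, c(1, 0.5),
                              nFrames = 20, noiseSd = 0.1, seed = 99)
  expect_identical(coords(a$ensemble), coords(b$ensemble))
  expect_identical(a$scores, b$scores)

  ctr <- makeStateCenters(toy$coords, 3, separation = 4, seed = 3)
  d1 <- dist(t(sapply(ctr, function(m) as.numeric(t(m)))))
  expect_equal(as.numeric(d1), rep(4, 3), tolerance = 1e-12)

  m1 <- generateMetastableEnsemble(toy$topology, ctr, 10, 0.2, seed = 11)
  m2 <- generateMetastableEnsemble(toy$topology, ctr, 10, 0.2, seed = 11)
  expect_identical(coords(m1$ensemble), coords(m2$ensemble))
  expect_identical(m1$labels, m2$labels)
})

test_that("metastable ensembles honor K = 1 and the overlap limit", {
  toy <- buildToyTopology(6)
  ctr1 <- makeStateCenters(toy$coords, 1, separation = 5, seed = 2)
  m <- generateMetastableEnsemble(toy$topology, ctr1, 12, 0.1, seed = 4)
  expect_true(all(m$labels == 1L))

  # overlapFactor -> 0 collapses all centers onto the grand mean
  ctr3 <- makeStateCenters(toy$coords, 3, separation = 8, seed = 2)
  m0 <- generateMetastableEnsemble(toy$topology, ctr3, 30, 0.05,
                                   overlapFactor = 0, seed = 4)
  X <- essdyn:::flattenFrames(coords(m0$ensemble))
  stateMeans <- sapply(1:3, function(k) colMeans(X[m0$labels == k, ]))
  expect_lt(max(dist(t(stateMeans))), 0.2)        # single effective cluster
})

test_that("hydrogen-bond scenarios hit their planted occupancy schedules", {
  toy <- buildToyTopology(6, withSidechains = TRUE)
  tri <- data.frame(donor = toy$donors$donor[c(2, 4)],
                    hydrogen = toy$donors$hydrogen[c(2, 4)],
                    acceptor = c(which(atoms(toy$topology)$name == "O" &
                                         atoms(toy$topology)$resid == 5),
                                 which(atoms(toy$topology)$name == "O" &
                                         atoms(toy$topology)$resid == 1)))
  occ <- matrix(c(1, 0, 0.7, 0.2), 2, 2, dimnames = list(NULL, c("A", "B")))
  sc <- generateHbondScenario(toy$topology, toy$coords, tri, occ,
                              nFramesPerCondition = 200, seed = 31)
  # occupancy 1 -> on in every frame; occupancy 0 -> never
  expect_equal(sc$realized$A[[1]], 1)
  expect_equal(sc$realized$A[[2]], 0)
  # stochastic occupancies within binomial 99% bounds of the plan
  for (ti in 1:2) {
    p <- occ[ti, "B"]
    half <- 2.576 * sqrt(p * (1 - p) / 200)
    expect_lt(abs(sc$realized$B[[ti]] - p), half + 1e-12)
  }
  # an invalid bound geometry is rejected
  expect_error(
    generateHbondScenario(toy$topology, toy$coords, tri, occ,
                          boundGeometry = list(distance = 3.4, deviation = 5),
                          seed = 1),
    "bound geometry")
})

test_that("spectroscopic generators reproduce their analytic limits", {
  # titration with E << Kd is indistinguishable from the hyperbola
  S <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
  ti <- generateSpectroDataset("titration", list(Kd = 10, dAmax = 0.1, E = 1e-5),
                               design = S, seed = 1)
  expect_equal(ti$data$dA, 0.1 * S / (S + 10), tolerance = 1e-6)

  # melting: half-transition exactly at the planted Tm
  me <- generateSpectroDataset("melting",
                               list(Tm = 51, slope = 2, lower = -10, upper = -2),
                               design = seq(20, 100, 0.5), seed = 1)
  atTm <- boltzmannSignal(51, 51, 2, -10, -2)
  expect_equal(atTm, (-10 + -2) / 2)

  # kinetics truth record carries the generating parameters
  ki <- generateSpectroDataset("kinetics",
                               list(A1 = 0.05, k1 = 183, A2 = 0.03, k2 = 24.1,
                                    offset = 0.4),
                               design = seq(0, 0.2, length.out = 100), seed = 1)
  expect_equal(ki$truth$k1, 183)
  expect_equal(ki$data$absorbance[1], 0.05 + 0.03 + 0.4)

  expect_error(generateSpectroDataset("melting",
                                      list(Tm = 150, slope = 2, lower = 0, upper = 1),
                                      design = seq(20, 100, 1), seed = 1),
               "Tm")
})
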