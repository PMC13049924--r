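test_that("Kabsch superposition recovers exact rigid transforms", {
  toy <- buildToyTopology(5)
  ref <- toy$coords
  # identity
  r0 <- kabschSuperpose(ref, ref)
  expect_equal(r0$rmsd, 0, tolerance = 1e-12)
  expect_equal(r0$rotation, diag(3), tolerance = 1e-9)

  # 90 degree rotation about z plus translation is undone exactly
  mob <- sweep(ref %*% t(rotationZ(90)), 2, c(5, 0, 0), `+`)
  r1 <- kabschSuperpose(mob, ref)
  expect_lt(r1$rmsd, 1e-9)
  expect_equal(r1$coords, ref, tolerance = 1e-9)
  expect_equal(det(r1$rotation), 1, tolerance = 1e-9)

  expect_error(kabschSuperpose(ref[1:2, ], ref[1:2, ]), "degenerate")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "collinear")
})

test_that("Kabsch RMSD equals brute-force minimization over rotations", {
  set.seed(17)
  ref <- matrix(rnorm(30), 10, 3)
  mob <- ref + matrix(rnorm(30, sd = 0.3), 10, 3)
  got <- kabschSuperpose(mob, ref)$rmsd
  # independent oracle: numeric optimization over Euler angles + translation
  obj <- function(p) {
    cz <- cos(p[1]); sz <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cx <- cos(p[3]); sx <- sin(p[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    out <- sweep(mob %*% t(Rz %*% Ry %*% Rx), 2, p[4:6], `+`)
    sqrt(mean(rowSums((out - ref)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    o <- stats::optim(c(rnorm(3, sd = 0.5), rnorm(3, sd = 0.5)), obj,
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(got, best, tolerance = 1e-6)
  # and no rigid pre-transformation can change the minimum
  pre <- sweep(mob %*% t(rotationZ(33)), 2, c(1, -2, 3), `+`)
  expect_equal(kabschSuperpose(pre, ref)$rmsd, got, tolerance = 1e-9)
})

test_that("ensemble alignment is optimal and idempotent", {
  toy <- buildToyTopology(6)
  # same structure scattered at random placements
  set.seed(3)
  frames <- lapply(1:5, function(f)
    sweep(toy$coords %*% t(rotationZ(runif(1, 0, 360))), 2, rnorm(3, sd = 10), `+`))
  ens <- toyEnsemble(toy$topology, frames)
  al <- alignEnsemble(ens)
  for (f in 2:5)
    expect_equal(frameCoords(al, f), frameCoords(al, 1), tolerance = 1e-9)

  # alignment never increases the fit RMSD, and aligning twice = aligning once
  set.seed(4)
  noisy <- lapply(1:6, function(f) toy$coords + matrix(rnorm(72, sd = 0.2), ncol = 3))
  ens2 <- toyEnsemble(toy$topology, noisy)
  al2 <- alignEnsemble(ens2)
  fitIdx <- selectAtoms(toy$topology, selectionSpec(backboneOnly = TRUE, excludeHydrogens = TRUE))
  for (f in 1:6) {
    pre <- sqrt(mean(rowSums((frameCoords(ens2, f)[fitIdx, ] - frameCoords(ens2, 1)[fitIdx, ])^2)))
    post <- sqrt(mean(rowSums((frameCoords(al2, f)[fitIdx, ] - frameCoords(al2, 1)[fitIdx, ])^2)))
    expect_lte(post, pre + 1e-12)
  }
  al3 <- alignEnsemble(al2)
  expect_equal(coords(al3), coords(al2), tolerance = 1e-9)
})

test_that("PCA matches a dense brute-force eigendecomposition", {
  toy <- buildToyTopology(5)                       # 20 atoms
  modes <- randomModes(60, 3, seed = 12)
  mt <- generateModeTrajectory(toy$topology, toy$coords, modes,
                               amplitudes = c(0.8, 0.5, 0.3), nFrames = 50,
                               noiseSd = 0.05, seed = 13)
  pm <- pcaHeavyAtoms(mt$ensemble, varianceTarget = 0.75)
  # oracle: eigen() of the explicit covariance matrix
  X <- essdyn:::flattenFrames(coords(mt$ensemble))
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  nc <- ncol(pm@loadings)
  expect_equal(pm@eigenvalues, eg$values[seq_len(nc)], tolerance = 1e-8)
  for (k in 1:5)
    expect_equal(abs(sum(pm@loadings[, k] * eg$vectors[, k])), 1, tolerance = 1e-8)
  # eigenvalue conservation: sum(lambda) = total variance
  expect_equal(sum(pm@eigenvalues), sum(diag(stats::cov(X))), tolerance = 1e-8)
})

test_that("the cumulative-variance target retains the planted component count", {
  toy <- buildToyTopology(8)
  modes <- randomModes(3 * nAtoms(toy$topology), 2, seed = 21)
  mt <- generateModeTrajectory(toy$topology, toy$coords, modes,
                               amplitudes = c(1.0, 0.5), nFrames = 4000,
                               noiseSd = 0, seed = 22)
  pm <- pcaHeavyAtoms(mt$ensemble, varianceTarget = 0.75)
  # planted ratio 1.0^2/(1.0^2+0.5^2) = 0.8 >= 0.75 -> K = 1
  expect_equal(pm@retained, 1L)
  expect_equal(pm@cumulativeVariance[1], 0.8, tolerance = 0.02)
  # planted modes recovered up to sign
  expect_gt(abs(sum(pm@loadings[, 1] * modes[, 1])), 0.99)
  expect_gt(abs(sum(pm@loadings[, 2] * modes[, 2])), 0.99)

  const <- toyEnsemble(toy$topology, list(toy$coords, toy$coords, toy$coords))
  expect_warning(pmc <- pcaHeavyAtoms(const), "K = 0")
  expect_equal(pmc@retained, 0L)
  expect_error(pcaHeavyAtoms(toyEnsemble(toy$topology, list(toy$coords))),
               "insufficient frames")
})

test_that("projection and reconstruction obey the Pythagorean decomposition", {
  toy <- buildToyTopology(6)
  modes <- randomModes(3 * nAtoms(toy$topology), 2, seed = 31)
  mt <- generateModeTrajectory(toy$topology, toy$coords, modes,
                               amplitudes = c(1.0, 0.5), nFrames = 500,
                               noiseSd = 0.02, seed = 32)
  pm <- pcaHeavyAtoms(mt$ensemble, varianceTarget = 0.75)

  # the mean structure projects to zero
  meanEns <- toyEnsemble(toy$topology, list(essdyn:::unflattenFrame(pm@mean)))
  expect_equal(as.numeric(projectFrames(pm, meanEns)), 0, tolerance = 1e-10)

  # mean + c v1 projects to (c, 0, ...)
  disp <- essdyn:::unflattenFrame(pm@mean + 2.5 * pm@loadings[, 1])
  sc <- projectFrames(pm, toyEnsemble(toy$topology, list(disp)),
                      nComponents = ncol(pm@loadings))
  expect_equal(sc[1, 1], 2.5, tolerance = 1e-10)
  expect_equal(max(abs(sc[1, -1])), 0, tolerance = 1e-10)

  # residual variance after K components is bounded by the unexplained share
  scores <- projectFrames(pm, mt$ensemble)
  X <- essdyn:::flattenFrames(coords(mt$ensemble))
  Xc <- sweep(X, 2, pm@mean)
  recon <- scores %*% t(pm@loadings[, seq_len(pm@retained), drop = FALSE])
  resid <- sum((Xc - recon)^2) / (nrow(X) - 1)
  total <- sum(Xc^2) / (nrow(X) - 1)
  expect_lte(resid, (1 - pm@cumulativeVariance[pm@retained]) * total + 1e-8)
})

test_that("the essential-dynamics score matches its analytic values", {
  toy <- buildToyTopology(4)
  nF <- 10
  # one atom (residue 2's CA) oscillates on x with sample variance exactly 1
  amp <- sqrt((nF - 1) / nF)
  frames <- lapply(1:nF, function(f) {
    crd <- toy$coords
    crd[6, 1] <- crd[6, 1] + amp * (-1)^f
    crd
  })
  ens <- toyEnsemble(toy$topology, frames)
  pm <- pcaHeavyAtoms(ens, varianceTarget = 0.75)
  ed <- essentialDynamicsScore(pm, toy$topology)
  expect_equal(ed$perAtom$B[6], 8 * pi^2 / 3, tolerance = 1e-8)
  expect_equal(max(ed$perAtom$B[-6]), 0, tolerance = 1e-8)
  # residue score is the mean over the residue's atoms (4 backbone atoms)
  expect_equal(ed$perResidue$B[ed$perResidue$resid == 2], (8 * pi^2 / 3) / 4,
               tolerance = 1e-8)

  # full-K score equals 8pi^2/3 x per-atom total variance (trace identity)
  modes <- randomModes(3 * nAtoms(toy$topology), 3, seed = 41)
  mt <- generateModeTrajectory(toy$topology, toy$coords, modes,
                               amplitudes = c(0.9, 0.6, 0.3), nFrames = 80,
                               noiseSd = 0.05, seed = 42)
  pm2 <- pcaHeavyAtoms(mt$ensemble)
  edFull <- essentialDynamicsScore(pm2, toy$topology,
                                   nComponents = ncol(pm2@loadings))
  X <- essdyn:::flattenFrames(coords(mt$ensemble))
  v <- apply(X, 2, stats::var)
  atomVar <- v[seq(1, length(v), 3)] + v[seq(2, length(v), 3)] + v[seq(3, length(v), 3)]
  expect_equal(edFull$perAtom$B, (8 * pi^2 / 3) * atomVar, tolerance = 1e-8)

  # B is monotone nondecreasing in the number of retained components
  for (k in 2:4) {
    lo <- essentialDynamicsScore(pm2, toy$topology, nComponents = k - 1)
    hi <- essentialDynamicsScore(pm2, toy$topology, nComponents = k)
    expect_true(all(hi$perAtom$B >= lo$perAtom$B - 1e-12))
  }

  const <- toyEnsemble(toy$topology, list(toy$coords, toy$coords))
  suppressWarnings(pmc <- pcaHeavyAtoms(const))
  expect_error(essentialDynamicsScore(pmc, toy$topology), "undefined score")
})
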