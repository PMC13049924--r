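test_that("donor/acceptor catalogs follow the covalent-assignment rule", {
  toy <- buildToyTopology(6, withSidechains = TRUE)
  cats <- assignDonorsAcceptors(toy$topology, toy$coords)
  # generator bookkeeping oracle: OG-HG pairs at 0.96 Angstrom are donors,
  # every N and O is an acceptor
  expect_identical(cats$donors$donor, toy$donors$donor)
  expect_identical(cats$donors$hydrogen, toy$donors$hydrogen)
  expect_identical(cats$acceptors, toy$acceptors)
  # backbone carbonyl O (no attached H) is acceptor only
  oIdx <- which(atoms(toy$topology)$name == "O")
  expect_true(all(oIdx %in% cats$acceptors))
  expect_false(any(oIdx %in% cats$donors$donor))

  noH <- buildToyTopology(4)
  expect_warning(c2 <- assignDonorsAcceptors(noH$topology, noH$coords),
                 "no hydrogens")
  expect_equal(nrow(c2$donors), 0L)
})

test_that("geometric detection applies both cutoffs against a trig oracle", {
  at <- data.frame(serial = 1:3, name = c("OG", "HG", "O"),
                   elem = c("O", "H", "O"), resname = c("SER", "SER", "GLY"),
                   resid = c(1L, 1L, 2L), chain = "A", insert = "",
                   hetero = FALSE)
  topo <- new("Topology", atoms = at)
  cats <- list(donors = data.frame(donor = 1L, hydrogen = 2L), acceptors = c(1L, 3L))

  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  expect_equal(nrow(detectHbondsFrame(collinear, topo, cats)), 1L)

  tooFar <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.05, 0, 0))
  expect_equal(nrow(detectHbondsFrame(tooFar, topo, cats)), 0L)

  # D-A = 2.8 but D-H-A angle 150 degrees (deviation 30) -> rejected.
  # Acceptor position solved independently: angle at H of 150 deg with
  # |DH| = 1, |DA| = 2.8  =>  r = cos(30)+sqrt(2.8^2-sin(30)^2) via the
  # law of cosines, direction rotated 30 deg off the D->H axis.
  dl <- 30 * pi / 180
  r <- -1 * cos(dl) + sqrt(2.8^2 - sin(dl)^2)
  A <- c(1, 0, 0) + r * c(cos(dl), sin(dl), 0)
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), A)
  expect_equal(sqrt(sum((bent[3, ] - bent[1, ])^2)), 2.8, tolerance = 1e-12)
  ang <- acos(sum((bent[1, ] - bent[2, ]) * (bent[3, ] - bent[2, ])) /
                (1 * sqrt(sum((bent[3, ] - bent[2, ])^2)))) * 180 / pi
  expect_equal(ang, 150, tolerance = 1e-9)
  expect_equal(nrow(detectHbondsFrame(bent, topo, cats)), 0L)

  # detection is invariant under global rigid motion
  moved <- sweep(collinear %*% t(rotationZ(57)), 2, c(3, -2, 8), `+`)
  expect_equal(nrow(detectHbondsFrame(moved, topo, cats)), 1L)
})

test_that("occupancy equals the per-frame recount and binomial bounds hold", {
  toy <- buildToyTopology(6, withSidechains = TRUE)
  cats <- assignDonorsAcceptors(toy$topology, toy$coords)
  don <- toy$donors[2, ]
  accO <- which(atoms(toy$topology)$name == "O" & atoms(toy$topology)$resid == 5)

  # planted: bond on in exactly 7 of 10 frames
  onPos <- essdyn:::placeAcceptor(toy$coords[don$donor, ], toy$coords[don$hydrogen, ],
                                  2.8, 5)
  offPos <- essdyn:::placeAcceptor(toy$coords[don$donor, ], toy$coords[don$hydrogen, ],
                                   4.5, 0)
  frames <- lapply(1:10, function(f) {
    crd <- toy$coords
    crd[accO, ] <- if (f <= 7) onPos else offPos
    crd
  })
  ens <- toyEnsemble(toy$topology, frames)
  tab <- hbondOccupancy(ens, cats)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$occupancy, 0.7)
  expect_equal(tab$res1, "A:SER2")
  expect_equal(tab$res2, "A:SER5")

  # a bond that is never satisfied is absent from the table
  ensOff <- toyEnsemble(toy$topology, rep(list(frames[[10]]), 3))
  expect_equal(nrow(hbondOccupancy(ensOff, cats)), 0L)

  # full scenario: empirical occupancies within binomial 99% bounds
  tri <- data.frame(donor = toy$donors$donor[c(1, 3)],
                    hydrogen = toy$donors$hydrogen[c(1, 3)],
                    acceptor = which(atoms(toy$topology)$name == "O" &
                                       atoms(toy$topology)$resid %in% c(5, 6)))
  occ <- matrix(c(0.7, 0.1, 0.2, 0.8), 2, 2, dimnames = list(NULL, c("20C", "30C")))
  sc <- generateHbondScenario(toy$topology, toy$coords, tri, occ,
                              nFramesPerCondition = 200, seed = 77)
  for (cond in c("20C", "30C")) {
    tabC <- hbondOccupancy(sc$ensembles[[cond]], cats)
    for (ti in 1:2) {
      p <- occ[ti, cond]
      bound <- 2.576 * sqrt(p * (1 - p) / 200)
      donorTag <- essdyn:::resTag(toy$topology)[tri$donor[ti]]
      row <- tabC[tabC$res1 == donorTag | tabC$res2 == donorTag, ]
      expect_equal(nrow(row), 1L)
      expect_lt(abs(row$occupancy - p), bound)
      # and the table exactly matches the generator's realized draw
      expect_equal(row$occupancy, sc$realized[[cond]][[ti]])
    }
  }
})

test_that("differential networks report antisymmetric condition switches", {
  tabA <- data.frame(res1 = c("A:SER2", "A:SER3"), res2 = c("A:GLU5", "A:SER6"),
                     occupancy = c(0.7, 0.1), nFrames = 200, triads = "OG->O")
  tabB <- data.frame(res1 = c("A:SER2", "A:SER3"), res2 = c("A:GLU5", "A:SER6"),
                     occupancy = c(0.2, 0.8), nFrames = 200, triads = "OG->O")

  ed <- differentialNetwork(tabA, tabB, 0.3, "20C", "30C")
  expect_equal(nrow(ed), 2L)
  sw <- ed[ed$res1 == "A:SER2", ]
  expect_equal(sw$delta, 0.5)
  expect_equal(sw$enriched, "20C")
  expect_equal(ed$enriched[ed$res1 == "A:SER3"], "30C")

  # swapping the tables negates every delta while the same physical
  # condition stays enriched
  edR <- differentialNetwork(tabB, tabA, 0.3, "30C", "20C")
  m <- match(paste(ed$res1, ed$res2), paste(edR$res1, edR$res2))
  expect_equal(edR$delta[m], -ed$delta)
  expect_equal(edR$enriched[m], ed$enriched)

  # identical tables -> empty edge list; missing pairs count as occupancy 0
  expect_equal(nrow(differentialNetwork(tabA, tabA, 0.25)), 0L)
  ed0 <- differentialNetwork(tabA, tabA[1, ], 0.05)
  expect_equal(ed0$occupancyB[ed0$res1 == "A:SER3"], 0)

  expect_error(differentialNetwork(tabA, tabB, 0), "deltaThreshold")
  expect_error(differentialNetwork(tabA, tabB, 1.2), "deltaThreshold")
})

test_that("edge tables export as CSV and SIF", {
  ed <- data.frame(res1 = "A:SER2", res2 = "A:GLU5", occupancyA = 0.7,
                   occupancyB = 0.2, delta = 0.5, enriched = "20C")
  tf <- withr::local_tempfile(fileext = ".csv")
  writeEdgeTable(ed, tf, "csv")
  back <- read.csv(tf)
  expect_equal(back$source, "A:SER2")
  expect_equal(back$delta, 0.5)
  tf2 <- withr::local_tempfile(fileext = ".sif")
  writeEdgeTable(ed, tf2, "sif")
  expect_equal(readLines(tf2), "A:SER2 hbond-20C A:GLU5")
})
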