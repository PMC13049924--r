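# Synthetic-data generators. Every input the pipeline consumes can be built
# here with planted ground truth (low-rank covariance modes, metastable
# states, hydrogen-bond occupancy schedules, residue-substrate coupling,
# spectroscopic curves), so all downstream stages are testable without MD
# runs. All generators take a mandatory seed and are seed-deterministic; each
# returns its ground truth alongside the data.

#' Build a toy protein-like topology
#'
#' Constructs a linear chain of residues with backbone atoms N/CA/C/O and,
#' optionally, a serine-like polar sidechain (OG with a covalent HG hydrogen,
#' giving each residue a hydrogen-bond donor) and cofactor groups: a HEM
#' hetero-residue carrying an FE atom and two propionate-like oxygens, and a
#' PLM (palmitate) hetero-residue carrying a carboxylate head and atoms named
#' CA and CB (the substrate Calpha and Cbeta). The returned bookkeeping
#' (atom counts per canonical selection, donor/acceptor catalogs) serves as an
#' independent oracle for selection and hydrogen-bond tests.
#'
#' @param nResidues number of protein residues (>= 2).
#' @param withCofactors add the HEM and PLM groups.
#' @param withSidechains add OG/HG serine-like sidechains (residues become
#'   SER; without, they are ALA with no hydrogens).
#' @param resnames optional character vector of residue names (length
#'   `nResidues`) overriding the default, e.g. to plant a charged-residue
#'   census.
#' @return list with `topology` ([Topology]), `coords` (`N x 3` reference
#'   frame), `counts` (advertised atom counts: `perResidueBackbone`, `hem`,
#'   `plm`, `hydrogens`), `donors` (`data.frame` of donor/hydrogen atom
#'   indices) and `acceptors` (indices of all N/O atoms).
#' @export
buildToyTopology <- function(nResidues, withCofactors = FALSE,
                             withSidechains = FALSE, resnames = NULL) {
  if (nResidues < 2L) stop("nResidues must be >= 2")
  if (is.null(resnames))
    resnames <- rep(if (withSidechains) "SER" else "ALA", nResidues)
  stopifnot(length(resnames) == nResidues)
  rows <- list(); xyz <- list()
  addAtom <- function(name, elem, resname, resid, hetero, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = 0L, name = name, elem = elem, resname = resname,
      resid = resid, chain = "A", insert = "", hetero = hetero,
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- pos
  }
  for (i in seq_len(nResidues)) {
    x <- 4 * (i - 1)
    addAtom("N",  "N", resnames[i], i, FALSE, c(x, 0, 0))
    addAtom("CA", "C", resnames[i], i, FALSE, c(x + 1.2, 0.8, 0))
    addAtom("C",  "C", resnames[i], i, FALSE, c(x + 2.5, 0, 0))
    addAtom("O",  "O", resnames[i], i, FALSE, c(x + 2.5, 1.2, 0.8))
    if (withSidechains) {
      og <- c(x + 1.2, 2.2, 0.3)
      addAtom("OG", "O", resnames[i], i, FALSE, og)
      addAtom("HG", "H", resnames[i], i, FALSE, og + c(0.96, 0, 0))
    }
  }
  cx <- 4 * (nResidues - 1) / 2
  if (withCofactors) {
    fe <- c(cx, 8, 0)
    addAtom("FE",  "FE", "HEM", 901L, TRUE, fe)
    addAtom("O1A", "O",  "HEM", 901L, TRUE, fe + c(1.8, 1.2, 0))
    addAtom("O2A", "O",  "HEM", 901L, TRUE, fe + c(-1.8, 1.2, 0))
    cb <- fe + c(0, 4.5, 0)
    addAtom("CB", "C", "PLM", 902L, TRUE, cb)
    addAtom("CA", "C", "PLM", 902L, TRUE, cb + c(1.5, 0, 0))
    c1 <- cb + c(0, 1.5, 0)
    addAtom("C1", "C", "PLM", 902L, TRUE, c1)
    addAtom("O1", "O", "PLM", 902L, TRUE, c1 + c(0.9, 1.0, 0))
    addAtom("O2", "O", "PLM", 902L, TRUE, c1 + c(-0.9, 1.0, 0))
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  topo <- new("Topology", atoms = at)
  crd <- do.call(rbind, xyz)
  donors <- if (withSidechains) {
    og <- which(at$name == "OG")
    hg <- which(at$name == "HG")
    data.frame(donor = og, hydrogen = hg)
  } else data.frame(donor = integer(0), hydrogen = integer(0))
  list(topology = topo, coords = crd,
       counts = list(perResidueBackbone = 4L,
                     hem = if (withCofactors) 3L else 0L,
                     plm = if (withCofactors) 5L else 0L,
                     hydrogens = if (withSidechains) nResidues else 0L),
       donors = donors,
       acceptors = which(at$elem %in% c("N", "O")))
}

#' Random orthonormal mode vectors
#'
#' QR-based orthonormal basis of a seeded Gaussian matrix, for planting
#' low-rank covariance modes.
#'
#' @param dim3N dimension (3 x atom count).
#' @param nModes number of mode vectors.
#' @param seed RNG seed.
#' @return `dim3N x nModes` matrix with orthonormal columns.
#' @export
randomModes <- function(dim3N, nModes, seed) {
  withSeed(seed, {
    M <- matrix(stats::rnorm(dim3N * nModes), dim3N, nModes)
    qr.Q(qr(M))[, seq_len(nModes), drop = FALSE]
  })
}

#' Generate a trajectory with planted covariance modes
#'
#' Frames are `reference + sum_m a_m(t) mode_m + noise` with
#' `a_m(t) ~ Normal(0, amplitude_m^2)`, so the population covariance has the
#' planted modes as eigenvectors with eigenvalues `amplitude_m^2` (plus
#' isotropic noise). Used to verify PCA recovery.
#'
#' @param topology a [Topology].
#' @param reference `N x 3` reference coordinates.
#' @param modes `3N x M` matrix of mutually orthonormal mode vectors.
#' @param amplitudes per-mode standard deviations (Angstrom), strictly
#'   decreasing and positive, so PC order is unambiguous.
#' @param nFrames number of frames.
#' @param noiseSd isotropic per-coordinate jitter sd (Angstrom).
#' @param seed RNG seed.
#' @param scores optional `nFrames x M` matrix of mode scores to use instead
#'   of sampling (e.g. to force a two-frame `(+1, -1)` trajectory).
#' @return list with `ensemble` ([TrajectoryEnsemble]) and `scores` (the mode
#'   scores actually used — the planted truth).
#' @export
generateModeTrajectory <- function(topology, reference, modes, amplitudes,
                                   nFrames, noiseSd = 0, seed = 1L,
                                   scores = NULL) {
  n3 <- 3L * nAtoms(topology)
  if (nrow(modes) != n3) stop("mode vectors must have dimension 3N")
  G <- crossprod(modes)
  if (max(abs(G - diag(ncol(modes)))) > 1e-8)
    stop("mode vectors must be mutually orthonormal")
  if (length(amplitudes) != ncol(modes))
    stop("one amplitude per mode is required")
  if (any(amplitudes < 0) || (length(amplitudes) > 1 && any(diff(amplitudes) >= 0)))
    stop("amplitudes must be nonnegative and strictly decreasing")
  refFlat <- as.numeric(t(reference))
  out <- withSeed(seed, {
    a <- if (is.null(scores)) {
      matrix(stats::rnorm(nFrames * length(amplitudes)), nFrames) %*%
        diag(amplitudes, nrow = length(amplitudes))
    } else scores
    X <- matrix(refFlat, nFrames, n3, byrow = TRUE) + a %*% t(modes)
    if (noiseSd > 0) X <- X + matrix(stats::rnorm(length(X), sd = noiseSd), nrow = nFrames)
    list(X = X, a = a)
  })
  arr <- array(0, c(nFrames, nAtoms(topology), 3L))
  for (f in seq_len(nFrames)) arr[f, , ] <- unflattenFrame(out$X[f, ])
  list(ensemble = newEnsemble(topology, arr), scores = out$a)
}

#' State centers for a planted metastable ensemble
#'
#' Displaces the reference structure along `K` random orthonormal 3N
#' directions, scaled so every pair of centers is `separation` Angstrom apart
#' (Euclidean distance in flattened coordinate space), giving K well-defined,
#' equidistant conformational state centers.
#'
#' @param reference `N x 3` reference coordinates.
#' @param K number of states.
#' @param separation pairwise center distance (Angstrom).
#' @param seed RNG seed.
#' @return list of `K` `N x 3` center matrices.
#' @export
makeStateCenters <- function(reference, K, separation, seed) {
  dirs <- randomModes(3L * nrow(reference), K, seed)
  # orthonormal displacements are sqrt(2) apart; rescale to `separation`
  lapply(seq_len(K), function(k)
    reference + (separation / sqrt(2)) * unflattenFrame(dirs[, k]))
}

#' Generate a metastable-state ensemble with known labels
#'
#' Frames are drawn around each state center with within-state fluctuation
#' that mimics MD: a few shared low-rank collective modes of spread
#' `withinStateSd` (collective motions dominate real trajectory covariance;
#' purely isotropic full-rank noise would let uninformative dimensions
#' swamp the cumulative-variance target of the downstream PCA) plus a small
#' isotropic jitter. `overlapFactor` scales the spread of the centers about
#' their grand mean: 1 keeps the planted separation ("well-separated,
#' compact clusters"), values toward 0 collapse the centers into partially
#' overlapping, then single, clusters — emulating the two regimes the
#' temperature conditions show.
#'
#' @param topology a [Topology].
#' @param stateCenters list of `N x 3` center matrices.
#' @param framesPerState integer count per state (recycled to K).
#' @param withinStateSd spread (Angstrom) along the leading within-state
#'   mode; further modes decay to 60% of it.
#' @param overlapFactor scalar in `[0, 1]` scaling center separation.
#' @param withinModes number of shared within-state collective modes
#'   (default 3).
#' @param jitterFraction isotropic per-coordinate jitter sd as a fraction of
#'   `withinStateSd` (default 0.1).
#' @param condition,temperature condition metadata for the ensemble.
#' @param seed RNG seed.
#' @return list with `ensemble` and `labels` (true per-frame state ids, the
#'   planted truth for ARI scoring).
#' @export
generateMetastableEnsemble <- function(topology, stateCenters, framesPerState,
                                       withinStateSd, overlapFactor = 1,
                                       withinModes = 3L, jitterFraction = 0.1,
                                       condition = "cond",
                                       temperature = NA_real_, seed = 1L) {
  K <- length(stateCenters)
  stopifnot(K >= 1L)
  framesPerState <- rep_len(as.integer(framesPerState), K)
  stopifnot(all(framesPerState >= 1L))
  n <- nAtoms(topology)
  grand <- Reduce(`+`, stateCenters) / K
  centers <- lapply(stateCenters, function(cmat) grand + overlapFactor * (cmat - grand))
  total <- sum(framesPerState)
  arr <- array(0, c(total, n, 3L))
  labels <- integer(total)
  withSeed(seed, {
    withinModes <- max(1L, as.integer(withinModes))
    M <- qr.Q(qr(matrix(stats::rnorm(3L * n * withinModes), 3L * n)))[,
           seq_len(withinModes), drop = FALSE]
    amps <- withinStateSd * seq(1, 0.6, length.out = withinModes)
    jitterSd <- jitterFraction * withinStateSd
    f <- 0L
    for (k in seq_len(K)) {
      for (j in seq_len(framesPerState[k])) {
        f <- f + 1L
        disp <- as.numeric(M %*% (amps * stats::rnorm(withinModes)))
        crd <- centers[[k]] + unflattenFrame(disp)
        if (jitterSd > 0)
          crd <- crd + matrix(stats::rnorm(3L * n, sd = jitterSd), n, 3L)
        arr[f, , ] <- crd
        labels[f] <- k
      }
    }
  })
  list(ensemble = newEnsemble(topology, arr, condition = condition,
                              temperature = temperature),
       labels = labels)
}

# Place acceptor atom so the D-H-A geometry has the given donor-acceptor
# distance and deviation from linearity (degrees).
placeAcceptor <- function(D, H, distance, deviation) {
  u <- H - D; dh <- sqrt(sum(u^2)); u <- u / dh
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- c(u[2] * ref[3] - u[3] * ref[2],
         u[3] * ref[1] - u[1] * ref[3],
         u[1] * ref[2] - u[2] * ref[1])
  p <- p / sqrt(sum(p^2))
  dl <- deviation * pi / 180
  disc <- distance^2 - dh^2 * sin(dl)^2
  if (disc < 0) stop("acceptor distance too short for the requested deviation")
  r <- -dh * cos(dl) + sqrt(disc)
  H + r * (cos(dl) * u + sin(dl) * p)
}

#' Generate a two-condition hydrogen-bond scenario
#'
#' Plants donor-hydrogen-acceptor triads whose geometric hydrogen bond is
#' independently "on" in each frame with a per-condition occupancy (e.g. a
#' bond at 0.8 occupancy at 30 degC and 0.1 at 20 degC emulates a
#' temperature-switched interaction). When on, the acceptor is placed at the
#' bound geometry (satisfying the detection cutoffs); when off, at the
#' unbound geometry (violating at least one cutoff). All other atoms stay at
#' the reference coordinates.
#'
#' @param topology a [Topology] containing the triad atoms.
#' @param coordsRef `N x 3` reference coordinates.
#' @param triads `data.frame` with columns `donor`, `hydrogen`, `acceptor`
#'   (atom indices); acceptor atoms must be distinct across triads.
#' @param occupancy `nTriads x 2` matrix of planted occupancies in `[0, 1]`,
#'   columns named by condition.
#' @param nFramesPerCondition frames to draw per condition.
#' @param boundGeometry list `(distance, deviation)` used when on; must
#'   satisfy the cutoffs.
#' @param unboundGeometry list `(distance, deviation)` used when off; must
#'   violate at least one cutoff.
#' @param temperatures numeric length 2, degrees Celsius.
#' @param distanceCutoff,angleCutoff the detection cutoffs the plan is phrased
#'   against (3.0 Angstrom, 20 degrees).
#' @param seed RNG seed.
#' @return list with `ensembles` (named list of two [TrajectoryEnsemble]s),
#'   `occupancy` (the planted matrix — the truth), and `realized` (empirical
#'   on-fractions actually drawn, per condition).
#' @export
generateHbondScenario <- function(topology, coordsRef, triads, occupancy,
                                  nFramesPerCondition = 200L,
                                  boundGeometry = list(distance = 2.8, deviation = 5),
                                  unboundGeometry = list(distance = 4.5, deviation = 0),
                                  temperatures = c(20, 30),
                                  distanceCutoff = 3.0, angleCutoff = 20,
                                  seed = 1L) {
  stopifnot(nrow(occupancy) == nrow(triads), ncol(occupancy) == 2L)
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancies must be in [0,1]")
  if (!(boundGeometry$distance <= distanceCutoff &&
        boundGeometry$deviation <= angleCutoff))
    stop("bound geometry must satisfy the detection cutoffs")
  if (unboundGeometry$distance <= distanceCutoff &&
      unboundGeometry$deviation <= angleCutoff)
    stop("unbound geometry must violate at least one cutoff")
  if (anyDuplicated(triads$acceptor))
    stop("each acceptor atom may serve only one planted triad")
  conds <- colnames(occupancy)
  if (is.null(conds)) conds <- paste0(temperatures, "C")
  n <- nAtoms(topology)
  out <- withSeed(seed, {
    ens <- list(); realized <- list()
    for (ci in 1:2) {
      arr <- array(0, c(nFramesPerCondition, n, 3L))
      on <- matrix(FALSE, nFramesPerCondition, nrow(triads))
      for (f in seq_len(nFramesPerCondition)) {
        crd <- coordsRef
        for (ti in seq_len(nrow(triads))) {
          isOn <- stats::runif(1) < occupancy[ti, ci]
          on[f, ti] <- isOn
          g <- if (isOn) boundGeometry else unboundGeometry
          crd[triads$acceptor[ti], ] <- placeAcceptor(
            coordsRef[triads$donor[ti], ], coordsRef[triads$hydrogen[ti], ],
            g$distance, g$deviation)
        }
        arr[f, , ] <- crd
      }
      ens[[conds[ci]]] <- newEnsemble(topology, arr, condition = conds[ci],
                                      temperature = temperatures[ci])
      realized[[conds[ci]]] <- colMeans(on)
    }
    list(ens = ens, realized = realized)
  })
  list(ensembles = out$ens, occupancy = occupancy, realized = out$realized)
}

#' Generate a trajectory with planted residue-substrate coupling
#'
#' A single latent series drives both reaction-geometry descriptors (the
#' Fe-Cbeta distance and the Calpha-Cbeta-Fe angle) and, attenuated by the
#' coupling strength `rho`, the displacement magnitude of one protein
#' residue's Calpha. Frames come in +/- pairs about the residue's reference
#' position, so the ensemble-mean position is exact and the per-frame
#' displacement magnitude is exactly linear in the latent: the asymptotic
#' Pearson correlation between the residue's displacement and the combined
#' z-score is `rho` by construction (exactly 1 at `rho = 1` with zero noise).
#'
#' @param topology a [Topology] with HEM (FE atom) and PLM (CA, CB) groups.
#' @param coordsRef `N x 3` reference coordinates.
#' @param coupledResidue protein residue id whose Calpha carries the planted
#'   coupling.
#' @param rho planted coupling strength in `[-1, 1]`.
#' @param nFrames even number of frames.
#' @param baseDistance,distanceSd mean and spread of the Fe-Cbeta distance
#'   (Angstrom).
#' @param baseAngle,angleSd mean and spread of the Calpha-Cbeta-Fe angle
#'   (degrees).
#' @param dispScale scale of the coupled residue's displacement (Angstrom).
#' @param jitterSd isotropic jitter on all other protein atoms (0 for exact
#'   recovery checks).
#' @param seed RNG seed.
#' @return list with `ensemble`, `z` (the true combined z-score series),
#'   `geometry` (`data.frame` of the planted distance/angle series),
#'   `coupledResidue` and `rho`.
#' @export
generateCoupledSubstrateTrajectory <- function(topology, coordsRef,
                                               coupledResidue, rho, nFrames,
                                               baseDistance = 4.5,
                                               distanceSd = 0.5,
                                               baseAngle = 110, angleSd = 8,
                                               dispScale = 0.5,
                                               jitterSd = 0.05, seed = 1L) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (nFrames %% 2L != 0L) stop("nFrames must be even (frames come in pairs)")
  at <- atoms(topology)
  fe <- which(at$resname == "HEM" & at$name == "FE")
  cb <- which(at$resname == "PLM" & at$name == "CB")
  caS <- which(at$resname == "PLM" & at$name == "CA")
  if (length(fe) != 1L || length(cb) != 1L || length(caS) != 1L)
    stop("topology must contain FE (HEM) and CA/CB (PLM) atoms")
  caR <- which(!at$hetero & at$resid == coupledResidue & at$name == "CA")
  if (length(caR) != 1L)
    stop(sprintf("no Calpha for coupled residue %d", coupledResidue))
  nP <- nFrames / 2L
  n <- nAtoms(topology)
  feP <- coordsRef[fe, ]
  e <- coordsRef[cb, ] - feP; e <- e / sqrt(sum(e^2))
  refv <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- c(e[2] * refv[3] - e[3] * refv[2],
         e[3] * refv[1] - e[1] * refv[3],
         e[1] * refv[2] - e[2] * refv[1])
  p <- p / sqrt(sum(p^2))
  out <- withSeed(seed, {
    w <- pmax(pmin(stats::rnorm(nP), 4), -4)
    eps <- stats::rnorm(nP)
    jit <- if (jitterSd > 0)
      array(stats::rnorm(nFrames * n * 3L, sd = jitterSd), c(nFrames, n, 3L))
    else NULL
    list(w = w, eps = eps, jit = jit)
  })
  wF <- rep(out$w, each = 2L)
  d <- baseDistance + distanceSd * wF
  a <- baseAngle + angleSd * wF
  m <- dispScale * (rho * out$w + sqrt(1 - rho^2) * out$eps)
  m0 <- 5 * dispScale + max(0, -min(m))     # keep displacement positive
  arr <- array(0, c(nFrames, n, 3L))
  protein <- which(!at$hetero)
  for (f in seq_len(nFrames)) {
    crd <- coordsRef
    if (!is.null(out$jit)) {
      others <- setdiff(protein, caR)
      crd[others, ] <- crd[others, ] + out$jit[f, others, ]
    }
    pair <- (f + 1L) %/% 2L
    sgn <- if (f %% 2L == 1L) 1 else -1
    crd[caR, 1] <- coordsRef[caR, 1] + sgn * (m0 + m[pair])
    crd[cb, ] <- feP + d[f] * e
    ang <- a[f] * pi / 180
    crd[caS, ] <- crd[cb, ] + 1.5 * (cos(ang) * (-e) + sin(ang) * p)
    arr[f, , ] <- crd
  }
  zd <- (d - mean(d)) / stats::sd(d)
  za <- (a - mean(a)) / stats::sd(a)
  list(ensemble = newEnsemble(topology, arr),
       z = (zd + za) / 2,
       geometry = data.frame(distance = d, angle = a),
       coupledResidue = coupledResidue, rho = rho)
}

# Curve models shared by the generator and the fitters.

#' Spectroscopic curve models
#'
#' `morrisonDeltaA()` is the tight-binding (Morrison quadratic) titration
#' model: `dAmax * ((E + S + Kd) - sqrt((E + S + Kd)^2 - 4 E S)) / (2 E)`.
#' `boltzmannSignal()` is the sigmoidal melt:
#' `lower + (upper - lower) / (1 + exp((Tm - T)/slope))`.
#' `doubleExponential()` is the stopped-flow decay:
#' `offset + A1 exp(-k1 t) + A2 exp(-k2 t)`.
#'
#' @param S substrate concentration (uM).
#' @param Kd dissociation constant (uM).
#' @param dAmax maximal absorbance change.
#' @param E enzyme concentration (uM).
#' @param temp temperature (degC).
#' @param Tm melting temperature (degC).
#' @param slope transition width parameter (degC).
#' @param lower,upper pre-/post-transition baselines.
#' @param t time (s).
#' @param A1,A2 phase amplitudes.
#' @param k1,k2 rate constants (1/s).
#' @param offset baseline absorbance.
#' @return numeric vector of model values.
#' @name curve-models
NULL

#' @rdname curve-models
#' @export
morrisonDeltaA <- function(S, Kd, dAmax, E) {
  dAmax * ((E + S + Kd) - sqrt((E + S + Kd)^2 - 4 * E * S)) / (2 * E)
}

#' @rdname curve-models
#' @export
boltzmannSignal <- function(temp, Tm, slope, lower, upper) {
  lower + (upper - lower) / (1 + exp((Tm - temp) / slope))
}

#' @rdname curve-models
#' @export
doubleExponential <- function(t, A1, k1, A2, k2, offset) {
  offset + A1 * exp(-k1 * t) + A2 * exp(-k2 * t)
}

#' Generate synthetic spectroscopy datasets
#'
#' Noiseless curves from the named model plus Gaussian noise, with the
#' generating parameters returned as the truth record. Kinds: `"titration"`
#' (Morrison tight-binding, params `Kd`, `dAmax`, `E`), `"melting"`
#' (Boltzmann sigmoid, params `Tm`, `slope`, `lower`, `upper`) and
#' `"kinetics"` (two-summed exponentials, params `A1`, `k1`, `A2`, `k2`,
#' `offset`).
#'
#' @param kind one of `"titration"`, `"melting"`, `"kinetics"`.
#' @param params named list of generating parameters (see above).
#' @param design numeric vector of design points: substrate concentrations
#'   (uM), scan temperatures (degC) or times (s).
#' @param noiseSd Gaussian noise sd on the response.
#' @param seed RNG seed.
#' @return list with `kind`, `data` (two-column `data.frame`) and `truth`
#'   (the generating parameters).
#' @export
generateSpectroDataset <- function(kind = c("titration", "melting", "kinetics"),
                                   params, design, noiseSd = 0, seed = 1L) {
  kind <- match.arg(kind)
  y <- switch(kind,
    titration = {
      stopifnot(params$Kd > 0, params$E > 0)
      if (is.unsorted(design, strictly = TRUE) || any(design < 0))
        stop("titration design must be nonnegative and strictly increasing")
      morrisonDeltaA(design, params$Kd, params$dAmax, params$E)
    },
    melting = {
      if (params$Tm < min(design) || params$Tm > max(design))
        stop("Tm must lie inside the scanned temperature range")
      boltzmannSignal(design, params$Tm, params$slope, params$lower, params$upper)
    },
    kinetics = {
      stopifnot(params$k1 > 0, params$k2 > 0)
      doubleExponential(design, params$A1, params$k1, params$A2, params$k2,
                        params$offset)
    })
  if (noiseSd > 0)
    y <- y + withSeed(seed, stats::rnorm(length(y), sd = noiseSd))
  nm <- switch(kind, titration = c("S", "dA"),
               melting = c("temperature", "signal"),
               kinetics = c("time", "absorbance"))
  d <- data.frame(design, y)
  names(d) <- nm
  list(kind = kind, data = d, truth = params)
}
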