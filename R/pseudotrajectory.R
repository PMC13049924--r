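# Nearest-neighbour ordering of medoids, RMSD-scaled linear morph
# interpolation into a pseudotrajectory, and Calpha RMSF profiles.

#' Nearest-neighbour traversal of a medoid RMSD matrix
#'
#' Greedy path through the medoids: from the current medoid the next one is
#' the unvisited medoid at smallest RMSD (ties to the lowest index). Every
#' medoid is visited exactly once.
#'
#' @param rmsdMatrix symmetric medoid RMSD matrix.
#' @param start index of the starting medoid; by convention the medoid of the
#'   most-populated cluster (see [traversalStart()]).
#' @return integer vector: visited medoid sequence.
#' @export
nearestNeighborOrder <- function(rmsdMatrix, start = 1L) {
  rmsdMatrix <- as.matrix(rmsdMatrix)
  if (nrow(rmsdMatrix) != ncol(rmsdMatrix) ||
      max(abs(rmsdMatrix - t(rmsdMatrix))) > 1e-9)
    stop("RMSD matrix must be symmetric")
  m <- nrow(rmsdMatrix)
  stopifnot(start >= 1L, start <= m)
  visited <- logical(m)
  path <- integer(m)
  cur <- as.integer(start)
  for (i in seq_len(m)) {
    path[i] <- cur
    visited[cur] <- TRUE
    if (i == m) break
    d <- rmsdMatrix[cur, ]
    d[visited] <- Inf
    cur <- which.min(d)             # which.min: lowest index on ties
  }
  path
}

#' Traversal start medoid
#'
#' The start rule of the pipeline: the medoid of the most-populated cluster;
#' ties break to the lowest cluster id.
#'
#' @param labels per-frame cluster labels (0 = noise).
#' @param medoids named medoid vector as returned by [findClusterMedoids()].
#' @return integer position of the start medoid within `medoids`.
#' @export
traversalStart <- function(labels, medoids) {
  ids <- as.integer(names(medoids))
  sizes <- vapply(ids, function(k) sum(labels == k), integer(1))
  which.max(sizes)                  # first max = lowest cluster id on ties
}

#' Build an interpolated pseudotrajectory from ordered medoids
#'
#' Walks the medoids in traversal order, superposing each successive medoid
#' onto its predecessor (drift reduction), and inserts
#' `m = max(minFrames, ceiling(framesPerAngstrom * d))` linearly interpolated
#' frames between consecutive medoids at RMSD `d` (at fractions
#' `1/(m+1) ... m/(m+1)`; `m = 0` when `d = 0`). The result is a geometric
#' morph path through the conformational states, used for RMSF and
#' hydrogen-bond occupancy analysis.
#'
#' @param ensemble the [TrajectoryEnsemble] holding the medoid frames.
#' @param medoidIdx integer frame indices of the medoids (in cluster-id
#'   order, as from [findClusterMedoids()]).
#' @param ordering visited sequence from [nearestNeighborOrder()] (positions
#'   into `medoidIdx`).
#' @param framesPerAngstrom interpolated frames per Angstrom of RMSD
#'   (default 10).
#' @param minFrames minimum interpolated frames between distinct medoids
#'   (default 1; pairs at RMSD 0 get none).
#' @param fitSpec [SelectionSpec] used both for the drift-reduction
#'   superposition and for the RMSD that scales the frame count.
#' @return a [Pseudotrajectory].
#' @export
buildPseudotrajectory <- function(ensemble, medoidIdx, ordering,
                                  framesPerAngstrom = 10, minFrames = 1L,
                                  fitSpec = selectionSpec(backboneOnly = TRUE,
                                                          excludeHydrogens = TRUE)) {
  if (length(ordering) == 0L) stop("empty medoid ordering")
  if (framesPerAngstrom <= 0) stop("framesPerAngstrom must be positive")
  idx <- selectAtoms(topology(ensemble), fitSpec)
  med <- lapply(medoidIdx[ordering], function(f) frameCoords(ensemble, f))
  # drift reduction: superpose each medoid onto its (already aligned)
  # predecessor
  for (i in seq_along(med)[-1])
    med[[i]] <- kabschSuperpose(med[[i]], med[[i - 1L]], idx)$coords
  frames <- list(); prov <- list()
  addFrame <- function(crd, type, from, to, frac) {
    frames[[length(frames) + 1L]] <<- crd
    prov[[length(prov) + 1L]] <<- data.frame(
      frame = length(frames), type = type, fromMedoid = from, toMedoid = to,
      fraction = frac)
  }
  addFrame(med[[1]], "medoid", 1L, 1L, NA_real_)
  for (i in seq_along(med)[-1]) {
    A <- med[[i - 1L]]; B <- med[[i]]
    dev <- A[idx, ] - B[idx, ]
    d <- sqrt(mean(rowSums(dev^2)))
    if (d < 1e-9) d <- 0                 # numerically identical medoids
    m <- if (d == 0) 0L else max(as.integer(minFrames),
                                 as.integer(ceiling(framesPerAngstrom * d)))
    if (m > 0L) for (j in seq_len(m)) {
      t <- j / (m + 1)
      addFrame((1 - t) * A + t * B, "interp", i - 1L, i, t)
    }
    addFrame(B, "medoid", i, i, NA_real_)
  }
  arr <- array(0, c(length(frames), nAtoms(ensemble), 3L))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  new("Pseudotrajectory", topology = topology(ensemble), coords = arr,
      provenance = do.call(rbind, prov), ordering = as.integer(ordering))
}

#' Per-residue Calpha root mean square fluctuation
#'
#' RMSF of each protein residue's Calpha about its mean position, after
#' removing global motion by iteratively superposing all frames onto the mean
#' structure (two passes, backbone heavy-atom fit). Residues without a Calpha
#' are excluded with a warning.
#'
#' @param x a [Pseudotrajectory] or [TrajectoryEnsemble] with >= 2 frames.
#' @param fitSpec [SelectionSpec] for the superposition fit.
#' @return `data.frame` with columns `chain`, `resid`, `resname`, `rmsf`
#'   (Angstrom).
#' @export
rmsfCalpha <- function(x, fitSpec = selectionSpec(backboneOnly = TRUE,
                                                  excludeHydrogens = TRUE)) {
  topo <- topology(x)
  arr <- coords(x)
  nF <- dim(arr)[1]
  if (nF < 2L) stop("RMSF needs at least 2 frames")
  fitIdx <- selectAtoms(topo, fitSpec)
  for (pass in 1:2) {
    ref <- apply(arr, c(2, 3), mean)
    for (f in seq_len(nF)) {
      m <- arr[f, , ]; dim(m) <- dim(arr)[2:3]
      arr[f, , ] <- kabschSuperpose(m, ref, fitIdx)$coords
    }
  }
  at <- atoms(topo)
  protRes <- unique(paste(at$chain, at$resid, at$insert, sep = "|")[!at$hetero])
  ca <- which(!at$hetero & at$name == "CA")
  caKey <- paste(at$chain, at$resid, at$insert, sep = "|")[ca]
  missing <- setdiff(protRes, caKey)
  if (length(missing))
    warning(sprintf("%d residue(s) without a Calpha excluded from RMSF",
                    length(missing)))
  mu <- apply(arr, c(2, 3), mean)
  rmsf <- vapply(ca, function(a) {
    dev <- sweep(arr[, a, , drop = TRUE], 2, mu[a, ])
    sqrt(mean(rowSums(dev^2)))
  }, numeric(1))
  data.frame(chain = at$chain[ca], resid = at$resid[ca],
             resname = at$resname[ca], rmsf = rmsf)
}
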