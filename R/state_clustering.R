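# Density-based conformational-state clustering in reduced PC space
# (HDBSCAN, Manhattan metric, leaf cluster selection), medoid identification
# and the medoid-to-medoid RMSD matrix.
#
# HDBSCAN here follows the standard construction: per-point core distances
# from the minSamples-th nearest neighbour, mutual-reachability distances,
# a single-linkage hierarchy on them, condensation of the hierarchy at
# minClusterSize, and selection of the condensed tree's leaves as the final
# clusters (the "leaf" selection method). Points never absorbed into a
# selected leaf are noise (label 0).

hdbscanLeaf <- function(X, minClusterSize, minSamples) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X, method = "manhattan"))
  # core distance: distance to the minSamples-th nearest point, self included
  core <- apply(D, 1L, function(r) sort(r)[min(minSamples, n)])
  MR <- pmax(D, outer(core, core, pmax))
  diag(MR) <- 0
  hc <- stats::hclust(stats::as.dist(MR), method = "single")

  merge <- hc$merge; height <- hc$height
  nodeMembers <- vector("list", nrow(merge))
  members <- function(id) if (id < 0L) -id else nodeMembers[[id]]
  for (i in seq_len(nrow(merge)))
    nodeMembers[[i]] <- c(members(merge[i, 1]), members(merge[i, 2]))

  labels <- integer(n)
  nextLabel <- 0L
  eps <- 1e-12

  # Descend from a condensed-cluster birth node; returns TRUE if the cluster
  # produced selected descendants (i.e. it split into two valid children),
  # FALSE if it terminated as a leaf (in which case it has been labelled).
  condense <- function(node, isRoot = FALSE) {
    birthMembers <- members(node)
    cur <- node
    sawPositiveSplit <- FALSE
    repeat {
      if (cur < 0L) {               # single point left: cluster dies
        break
      }
      h <- height[cur]
      left <- merge[cur, 1]; right <- merge[cur, 2]
      sl <- length(members(left)); sr <- length(members(right))
      if (h <= eps) break           # no further separation: cluster is a leaf
      sawPositiveSplit <- TRUE
      lOK <- sl >= minClusterSize; rOK <- sr >= minClusterSize
      if (lOK && rOK) {             # true split: two child condensed clusters
        condense(left)
        condense(right)
        return(TRUE)
      } else if (lOK) {
        cur <- left                 # shed the small side, continue
      } else if (rOK) {
        cur <- right
      } else {
        break                       # both below size: cluster dies -> leaf
      }
    }
    # leaf condensed cluster: label every point present at its birth,
    # except the root, which is only selectable if it never really split
    if (isRoot && sawPositiveSplit) return(FALSE)
    nextLabel <<- nextLabel + 1L
    labels[birthMembers] <<- nextLabel
    FALSE
  }

  root <- nrow(merge)
  if (root == 0L) {                 # n == 1
    labels[] <- 1L
  } else {
    condense(root, isRoot = TRUE)
  }
  # renumber clusters by first-frame order for determinism
  seen <- unique(labels[labels > 0L])
  if (length(seen)) {
    remap <- integer(max(seen)); remap[seen] <- seq_along(seen)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  labels
}

#' Cluster frames in reduced PC space
#'
#' Hierarchical density-based clustering (the HDBSCAN algorithm) of PC-space
#' frame coordinates with the Manhattan (L1) metric and leaf cluster
#' selection. Noise frames get label 0. Deterministic for fixed input.
#'
#' @param pcTable `F x K` matrix of PC scores (from [projectFrames()]).
#' @param nComponents number of leading PC columns to use; default
#'   `min(20, ncol(pcTable))`.
#' @param minClusterSize smallest cluster size; default
#'   `max(5, ceiling(0.10 F))`. Leaf selection reports the finest
#'   density-stable structure, so the size floor must be an appreciable
#'   fraction of a real state's population: a 1% floor shatters compact
#'   states into density fluctuations (the reference implementation behaves
#'   identically), while a 10% floor sits well inside the stable regime. A
#'   conformational state holding under a tenth of the frames is treated as
#'   unresolved at this sampling depth.
#' @param minSamples neighbourhood size for core distances; default
#'   `minClusterSize`.
#' @return integer vector of per-frame cluster labels (0 = noise).
#' @export
clusterPCSpace <- function(pcTable,
                           nComponents = min(20L, ncol(pcTable)),
                           minClusterSize = max(5L, ceiling(0.10 * nrow(pcTable))),
                           minSamples = minClusterSize) {
  pcTable <- as.matrix(pcTable)
  if (ncol(pcTable) == 0L) stop("PC table has no components")
  if (nrow(pcTable) < minClusterSize)
    stop("fewer frames than minClusterSize")
  X <- pcTable[, seq_len(min(nComponents, ncol(pcTable))), drop = FALSE]
  hdbscanLeaf(X, as.integer(minClusterSize), as.integer(minSamples))
}

#' Find the medoid frame of each cluster
#'
#' Per cluster, the member frame minimizing the mean pairwise RMSD (after
#' optimal superposition over the RMSD selection) to all other members. Ties
#' break to the lowest frame index.
#'
#' @param ensemble the [TrajectoryEnsemble] the labels refer to.
#' @param labels integer per-frame cluster labels (0 = noise, ignored).
#' @param rmsdSpec [SelectionSpec] for the structural RMSD; default backbone
#'   heavy atoms.
#' @return named integer vector: medoid frame index per cluster id.
#' @export
findClusterMedoids <- function(ensemble, labels,
                               rmsdSpec = selectionSpec(backboneOnly = TRUE,
                                                        excludeHydrogens = TRUE)) {
  idx <- selectAtoms(topology(ensemble), rmsdSpec)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) stop("no non-noise clusters in labels")
  out <- integer(length(ids)); names(out) <- ids
  for (k in seq_along(ids)) {
    fr <- which(labels == ids[k])
    if (length(fr) == 1L) { out[k] <- fr; next }
    crd <- lapply(fr, function(f) frameCoords(ensemble, f))
    m <- length(fr)
    S <- matrix(0, m, m)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      r <- superposedRmsd(crd[[i]], crd[[j]], idx)
      S[i, j] <- r; S[j, i] <- r
    }
    meanR <- rowSums(S) / (m - 1L)
    out[k] <- fr[which.min(meanR)]   # which.min: first (lowest frame) on ties
  }
  out
}

#' Medoid-to-medoid RMSD matrix
#'
#' Symmetric matrix of minimal-superposition RMSDs between medoid frames over
#' the structural selection (canonically: protein backbone of the analysis
#' residue range, plus heme and substrate, hydrogens excluded).
#'
#' @param ensemble the [TrajectoryEnsemble].
#' @param medoidIdx integer frame indices of the medoids (>= 2).
#' @param rmsdSpec [SelectionSpec] for the RMSD atoms.
#' @param superpose superpose each pair before the RMSD (default `TRUE`;
#'   un-fitted RMSD would depend on arbitrary frame placement).
#' @return symmetric numeric matrix (Angstrom) with zero diagonal.
#' @export
medoidRmsdMatrix <- function(ensemble, medoidIdx,
                             rmsdSpec = selectionSpec(
                               residueRange = c(11L, 412L),
                               backboneOnly = TRUE,
                               includeResidueNames = c("HEM", "PLM"),
                               excludeHydrogens = TRUE),
                             superpose = TRUE) {
  if (length(medoidIdx) < 2L) stop("at least 2 medoids are required")
  idx <- selectAtoms(topology(ensemble), rmsdSpec)
  m <- length(medoidIdx)
  crd <- lapply(medoidIdx, function(f) frameCoords(ensemble, f))
  M <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    r <- if (superpose) superposedRmsd(crd[[i]], crd[[j]], idx)
    else {
      dev <- crd[[i]][idx, ] - crd[[j]][idx, ]
      sqrt(mean(rowSums(dev^2)))
    }
    M[i, j] <- r; M[j, i] <- r
  }
  dimnames(M) <- list(names(medoidIdx), names(medoidIdx))
  M
}

#' Full conformational-state decomposition of an ensemble
#'
#' Convenience wrapper running [clusterPCSpace()], [findClusterMedoids()] and
#' [medoidRmsdMatrix()] into a single [StateDecomposition].
#'
#' @param ensemble an aligned [TrajectoryEnsemble].
#' @param pcTable `F x K` PC score matrix for the same frames.
#' @param rmsdSpec structural selection for medoids and the RMSD matrix.
#' @param ... passed to [clusterPCSpace()].
#' @return a [StateDecomposition].
#' @export
stateDecomposition <- function(ensemble, pcTable,
                               rmsdSpec = selectionSpec(backboneOnly = TRUE,
                                                        excludeHydrogens = TRUE),
                               ...) {
  labels <- clusterPCSpace(pcTable, ...)
  med <- findClusterMedoids(ensemble, labels, rmsdSpec)
  M <- if (length(med) >= 2L) medoidRmsdMatrix(ensemble, med, rmsdSpec)
  else matrix(0, length(med), length(med),
              dimnames = list(names(med), names(med)))
  new("StateDecomposition", labels = labels, medoidFrames = med,
      medoidRmsd = M)
}
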