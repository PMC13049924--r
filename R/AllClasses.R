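#' @import methods
NULL

#' Topology of a molecular system
#'
#' Ordered atom table for a structure: one row per atom with PDB-style
#' identity fields. Coordinates live in the companion frame matrices or in a
#' [TrajectoryEnsemble]; a `Topology` carries only identity, so one topology
#' can be shared by many frames.
#'
#' @slot atoms `data.frame` with one row per atom and columns `serial`
#'   (integer), `name` (atom name), `elem` (element symbol), `resname`
#'   (3-letter residue code), `resid` (integer residue number, file
#'   numbering), `chain` (single character), `insert` (insertion code, `""`
#'   when absent), `hetero` (logical, `TRUE` for HETATM records).
#'
#' @details Atom identity `(chain, resid, insert, name)` must be unique after
#' alternate-location resolution, and every element field must be non-empty
#' (the reader fills blank elements from the atom name).
#'
#' @seealso [readStructure()], [selectAtoms()], [TrajectoryEnsemble]
#' @export
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  at <- object@atoms
  need <- c("serial", "name", "elem", "resname", "resid", "chain", "insert", "hetero")
  if (!all(need %in% names(at)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(at) == 0L) return("topology must contain at least one atom")
  if (any(is.na(at$elem)) || any(!nzchar(at$elem)))
    return("element field must be non-empty for every atom")
  key <- paste(at$chain, at$resid, at$insert, at$name, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate atom identity (chain, resid, insert, name) in topology")
  TRUE
})

#' Trajectory ensemble
#'
#' A set of coordinate frames over a shared [Topology], labelled with the
#' experimental condition (typically a temperature) and per-frame replicate
#' provenance. This is the substrate of every dynamics stage: alignment, PCA,
#' clustering, pseudotrajectory building, hydrogen-bond analysis and
#' substrate-coupling profiles all consume a `TrajectoryEnsemble`.
#'
#' @slot topology a [Topology].
#' @slot coords numeric array `F x N x 3` (frames, atoms, xyz) in Angstrom.
#' @slot condition character condition label (e.g. `"20C"`).
#' @slot temperature numeric temperature in degrees Celsius (`NA` if unknown).
#' @slot replicateIds integer vector of length `F`: which input replicate each
#'   frame came from.
#' @slot frameConditions character vector of length `F`: per-frame condition
#'   label. Equal to `condition` for a single-condition ensemble; preserved per
#'   frame block by [concatenateEnsembles()] when pooling conditions.
#'
#' @seealso [readTrajectory()], [concatenateEnsembles()], [alignEnsemble()]
#' @export
setClass("TrajectoryEnsemble", representation(
  topology = "Topology",
  coords = "array",
  condition = "character",
  temperature = "numeric",
  replicateIds = "integer",
  frameConditions = "character"
))

setValidity("TrajectoryEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be an F x N x 3 array")
  if (d[1] < 1L) return("ensemble must contain at least one frame")
  if (d[2] != nrow(object@topology@atoms))
    return(sprintf("frame atom count (%d) != topology atom count (%d)",
                   d[2], nrow(object@topology@atoms)))
  if (any(!is.finite(object@coords)))
    return("coordinates must be finite")
  if (length(object@replicateIds) != d[1])
    return("replicateIds must have one entry per frame")
  if (length(object@condition) != 1L)
    return("condition must be a single label")
  if (length(object@frameConditions) != d[1])
    return("frameConditions must have one entry per frame")
  TRUE
})

#' Atom selection specification
#'
#' Declarative atom selection resolved against a [Topology] by
#' [selectAtoms()]. Criteria combine as: protein (non-hetero) atoms passing
#' all of `residueRange`, `backboneOnly` and `atomNames` (when any of those is
#' set; otherwise all atoms), plus every atom of residues named in
#' `includeResidueNames` (e.g. `"HEM"`, `"PLM"`), minus hydrogens when
#' `excludeHydrogens`. The canonical analysis selection of the pipeline —
#' protein backbone of a residue range plus heme plus substrate, hydrogens
#' excluded — is expressed this way.
#'
#' @slot residueRange integer of length 0 or 2: inclusive residue-id interval.
#' @slot backboneOnly logical: restrict protein atoms to names N, CA, C, O.
#' @slot includeResidueNames character: residue names pulled in whole.
#' @slot atomNames character: protein atom names to keep (empty = all).
#' @slot excludeHydrogens logical: drop hydrogen atoms from the result.
#'
#' @seealso [selectionSpec()], [selectAtoms()]
#' @export
setClass("SelectionSpec", representation(
  residueRange = "integer",
  backboneOnly = "logical",
  includeResidueNames = "character",
  atomNames = "character",
  excludeHydrogens = "logical"
))

setValidity("SelectionSpec", function(object) {
  if (!length(object@residueRange) %in% c(0L, 2L))
    return("residueRange must be empty or an inclusive (lo, hi) pair")
  if (length(object@residueRange) == 2L &&
      object@residueRange[1] > object@residueRange[2])
    return("residueRange lower bound exceeds upper bound")
  any.set <- length(object@residueRange) == 2L || isTRUE(object@backboneOnly) ||
    length(object@includeResidueNames) > 0L || length(object@atomNames) > 0L ||
    isTRUE(object@excludeHydrogens)
  if (!any.set) return("at least one selection criterion must be set")
  TRUE
})

#' Principal component model of an aligned ensemble
#'
#' Eigendecomposition of the sample covariance of flattened analysis-selection
#' coordinates, with the number of components needed to reach a cumulative
#' variance target. Eigenvalues are in Angstrom^2; loading vectors are
#' orthonormal 3M-vectors over the M selected atoms.
#'
#' @slot mean numeric 3M-vector: mean structure over the analysis selection
#'   (x1, y1, z1, x2, ...).
#' @slot eigenvalues numeric, nonincreasing, Angstrom^2.
#' @slot loadings numeric 3M x C matrix, orthonormal columns.
#' @slot cumulativeVariance numeric in (0, 1], nondecreasing.
#' @slot retained integer: smallest K with cumulative variance >= the target
#'   (0 when total variance is zero).
#' @slot varianceTarget numeric: the cumulative-variance target used.
#' @slot atomIndices integer: topology indices of the analysis selection.
#'
#' @seealso [pcaHeavyAtoms()], [projectFrames()], [essentialDynamicsScore()]
#' @export
setClass("PCAModel", representation(
  mean = "numeric",
  eigenvalues = "numeric",
  loadings = "matrix",
  cumulativeVariance = "numeric",
  retained = "integer",
  varianceTarget = "numeric",
  atomIndices = "integer"
))

setValidity("PCAModel", function(object) {
  if (any(object@eigenvalues < -1e-10))
    return("eigenvalues must be nonnegative")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE) &&
      any(diff(object@eigenvalues) > 1e-10))
    return("eigenvalues must be nonincreasing")
  if (length(object@mean) != nrow(object@loadings))
    return("mean length must equal loading-vector dimension")
  if (length(object@mean) != 3L * length(object@atomIndices))
    return("mean length must be 3 x number of selected atoms")
  TRUE
})

#' Conformational state decomposition
#'
#' Result of density-based clustering of frames in reduced PC space: per-frame
#' state labels (0 = noise), one medoid frame per state, and the symmetric
#' medoid-to-medoid RMSD matrix over the structural selection used for RMSD.
#'
#' @slot labels integer per-frame cluster id; 0 is the noise sentinel.
#' @slot medoidFrames named integer: medoid frame index per cluster id.
#' @slot medoidRmsd symmetric numeric matrix (Angstrom), zero diagonal,
#'   rows/columns in cluster-id order.
#'
#' @seealso [clusterPCSpace()], [findClusterMedoids()], [medoidRmsdMatrix()]
#' @export
setClass("StateDecomposition", representation(
  labels = "integer",
  medoidFrames = "integer",
  medoidRmsd = "matrix"
))

setValidity("StateDecomposition", function(object) {
  if (any(object@labels < 0L)) return("labels must be >= 0 (0 = noise)")
  k <- length(object@medoidFrames)
  if (k > 0L) {
    lab <- object@labels[object@medoidFrames]
    if (!identical(sort(unique(object@labels[object@labels > 0L])),
                   sort(as.integer(names(object@medoidFrames)))))
      return("medoidFrames must name every non-noise cluster id")
    if (any(lab != as.integer(names(object@medoidFrames))))
      return("each medoid frame must belong to its own cluster")
  }
  m <- object@medoidRmsd
  if (length(m) > 0L) {
    if (nrow(m) != ncol(m)) return("medoidRmsd must be square")
    if (max(abs(m - t(m))) > 0) return("medoidRmsd must be symmetric")
    if (any(diag(m) != 0)) return("medoidRmsd must have a zero diagonal")
  }
  TRUE
})

#' Pseudotrajectory of interpolated conformational states
#'
#' An ordered walk through medoid structures with RMSD-scaled linear morph
#' interpolation between successive medoids. Frames are geometric constructs
#' for fluctuation and interaction analysis; they carry no physical time, so
#' downstream outputs index them as "frame index", never nanoseconds.
#'
#' @slot topology the shared [Topology].
#' @slot coords numeric `F x N x 3` array of pseudotrajectory frames.
#' @slot provenance `data.frame` with columns `frame`, `type` (`"medoid"` or
#'   `"interp"`), `fromMedoid`, `toMedoid` (positions in the visited ordering)
#'   and `fraction` (interpolation fraction in (0,1); `NA` for medoids).
#' @slot ordering integer: visited medoid sequence as indices into the medoid
#'   set that was traversed.
#'
#' @seealso [buildPseudotrajectory()], [nearestNeighborOrder()], [rmsfCalpha()]
#' @export
setClass("Pseudotrajectory", representation(
  topology = "Topology",
  coords = "array",
  provenance = "data.frame",
  ordering = "integer"
))

setValidity("Pseudotrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be an F x N x 3 array")
  if (nrow(object@provenance) != d[1])
    return("provenance must have one row per frame")
  pv <- object@provenance
  if (pv$type[1] != "medoid" || pv$type[nrow(pv)] != "medoid")
    return("first and last frames must be medoids")
  if (any(duplicated(object@ordering)))
    return("each medoid must appear exactly once in the ordering")
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "Topology", function(object) {
  at <- object@atoms
  cat(sprintf("Topology: %d atoms, %d residues (%d hetero atoms)\n",
              nrow(at), length(unique(paste(at$chain, at$resid, at$insert))),
              sum(at$hetero)))
  cat("  residue names:", paste(unique(at$resname), collapse = " "), "\n")
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  d <- dim(object@coords)
  cat(sprintf("TrajectoryEnsemble: %d frames x %d atoms, condition '%s' (%s degC)\n",
              d[1], d[2], object@condition,
              ifelse(is.na(object@temperature), "?", format(object@temperature))))
  cat(sprintf("  replicates: %s\n",
              paste(unique(object@replicateIds), collapse = " ")))
})

setMethod("show", "SelectionSpec", function(object) {
  parts <- character(0)
  if (length(object@residueRange) == 2L)
    parts <- c(parts, sprintf("residues %d-%d", object@residueRange[1], object@residueRange[2]))
  if (isTRUE(object@backboneOnly)) parts <- c(parts, "backbone (N,CA,C,O)")
  if (length(object@atomNames)) parts <- c(parts, paste("atoms", paste(object@atomNames, collapse = ",")))
  if (length(object@includeResidueNames))
    parts <- c(parts, paste("+", paste(object@includeResidueNames, collapse = ",")))
  if (isTRUE(object@excludeHydrogens)) parts <- c(parts, "no hydrogens")
  cat("SelectionSpec:", paste(parts, collapse = "; "), "\n")
})

setMethod("show", "PCAModel", function(object) {
  tot <- sum(object@eigenvalues)
  cat(sprintf("PCAModel: %d atoms, %d components, retained K = %d (target %.0f%%)\n",
              length(object@atomIndices), length(object@eigenvalues),
              object@retained, 100 * object@varianceTarget))
  if (tot > 0)
    cat(sprintf("  lambda_1 = %.4g A^2 (%.1f%% of variance)\n",
                object@eigenvalues[1], 100 * object@eigenvalues[1] / tot))
})

setMethod("show", "StateDecomposition", function(object) {
  cat(sprintf("StateDecomposition: %d frames, %d clusters, %d noise frames\n",
              length(object@labels), length(object@medoidFrames),
              sum(object@labels == 0L)))
})

setMethod("show", "Pseudotrajectory", function(object) {
  cat(sprintf("Pseudotrajectory: %d frames (%d medoids, %d interpolated)\n",
              dim(object@coords)[1], sum(object@provenance$type == "medoid"),
              sum(object@provenance$type == "interp")))
})

## ---- accessors -------------------------------------------------------------

#' Accessors for essdyn data objects
#'
#' Small accessor generics: `atoms()` returns the atom table of a topology (or
#' of the topology inside an ensemble/pseudotrajectory); `topology()` the
#' shared [Topology]; `coords()` the `F x N x 3` coordinate array; `nFrames()`
#' and `nAtoms()` the dimensions; `conditionLabel()` and `temperature()` the
#' condition metadata; `replicateIds()` per-frame provenance; `frameCoords()`
#' one frame as an `N x 3` matrix.
#'
#' @param x an essdyn object.
#' @param i frame index for `frameCoords`.
#' @return the slot contents described above.
#' @name accessors
#' @aliases atoms topology coords nFrames nAtoms conditionLabel temperature
#'   replicateIds frameCoords
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))
#' @rdname accessors
#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("frameConditions", function(x) standardGeneric("frameConditions"))
#' @rdname accessors
setMethod("frameConditions", "TrajectoryEnsemble", function(x) x@frameConditions)

#' @rdname accessors
setMethod("atoms", "Topology", function(x) x@atoms)
#' @rdname accessors
setMethod("atoms", "TrajectoryEnsemble", function(x) x@topology@atoms)
#' @rdname accessors
setMethod("topology", "TrajectoryEnsemble", function(x) x@topology)
#' @rdname accessors
setMethod("topology", "Pseudotrajectory", function(x) x@topology)
#' @rdname accessors
setMethod("coords", "TrajectoryEnsemble", function(x) x@coords)
#' @rdname accessors
setMethod("coords", "Pseudotrajectory", function(x) x@coords)
#' @rdname accessors
setMethod("nFrames", "TrajectoryEnsemble", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("nFrames", "Pseudotrajectory", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("nAtoms", "TrajectoryEnsemble", function(x) dim(x@coords)[2])
#' @rdname accessors
setMethod("conditionLabel", "TrajectoryEnsemble", function(x) x@condition)
#' @rdname accessors
setMethod("temperature", "TrajectoryEnsemble", function(x) x@temperature)
#' @rdname accessors
setMethod("replicateIds", "TrajectoryEnsemble", function(x) x@replicateIds)
#' @rdname accessors
setMethod("frameCoords", "TrajectoryEnsemble", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= dim(x@coords)[1])
  m <- x@coords[i, , , drop = FALSE]
  dim(m) <- dim(x@coords)[2:3]
  m
})
#' @rdname accessors
setMethod("frameCoords", "Pseudotrajectory", function(x, i) {
  m <- x@coords[i, , , drop = FALSE]
  dim(m) <- dim(x@coords)[2:3]
  m
})

#' Cluster labels, medoid frames and the medoid RMSD matrix
#'
#' @param x a [StateDecomposition].
#' @return `stateLabels()` the per-frame integer labels (0 = noise);
#'   `medoidFrames()` the named medoid frame indices; `medoidRmsd()` the
#'   symmetric medoid RMSD matrix in Angstrom.
#' @name state-accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname state-accessors
#' @export
setGeneric("medoidFrames", function(x) standardGeneric("medoidFrames"))
#' @rdname state-accessors
#' @export
setGeneric("medoidRmsd", function(x) standardGeneric("medoidRmsd"))
#' @rdname state-accessors
setMethod("stateLabels", "StateDecomposition", function(x) x@labels)
#' @rdname state-accessors
setMethod("medoidFrames", "StateDecomposition", function(x) x@medoidFrames)
#' @rdname state-accessors
setMethod("medoidRmsd", "StateDecomposition", function(x) x@medoidRmsd)
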