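# Structure and trajectory I/O over PDB text, with a declarative atom
# selection facility. Parsing is delegated to bio3d; this layer applies the
# package's altloc and element rules and builds the S4 containers.

bio3dToAtoms <- function(pdb, path) {
  at <- pdb$atom
  if (any(is.na(at$x) | is.na(at$y) | is.na(at$z))) {
    bad <- which(is.na(at$x) | is.na(at$y) | is.na(at$z))[1]
    stop(sprintf("malformed coordinate field in '%s' (record for atom serial %s)",
                 path, at$eleno[bad]))
  }
  insert <- ifelse(is.na(at$insert), "", at$insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  chain <- ifelse(is.na(at$chain), " ", at$chain)

  # altloc resolution: per resolved atom identity keep the highest-occupancy
  # record; ties go to the first encountered.
  key <- paste(chain, at$resno, insert, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  dupKeys <- unique(key[duplicated(key)])
  for (k in dupKeys) {
    idx <- which(key == k)
    best <- idx[which.max(occ[idx])]   # which.max is first-wins on ties
    keep[setdiff(idx, best)] <- FALSE
  }

  elem <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  blank <- !nzchar(elem)
  if (any(blank)) {
    nm <- toupper(sub("^[0-9]+", "", trimws(at$elety[blank])))
    elem[blank] <- substr(nm, 1L, 1L)
  }

  df <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    elem = elem,
    resname = trimws(at$resid),
    resid = as.integer(at$resno),
    chain = chain,
    insert = insert,
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  list(atoms = df[keep, , drop = FALSE], keep = which(keep))
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records of a (possibly multi-model) PDB file into a
#' [Topology] plus the first model's coordinates. Alternate locations are
#' resolved to the highest-occupancy record (ties: first encountered);
#' insertion codes are preserved in residue identity; blank element fields are
#' filled from the atom name.
#'
#' @param path path to a PDB-format text file.
#' @return list with elements `topology` (a [Topology]) and `coords`
#'   (`N x 3` numeric matrix, Angstrom) of the first model.
#' @examples
#' tf <- tempfile(fileext = ".pdb")
#' writeLines(paste0("ATOM      1  CA  GLY A   1      ",
#'                   "  1.000   2.000   3.000  1.00  0.00           C"), tf)
#' s <- readStructure(tf)
#' atoms(s$topology)
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  parsed <- bio3dToAtoms(pdb, path)
  topo <- tryCatch(new("Topology", atoms = parsed$atoms), error = function(e)
    stop(sprintf("integrity error in '%s': %s", path, conditionMessage(e))))
  xyz <- pdb$xyz[1, bio3d::atom2xyz(parsed$keep)]
  list(topology = topo, coords = unflattenFrame(xyz))
}

#' Write a structure or multi-frame trajectory as PDB
#'
#' Writes one frame as a plain PDB, or several frames as a multi-model PDB
#' (MODEL/ENDMDL blocks). Coordinates are written at the PDB's fixed precision
#' (3 decimals); `readStructure`/`readTrajectory` of the output reproduces the
#' parsed fields exactly.
#'
#' @param topology a [Topology].
#' @param coords `N x 3` matrix, or `F x N x 3` array for several frames, or a
#'   [TrajectoryEnsemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(topology, coords, path) {
  if (is(coords, "TrajectoryEnsemble")) coords <- coords(coords)
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  at <- atoms(topology)
  if (dim(coords)[2] != nrow(at))
    stop("coordinate atom count does not match topology")
  nm <- at$name
  nm4 <- ifelse(nchar(nm) < 4L, paste0(" ", nm), nm)  # PDB name column rule
  rec <- ifelse(at$hetero, "HETATM", "ATOM")
  nF <- dim(coords)[1]
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(nF)) {
    if (nF > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, at$serial, nm4, "", at$resname, at$chain, at$resid,
                     ifelse(nzchar(at$insert), at$insert, " "),
                     coords[f, , 1], coords[f, , 2], coords[f, , 3],
                     1, 0, at$elem)
    writeLines(lines, con)
    if (nF > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory ensemble from multi-model PDB files
#'
#' Reads frames from one or more multi-model PDB files over a known topology.
#' Frames keep file order; each input file becomes one replicate
#' (`replicateIds` 1, 2, ... in argument order).
#'
#' @param topology the shared [Topology] the frames must match.
#' @param paths character vector of PDB file paths (one per replicate).
#' @param condition condition label for the ensemble.
#' @param temperature temperature in degrees Celsius (optional).
#' @return a [TrajectoryEnsemble].
#' @export
readTrajectory <- function(topology, paths, condition = "cond",
                           temperature = NA_real_) {
  frames <- list(); reps <- integer(0)
  for (i in seq_along(paths)) {
    pdb <- bio3d::read.pdb(paths[i], multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    parsed <- bio3dToAtoms(pdb, paths[i])
    if (nrow(parsed$atoms) != nAtoms(topology))
      stop(sprintf("atom-count mismatch in '%s': file has %d atoms, topology has %d",
                   paths[i], nrow(parsed$atoms), nAtoms(topology)))
    xyz <- pdb$xyz[, bio3d::atom2xyz(parsed$keep), drop = FALSE]
    for (f in seq_len(nrow(xyz))) frames[[length(frames) + 1L]] <- unflattenFrame(xyz[f, ])
    reps <- c(reps, rep(i, nrow(xyz)))
  }
  arr <- array(0, c(length(frames), nAtoms(topology), 3L))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  newEnsemble(topology, arr, condition = condition, temperature = temperature,
              replicateIds = reps)
}

#' Construct an atom selection specification
#'
#' @param residueRange optional length-2 inclusive residue-id interval applied
#'   to protein (non-hetero) atoms.
#' @param backboneOnly restrict protein atoms to the backbone names
#'   N, CA, C, O.
#' @param includeResidueNames residue names (e.g. `"HEM"`, `"PLM"`) whose
#'   atoms are all pulled into the selection regardless of the protein
#'   criteria.
#' @param atomNames optional protein atom names to keep.
#' @param excludeHydrogens drop hydrogens from the final selection.
#' @return a [SelectionSpec].
#' @examples
#' # the canonical structural selection of the pipeline:
#' selectionSpec(residueRange = c(11, 412), backboneOnly = TRUE,
#'               includeResidueNames = c("HEM", "PLM"),
#'               excludeHydrogens = TRUE)
#' @export
selectionSpec <- function(residueRange = NULL, backboneOnly = FALSE,
                          includeResidueNames = character(0),
                          atomNames = character(0),
                          excludeHydrogens = FALSE) {
  new("SelectionSpec",
      residueRange = as.integer(residueRange %||% integer(0)),
      backboneOnly = backboneOnly,
      includeResidueNames = includeResidueNames,
      atomNames = atomNames,
      excludeHydrogens = excludeHydrogens)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

backboneNames <- c("N", "CA", "C", "O")

#' Resolve a selection against a topology
#'
#' Returns the ordered (topology-order) atom indices matched by a
#' [SelectionSpec]. Selection is deterministic and idempotent; an empty result
#' is an error, never a silent empty vector.
#'
#' @param topology a [Topology].
#' @param spec a [SelectionSpec].
#' @return integer vector of atom indices into the topology's atom table.
#' @export
selectAtoms <- function(topology, spec) {
  validObject(spec)
  at <- atoms(topology)
  proteinCriteria <- length(spec@residueRange) == 2L || isTRUE(spec@backboneOnly) ||
    length(spec@atomNames) > 0L
  if (proteinCriteria) {
    keep <- !at$hetero
    if (length(spec@residueRange) == 2L)
      keep <- keep & at$resid >= spec@residueRange[1] & at$resid <= spec@residueRange[2]
    if (isTRUE(spec@backboneOnly)) keep <- keep & at$name %in% backboneNames
    if (length(spec@atomNames) > 0L) keep <- keep & at$name %in% spec@atomNames
  } else {
    keep <- rep(TRUE, nrow(at))
  }
  if (length(spec@includeResidueNames) > 0L)
    keep <- keep | at$resname %in% spec@includeResidueNames
  if (isTRUE(spec@excludeHydrogens)) keep <- keep & !isHydrogen(topology)
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("selection resolves to no atoms on this topology")
  idx
}

#' Concatenate trajectory ensembles over a shared topology
#'
#' Pools frames of several ensembles (e.g. all replicates of both temperature
#' conditions before a joint PCA). Frame order within each input is preserved;
#' per-frame condition labels and replicate ids are carried through.
#'
#' @param ... [TrajectoryEnsemble] objects, or a single list of them.
#' @return a [TrajectoryEnsemble] whose `condition` is the unique input label
#'   (or the labels joined with `"+"`), with `frameConditions` recording each
#'   frame's origin.
#' @export
concatenateEnsembles <- function(...) {
  ens <- list(...)
  if (length(ens) == 1L && is.list(ens[[1]]) && !is(ens[[1]], "TrajectoryEnsemble"))
    ens <- ens[[1]]
  if (length(ens) == 0L) stop("no ensembles given")
  ref <- atoms(ens[[1]])
  for (e in ens[-1]) {
    if (!identical(atoms(e), ref))
      stop("topology mismatch: ensembles must share an identical topology")
  }
  nF <- vapply(ens, nFrames, integer(1))
  arr <- array(0, c(sum(nF), nrow(ref), 3L))
  off <- 0L
  for (e in ens) {
    arr[off + seq_len(nFrames(e)), , ] <- coords(e)
    off <- off + nFrames(e)
  }
  conds <- unlist(lapply(ens, frameConditions))
  reps <- unlist(lapply(ens, replicateIds))
  lab <- unique(vapply(ens, conditionLabel, character(1)))
  temp <- unique(vapply(ens, temperature, numeric(1)))
  newEnsemble(topology(ens[[1]]), arr,
              condition = paste(lab, collapse = "+"),
              temperature = if (length(temp) == 1L) temp else NA_real_,
              replicateIds = reps, frameConditions = conds)
}

#' Restrict an ensemble to the frames of one condition
#'
#' @param ensemble a [TrajectoryEnsemble] (possibly pooled).
#' @param condition the condition label to keep.
#' @return a [TrajectoryEnsemble] with only the matching frames.
#' @export
subsetCondition <- function(ensemble, condition) {
  keep <- frameConditions(ensemble) == condition
  if (!any(keep)) stop(sprintf("no frames with condition '%s'", condition))
  newEnsemble(topology(ensemble),
              coords(ensemble)[keep, , , drop = FALSE],
              condition = condition, temperature = temperature(ensemble),
              replicateIds = replicateIds(ensemble)[keep],
              frameConditions = frameConditions(ensemble)[keep])
}
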