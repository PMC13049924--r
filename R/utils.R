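# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single numeric seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Per-atom residue key "chain|resid|insert"; unique within a residue.
resKey <- function(topology) {
  at <- atoms(topology)
  paste(at$chain, at$resid, at$insert, sep = "|")
}

# Human-readable residue tag like "A:SER101".
resTag <- function(topology) {
  at <- atoms(topology)
  paste0(at$chain, ":", at$resname, at$resid,
         ifelse(nzchar(at$insert), at$insert, ""))
}

# Hydrogen detection: element field when present, else atom-name first letter
# after stripping leading digits (tolerates minimal PDB writers).
isHydrogen <- function(topology) {
  at <- atoms(topology)
  el <- toupper(trimws(at$elem))
  byElem <- el %in% c("H", "D")
  blank <- !nzchar(el)
  if (any(blank)) {
    nm <- toupper(sub("^[0-9]+", "", trimws(at$name[blank])))
    byElem[blank] <- substr(nm, 1L, 1L) == "H"
  }
  byElem
}

# Flatten an F x N x 3 array to F x 3N (x1,y1,z1,x2,...) and back.
flattenFrames <- function(arr, atomIdx = NULL) {
  if (!is.null(atomIdx)) arr <- arr[, atomIdx, , drop = FALSE]
  f <- dim(arr)[1]; n <- dim(arr)[2]
  out <- matrix(0, f, 3L * n)
  out[, seq(1L, 3L * n, by = 3L)] <- arr[, , 1]
  out[, seq(2L, 3L * n, by = 3L)] <- arr[, , 2]
  out[, seq(3L, 3L * n, by = 3L)] <- arr[, , 3]
  out
}

unflattenFrame <- function(v) {
  matrix(v, ncol = 3L, byrow = TRUE)
}

# New ensemble sharing a topology, with basic checks delegated to validity.
newEnsemble <- function(topology, coords, condition = "cond",
                        temperature = NA_real_, replicateIds = NULL,
                        frameConditions = NULL) {
  if (is.matrix(coords)) {         # single N x 3 frame
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  if (is.null(replicateIds)) replicateIds <- rep(1L, dim(coords)[1])
  if (is.null(frameConditions)) frameConditions <- rep(condition, dim(coords)[1])
  new("TrajectoryEnsemble", topology = topology, coords = coords,
      condition = condition, temperature = as.numeric(temperature),
      replicateIds = as.integer(replicateIds),
      frameConditions = frameConditions)
}

# Angle (degrees) at vertex b formed by rays b->a and b->c.
vectorAngle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cs <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  cs <- max(-1, min(1, cs))
  acos(cs) * 180 / pi
}
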