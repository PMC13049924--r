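# Substrate-positioning coupling: the combined z-score of the heme-iron to
# substrate-Cbeta distance and the Calpha-Cbeta-Fe angle, and the per-residue
# correlation of motion with that score.

#' Locate an atom by residue name and atom name
#'
#' @param topology a [Topology].
#' @param resname residue name (e.g. `"HEM"`).
#' @param name atom name (e.g. `"FE"`).
#' @return the atom's topology index (error if absent or ambiguous).
#' @export
findAtom <- function(topology, resname, name) {
  at <- atoms(topology)
  i <- which(at$resname == resname & at$name == name)
  if (length(i) == 0L)
    stop(sprintf("no atom '%s' in residue '%s'", name, resname))
  if (length(i) > 1L)
    stop(sprintf("atom '%s' in residue '%s' is ambiguous", name, resname))
  i
}

#' Reaction-geometry series of substrate positioning
#'
#' Per frame: the Euclidean distance between the heme iron and the substrate
#' Cbeta atom, and the angle at the Cbeta vertex between the rays toward the
#' substrate Calpha and the iron. Together the two descriptors capture
#' substrate proximity and orientation within the active site.
#'
#' @param ensemble a [TrajectoryEnsemble].
#' @param feAtom,calphaAtom,cbetaAtom atom indices (see [findAtom()]); by
#'   default the FE atom of HEM and the CA/CB atoms of PLM.
#' @return `data.frame` with columns `frame`, `distance` (Angstrom) and
#'   `angle` (degrees, in `[0, 180]`).
#' @export
reactionGeometrySeries <- function(ensemble,
                                   feAtom = findAtom(topology(ensemble), "HEM", "FE"),
                                   calphaAtom = findAtom(topology(ensemble), "PLM", "CA"),
                                   cbetaAtom = findAtom(topology(ensemble), "PLM", "CB")) {
  arr <- coords(ensemble)
  nF <- dim(arr)[1]
  dist <- numeric(nF); ang <- numeric(nF)
  for (f in seq_len(nF)) {
    fe <- arr[f, feAtom, ]; ca <- arr[f, calphaAtom, ]; cb <- arr[f, cbetaAtom, ]
    dist[f] <- sqrt(sum((fe - cb)^2))
    ang[f] <- vectorAngle(ca, cb, fe)
  }
  data.frame(frame = seq_len(nF), distance = dist, angle = ang)
}

#' Combined z-score of substrate positioning
#'
#' Standardizes each reaction-geometry descriptor over the frames (mean 0,
#' unit variance) and combines them with the given weights (default: equal
#' weights, `z = (z_distance + z_angle) / 2`). Larger z means larger Fe-Cbeta
#' distance and larger angle. Standardization makes z invariant to affine
#' rescaling of either raw descriptor. Standardize within one condition at a
#' time: pooling conditions would fold the between-condition contrast into
#' the score.
#'
#' @param series `data.frame` from [reactionGeometrySeries()] (>= 2 frames,
#'   both descriptors with nonzero variance).
#' @param weights length-2 numeric weights for (distance, angle), summing
#'   to 1.
#' @return `data.frame` with columns `frame`, `zDistance`, `zAngle`, `z`.
#' @export
combinedZscore <- function(series, weights = c(0.5, 0.5)) {
  if (nrow(series) < 2L) stop("z-score needs at least 2 frames")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  sdd <- stats::sd(series$distance); sda <- stats::sd(series$angle)
  if (sdd == 0) stop("degenerate series: distance has zero variance")
  if (sda == 0) stop("degenerate series: angle has zero variance")
  zd <- (series$distance - mean(series$distance)) / sdd
  za <- (series$angle - mean(series$angle)) / sda
  data.frame(frame = series$frame, zDistance = zd, zAngle = za,
             z = weights[1] * zd + weights[2] * za)
}

#' Per-residue coupling profile against the substrate z-score
#'
#' Pearson correlation, per protein residue, between the per-frame
#' displacement magnitude of the residue's Calpha from its ensemble-mean
#' position and the combined z-score series. Requires an ensemble with global
#' motion already removed (aligned); high `|r|` marks regions whose motion is
#' coupled to substrate positioning.
#'
#' @param ensemble an aligned [TrajectoryEnsemble].
#' @param zscore `data.frame` from [combinedZscore()] (or any vector-like
#'   with a `z` column) with one row per frame.
#' @param statistic `"ca-displacement"` (default) or `"residue-rmsd"`:
#'   summarize residue motion by the Calpha displacement magnitude or by the
#'   per-frame RMSD of the residue's heavy atoms from their mean positions.
#' @return `data.frame` with columns `chain`, `resid`, `resname`, `r` and
#'   `n` (frames used); residues without a Calpha are excluded.
#' @export
residueCouplingProfile <- function(ensemble, zscore,
                                   statistic = c("ca-displacement",
                                                 "residue-rmsd")) {
  statistic <- match.arg(statistic)
  z <- if (is.data.frame(zscore)) zscore$z else as.numeric(zscore)
  arr <- coords(ensemble)
  nF <- dim(arr)[1]
  if (length(z) != nF)
    stop(sprintf("shape error: %d z values for %d frames", length(z), nF))
  at <- atoms(topology(ensemble))
  ca <- which(!at$hetero & at$name == "CA")
  mu <- apply(arr, c(2, 3), mean)
  r <- vapply(ca, function(a) {
    disp <- if (statistic == "ca-displacement") {
      dev <- sweep(arr[, a, , drop = TRUE], 2, mu[a, ])
      sqrt(rowSums(dev^2))
    } else {
      key <- resKey(topology(ensemble))
      grp <- which(key == key[a] & !isHydrogen(topology(ensemble)))
      vapply(seq_len(nF), function(f) {
        dev <- arr[f, grp, , drop = TRUE] - mu[grp, , drop = TRUE]
        sqrt(mean(rowSums(matrix(dev, ncol = 3)^2)))
      }, numeric(1))
    }
    if (stats::sd(disp) == 0) return(NA_real_)
    stats::cor(disp, z)
  }, numeric(1))
  data.frame(chain = at$chain[ca], resid = at$resid[ca],
             resname = at$resname[ca], r = r, n = nF)
}
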