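# Solvent-accessible surface area (Shrake-Rupley sphere-point quadrature),
# surface-residue classification and the charged-residue census used for
# cross-homolog surface-composition comparison.

# Default van der Waals radii (Angstrom) per element.
defaultVdwRadii <- local({
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
         P = 1.80, FE = 2.00, ZN = 1.39, MG = 1.73,
         K = 2.75, CL = 1.75, BR = 1.85, I = 1.98, F = 1.47)
  r[["NA"]] <- 2.27   # sodium
  r
})

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral), the quadrature grid of the Shrake-Rupley algorithm.
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by sphere-point quadrature: each atom's solvent-accessible
#' sphere (van der Waals radius plus probe radius) is sampled at `nPoints`
#' quasi-uniform points; a point is accessible when it lies outside every
#' neighbouring atom's accessible sphere. Deterministic for a fixed point
#' count.
#'
#' @param topology a [Topology].
#' @param coordsFrame `N x 3` coordinates (Angstrom).
#' @param probeRadius solvent probe radius (default 1.4 Angstrom, water).
#' @param nPoints quadrature points per atom (default 960).
#' @param radii named per-element radius table overriding/extending the
#'   built-in van der Waals defaults.
#' @param includeHydrogens include hydrogens in the calculation (default
#'   FALSE: heavy-atom SASA).
#' @return list with `perAtom` (`data.frame`: `atom`, `sasa` in Angstrom^2),
#'   `perResidue` (`data.frame`: `chain`, `resid`, `resname`, `sasa` — the
#'   sum over member atoms), `probeRadius` and `nPoints`.
#' @export
shrakeRupleySasa <- function(topology, coordsFrame, probeRadius = 1.4,
                             nPoints = 960L, radii = NULL,
                             includeHydrogens = FALSE) {
  at <- atoms(topology)
  rt <- defaultVdwRadii
  if (!is.null(radii)) rt[names(radii)] <- radii
  use <- if (includeHydrogens) seq_len(nrow(at)) else which(!isHydrogen(topology))
  el <- toupper(at$elem[use])
  unknown <- setdiff(unique(el), names(rt))
  if (length(unknown))
    stop(sprintf("no radius for element(s): %s", paste(unknown, collapse = ", ")))
  r <- unname(rt[el]) + probeRadius
  crd <- coordsFrame[use, , drop = FALSE]
  pts <- spherePoints(nPoints)
  n <- length(use)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    ctr <- crd[i, ]
    dd <- sqrt(rowSums(sweep(crd, 2, ctr)^2))
    nb <- which(dd < r[i] + r & seq_len(n) != i)
    if (length(nb) == 0L) {
      sasa[i] <- 4 * pi * r[i]^2
      next
    }
    P <- sweep(pts * r[i], 2, ctr, `+`)
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      d2 <- rowSums(sweep(P, 2, crd[j, ])^2)
      free <- free & d2 >= r[j]^2
    }
    sasa[i] <- 4 * pi * r[i]^2 * sum(free) / nPoints
  }
  perAtom <- data.frame(atom = use, sasa = sasa)
  key <- paste(at$chain[use], at$resid[use], at$insert[use], sep = "|")
  agg <- tapply(sasa, key, sum)
  first <- !duplicated(key)
  perResidue <- data.frame(chain = at$chain[use][first],
                           resid = at$resid[use][first],
                           resname = at$resname[use][first],
                           sasa = as.numeric(agg[key[first]]))
  perResidue <- perResidue[order(perResidue$chain, perResidue$resid), ]
  rownames(perResidue) <- NULL
  list(perAtom = perAtom, perResidue = perResidue,
       probeRadius = probeRadius, nPoints = as.integer(nPoints))
}

#' Classify surface residues by SASA
#'
#' A residue is on the surface when its summed SASA exceeds the threshold
#' (default 2.5 Angstrom^2, the convention of the commonly used
#' surface-residue scripts). Classification is monotone in the threshold.
#'
#' @param sasa result of [shrakeRupleySasa()].
#' @param threshold per-residue SASA threshold (Angstrom^2).
#' @return `data.frame` of surface residues (`chain`, `resid`, `resname`,
#'   `sasa`); zero rows when none qualify.
#' @export
classifySurfaceResidues <- function(sasa, threshold = 2.5) {
  pr <- sasa$perResidue
  pr[pr$sasa > threshold, , drop = FALSE]
}

chargedClasses <- c(ARG = "R", LYS = "K", HIS = "H", ASP = "D", GLU = "E")

#' Charged-residue census
#'
#' Counts arginine (R), aspartate (D), glutamate (E), histidine (H) and
#' lysine (K) over a residue set — the whole protein or its surface residues.
#' Negatives are D+E; positives are R+K+H, with histidine also reported
#' separately since its charge is pH-dependent. Non-standard residue names
#' count as "other".
#'
#' @param topology a [Topology].
#' @param residues optional `data.frame` with `chain` and `resid` columns
#'   restricting the census (e.g. from [classifySurfaceResidues()]); default:
#'   all protein residues.
#' @return list with `counts` (named integer vector over R, K, H, D, E),
#'   `negative` (D+E), `positive` (R+K+H), `histidine`, `net`
#'   (positive - negative), `other` and `nResidues`.
#' @export
chargedResidueCensus <- function(topology, residues = NULL) {
  at <- atoms(topology)
  first <- !duplicated(paste(at$chain, at$resid, at$insert, sep = "|")) & !at$hetero
  res <- at[first, c("chain", "resid", "resname")]
  if (!is.null(residues)) {
    key <- paste(res$chain, res$resid)
    res <- res[key %in% paste(residues$chain, residues$resid), , drop = FALSE]
  }
  cls <- chargedClasses[res$resname]
  counts <- vapply(c("R", "K", "H", "D", "E"),
                   function(x) sum(cls == x, na.rm = TRUE), integer(1))
  std <- c(names(chargedClasses), "ALA", "GLY", "SER", "THR", "CYS", "VAL",
           "LEU", "ILE", "MET", "PRO", "PHE", "TYR", "TRP", "ASN", "GLN")
  list(counts = counts,
       negative = unname(counts["D"] + counts["E"]),
       positive = unname(counts["R"] + counts["K"] + counts["H"]),
       histidine = unname(counts["H"]),
       net = unname(counts["R"] + counts["K"] + counts["H"] -
                      counts["D"] - counts["E"]),
       other = sum(!res$resname %in% std),
       nResidues = nrow(res))
}
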