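# Geometric hydrogen-bond detection (donor-acceptor distance and deviation
# from D-H-A linearity), occupancy quantification over frames, and
# two-condition differential networks.

#' Build donor and acceptor catalogs
#'
#' Donors are N/O atoms with at least one hydrogen within the covalent
#' assignment distance in the reference frame; acceptors are all N/O atoms.
#' Heme propionate and substrate carboxylate oxygens participate under the
#' same rules.
#'
#' @param topology a [Topology].
#' @param coordsRef `N x 3` reference coordinates used for the covalent
#'   hydrogen assignment.
#' @param covalentCutoff maximum donor-hydrogen distance (default 1.2
#'   Angstrom).
#' @param elements element symbols eligible as donors/acceptors.
#' @return list with `donors` (`data.frame`: `donor`, `hydrogen` atom
#'   indices) and `acceptors` (integer atom indices). A topology without
#'   hydrogens yields an empty donor catalog with a warning.
#' @export
assignDonorsAcceptors <- function(topology, coordsRef, covalentCutoff = 1.2,
                                  elements = c("N", "O")) {
  at <- atoms(topology)
  hyd <- which(isHydrogen(topology))
  heavy <- which(at$elem %in% elements)
  donors <- data.frame(donor = integer(0), hydrogen = integer(0))
  if (length(hyd) == 0L) {
    warning("no hydrogens in topology: donor catalog is empty")
  } else {
    key <- resKey(topology)
    for (h in hyd) {
      cand <- heavy[key[heavy] == key[h]]   # covalent partner: same residue
      if (length(cand) == 0L) cand <- heavy
      dd <- sqrt(colSums((t(coordsRef[cand, , drop = FALSE]) - coordsRef[h, ])^2))
      ok <- cand[dd <= covalentCutoff]
      if (length(ok))
        donors <- rbind(donors, data.frame(donor = ok[which.min(dd[dd <= covalentCutoff])],
                                           hydrogen = h))
    }
  }
  list(donors = donors, acceptors = heavy)
}

#' Detect hydrogen bonds in one frame
#'
#' A donor-hydrogen-acceptor triad is a hydrogen bond when the donor-acceptor
#' heavy-atom distance is at most `distanceCutoff` (3.0 Angstrom) and the
#' D-H-A angle deviates from linearity by at most `angleCutoff` (20 degrees,
#' i.e. the D-H-A angle is at least 160 degrees) — the convention of the
#' standard trajectory-analysis tools. Intra-residue bonds are excluded by
#' default. Detection depends only on internal geometry, so it is invariant
#' under rigid motion of the frame.
#'
#' @param coordsFrame `N x 3` coordinates of one frame.
#' @param topology the [Topology].
#' @param catalogs donor/acceptor catalogs from [assignDonorsAcceptors()].
#' @param distanceCutoff donor-acceptor distance cutoff (Angstrom).
#' @param angleCutoff maximum deviation from D-H-A linearity (degrees).
#' @param excludeIntraResidue drop donor/acceptor pairs within one residue.
#' @return `data.frame` with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `distance` (Angstrom) and `deviation` (degrees); zero rows when
#'   no bond is present.
#' @export
detectHbondsFrame <- function(coordsFrame, topology, catalogs,
                              distanceCutoff = 3.0, angleCutoff = 20,
                              excludeIntraResidue = TRUE) {
  dn <- catalogs$donors
  acc <- catalogs$acceptors
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      deviation = numeric(0))
  if (nrow(dn) == 0L || length(acc) == 0L) return(empty)
  key <- resKey(topology)
  hits <- list()
  for (i in seq_len(nrow(dn))) {
    d <- dn$donor[i]; h <- dn$hydrogen[i]
    a <- setdiff(acc, d)
    if (excludeIntraResidue) a <- a[key[a] != key[d]]
    if (length(a) == 0L) next
    dv <- t(coordsFrame[a, , drop = FALSE]) - coordsFrame[d, ]
    dist <- sqrt(colSums(dv^2))
    near <- dist <= distanceCutoff
    if (!any(near)) next
    a <- a[near]; dist <- dist[near]
    dev <- vapply(seq_along(a), function(j)
      180 - vectorAngle(coordsFrame[d, ], coordsFrame[h, ], coordsFrame[a[j], ]),
      numeric(1))
    ok <- dev <= angleCutoff
    if (any(ok))
      hits[[length(hits) + 1L]] <- data.frame(
        donor = d, hydrogen = h, acceptor = a[ok],
        distance = dist[ok], deviation = dev[ok])
  }
  if (length(hits) == 0L) return(empty)
  do.call(rbind, hits)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Per residue pair, the fraction of frames in which at least one
#' donor-hydrogen-acceptor triad between the two residues satisfies the
#' geometric criterion. By default this is run on pseudotrajectory frames
#' (mirroring the conformational-state pipeline); any raw ensemble works the
#' same way.
#'
#' @param x a [Pseudotrajectory] or [TrajectoryEnsemble].
#' @param catalogs donor/acceptor catalogs from [assignDonorsAcceptors()].
#' @param distanceCutoff,angleCutoff detection cutoffs (3.0 Angstrom,
#'   20 degrees).
#' @param excludeIntraResidue drop intra-residue bonds.
#' @return `data.frame` with columns `res1`, `res2` (residue tags, donor-side
#'   first by frame-count majority is not imposed: pairs are unordered and
#'   canonicalized by topology order), `occupancy` in `[0, 1]`, `nFrames` and
#'   `triads` (supporting triads as `donor->acceptor` atom-name strings).
#'   Pairs never satisfying the criterion are absent.
#' @export
hbondOccupancy <- function(x, catalogs, distanceCutoff = 3.0, angleCutoff = 20,
                           excludeIntraResidue = TRUE) {
  topo <- topology(x)
  arr <- coords(x)
  nF <- dim(arr)[1]
  at <- atoms(topo)
  tag <- resTag(topo)
  key <- resKey(topo)
  resOrder <- match(key, unique(key))    # topology order of residues
  counts <- new.env(parent = emptyenv())
  triads <- new.env(parent = emptyenv())
  for (f in seq_len(nF)) {
    crd <- arr[f, , ]; dim(crd) <- dim(arr)[2:3]
    hb <- detectHbondsFrame(crd, topo, catalogs, distanceCutoff, angleCutoff,
                            excludeIntraResidue)
    if (nrow(hb) == 0L) next
    r1 <- ifelse(resOrder[hb$donor] <= resOrder[hb$acceptor],
                 tag[hb$donor], tag[hb$acceptor])
    r2 <- ifelse(resOrder[hb$donor] <= resOrder[hb$acceptor],
                 tag[hb$acceptor], tag[hb$donor])
    pair <- paste(r1, r2, sep = "~")
    tr <- paste0(at$name[hb$donor], "->", at$name[hb$acceptor])
    for (p in unique(pair)) {
      counts[[p]] <- (if (is.null(counts[[p]])) 0L else counts[[p]]) + 1L
      triads[[p]] <- union(if (is.null(triads[[p]])) character(0) else triads[[p]],
                           tr[pair == p])
    }
  }
  pairs <- ls(counts)
  if (length(pairs) == 0L)
    return(data.frame(res1 = character(0), res2 = character(0),
                      occupancy = numeric(0), nFrames = integer(0),
                      triads = character(0)))
  parts <- strsplit(pairs, "~", fixed = TRUE)
  out <- data.frame(
    res1 = vapply(parts, `[`, character(1), 1),
    res2 = vapply(parts, `[`, character(1), 2),
    occupancy = vapply(pairs, function(p) counts[[p]] / nF, numeric(1)),
    nFrames = nF,
    triads = vapply(pairs, function(p) paste(sort(triads[[p]]), collapse = ";"),
                    character(1)),
    row.names = NULL)
  out[order(out$res1, out$res2), , drop = FALSE]
}

#' Differential hydrogen-bond network between two conditions
#'
#' Pairs whose occupancy differs between condition A and condition B by at
#' least `deltaThreshold` become directed "enrichment" edges: positive
#' `delta = occupancyA - occupancyB` tags the pair enriched in A, negative in
#' B. Pairs absent from one table count as occupancy 0 there. Swapping A and
#' B flips every enrichment label and negates every delta.
#'
#' @param tableA,tableB occupancy tables from [hbondOccupancy()] for the two
#'   conditions (same topology).
#' @param deltaThreshold reporting threshold in `(0, 1]` (default 0.25).
#' @param conditionA,conditionB labels used in the `enriched` column.
#' @return `data.frame` with columns `res1`, `res2`, `occupancyA`,
#'   `occupancyB`, `delta` and `enriched`, sorted by decreasing `|delta|`.
#' @seealso [writeEdgeTable()]
#' @export
differentialNetwork <- function(tableA, tableB, deltaThreshold = 0.25,
                                conditionA = "A", conditionB = "B") {
  if (deltaThreshold <= 0 || deltaThreshold > 1)
    stop("deltaThreshold must lie in (0, 1]")
  keyA <- paste(tableA$res1, tableA$res2, sep = "~")
  keyB <- paste(tableB$res1, tableB$res2, sep = "~")
  allKeys <- union(keyA, keyB)
  occA <- tableA$occupancy[match(allKeys, keyA)]
  occB <- tableB$occupancy[match(allKeys, keyB)]
  occA[is.na(occA)] <- 0
  occB[is.na(occB)] <- 0
  delta <- occA - occB
  keep <- abs(delta) >= deltaThreshold
  parts <- strsplit(allKeys[keep], "~", fixed = TRUE)
  out <- data.frame(
    res1 = vapply(parts, `[`, character(1), 1),
    res2 = vapply(parts, `[`, character(1), 2),
    occupancyA = occA[keep], occupancyB = occB[keep], delta = delta[keep],
    enriched = ifelse(delta[keep] > 0, conditionA, conditionB),
    row.names = NULL)
  out[order(-abs(out$delta), out$res1), , drop = FALSE]
}

#' Export a differential edge table
#'
#' Writes the edges of a differential hydrogen-bond network as a plain edge
#' table for downstream network tools: CSV (`source, target, delta,
#' enriched`) or SIF (`source interaction target`).
#'
#' @param edges `data.frame` from [differentialNetwork()].
#' @param path output file path.
#' @param format `"csv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
writeEdgeTable <- function(edges, path, format = c("csv", "sif")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(data.frame(source = edges$res1, target = edges$res2,
                                delta = edges$delta, enriched = edges$enriched),
                     path, row.names = FALSE)
  } else {
    writeLines(sprintf("%s hbond-%s %s", edges$res1, edges$enriched, edges$res2),
               path)
  }
  invisible(path)
}
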