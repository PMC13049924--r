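# Rigid-body superposition, heavy-atom PCA to a cumulative-variance target,
# and the composite per-residue essential-dynamics (B-factor-like) score.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of a mobile frame onto a reference over a set
#' of fit atoms. The returned rotation is proper (determinant +1; reflections
#' excluded) and the returned RMSD over the fit atoms is the global minimum
#' over rigid transforms.
#'
#' @param mobile `N x 3` coordinate matrix to transform.
#' @param reference `N x 3` coordinate matrix to fit onto.
#' @param fitIdx integer atom indices used for the fit (at least 3,
#'   non-collinear). All atoms of `mobile` are carried by the fitted
#'   transform.
#' @return list with `rotation` (3x3), `translation` (length 3), `coords`
#'   (transformed mobile frame) and `rmsd` (Angstrom, over `fitIdx`).
#' @export
kabschSuperpose <- function(mobile, reference, fitIdx = seq_len(nrow(mobile))) {
  if (length(fitIdx) < 3L)
    stop("degenerate fit: at least 3 fit atoms are required")
  P <- mobile[fitIdx, , drop = FALSE]
  Q <- reference[fitIdx, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity check: centered fit atoms must span a plane
  sv <- svd(Pc, nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate fit: fit atoms are (near-)collinear")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cq - R %*% cp)
  out <- sweep(mobile %*% t(R), 2, trans, `+`)
  dev <- out[fitIdx, , drop = FALSE] - reference[fitIdx, , drop = FALSE]
  list(rotation = R, translation = trans, coords = out,
       rmsd = sqrt(mean(rowSums(dev^2))))
}

# RMSD between two frames after optimal superposition over idx.
superposedRmsd <- function(a, b, idx) {
  kabschSuperpose(a, b, idx)$rmsd
}

#' Align every frame of an ensemble onto a reference frame
#'
#' Superposes each frame onto the chosen reference frame over the fit
#' selection (default: protein backbone heavy atoms); non-fit atoms are
#' carried by the same rigid transform. Alignment is idempotent.
#'
#' @param ensemble a [TrajectoryEnsemble].
#' @param referenceFrame index of the reference frame (default 1).
#' @param fitSpec a [SelectionSpec] for the fit atoms; default backbone heavy
#'   atoms.
#' @return the aligned [TrajectoryEnsemble].
#' @export
alignEnsemble <- function(ensemble, referenceFrame = 1L,
                          fitSpec = selectionSpec(backboneOnly = TRUE,
                                                  excludeHydrogens = TRUE)) {
  fitIdx <- selectAtoms(topology(ensemble), fitSpec)
  arr <- coords(ensemble)
  ref <- frameCoords(ensemble, referenceFrame)
  for (f in seq_len(nFrames(ensemble))) {
    m <- arr[f, , ]; dim(m) <- dim(arr)[2:3]
    arr[f, , ] <- kabschSuperpose(m, ref, fitIdx)$coords
  }
  newEnsemble(topology(ensemble), arr, condition = conditionLabel(ensemble),
              temperature = temperature(ensemble),
              replicateIds = replicateIds(ensemble),
              frameConditions = frameConditions(ensemble))
}

#' Principal component analysis of heavy-atom coordinates
#'
#' Eigendecomposition of the sample covariance (unbiased, F-1 denominator) of
#' the flattened analysis-selection coordinates of an aligned ensemble. The
#' retained component count K is the smallest k whose cumulative variance
#' fraction reaches `varianceTarget` (default 0.75). A zero-variance ensemble
#' yields K = 0 with a warning.
#'
#' @param ensemble an aligned [TrajectoryEnsemble] with at least 2 frames.
#' @param analysisSpec [SelectionSpec] of analysis atoms; default all heavy
#'   atoms.
#' @param varianceTarget cumulative variance fraction to retain.
#' @return a [PCAModel].
#' @export
pcaHeavyAtoms <- function(ensemble,
                          analysisSpec = selectionSpec(excludeHydrogens = TRUE),
                          varianceTarget = 0.75) {
  if (nFrames(ensemble) < 2L)
    stop("insufficient frames: PCA needs at least 2 frames")
  idx <- selectAtoms(topology(ensemble), analysisSpec)
  X <- flattenFrames(coords(ensemble), idx)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc)
  lam <- s$d^2 / (nrow(X) - 1)
  keep <- seq_len(min(nrow(X) - 1L, ncol(X)))
  lam <- lam[keep]
  V <- s$v[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude loading component positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  tot <- sum(lam)
  if (tot <= 1e-12) {
    warning("zero total variance: cumulative-variance target unreachable, K = 0")
    cv <- rep(NaN, length(lam))
    K <- 0L
  } else {
    cv <- cumsum(lam) / tot
    K <- as.integer(which(cv >= varianceTarget - 1e-12)[1])
  }
  new("PCAModel", mean = mu, eigenvalues = lam, loadings = V,
      cumulativeVariance = cv, retained = K,
      varianceTarget = varianceTarget, atomIndices = idx)
}

#' Project frames onto retained principal components
#'
#' Projects mean-centered flattened analysis coordinates onto the retained
#' loading vectors, giving the reduced PC-space representation used for
#' conformational-state clustering.
#'
#' @param model a [PCAModel].
#' @param ensemble a [TrajectoryEnsemble] over the same topology/selection.
#' @param nComponents number of components to project on. Default: the
#'   model's retained K (the essential subspace at the cumulative-variance
#'   target); pass `ncol(model@loadings)` for all stored components.
#' @return `F x nComponents` numeric matrix of PC scores.
#' @export
projectFrames <- function(model, ensemble,
                          nComponents = max(model@retained, 1L)) {
  X <- flattenFrames(coords(ensemble), model@atomIndices)
  if (ncol(X) != length(model@mean))
    stop("shape error: ensemble selection does not match the PCA model")
  nComponents <- min(nComponents, ncol(model@loadings))
  sweep(X, 2, model@mean) %*% model@loadings[, seq_len(nComponents), drop = FALSE]
}

#' Per-residue essential-dynamics score
#'
#' Computes the composite temperature-factor-like score from a PCA model:
#' per atom, `B_a = (8 pi^2 / 3) * sum_{k <= K} lambda_k * ||v_{k,a}||^2`
#' where `v_{k,a}` is atom a's 3-component block of the k-th loading vector
#' and K is the retained component count; per residue, the mean of `B_a` over
#' the residue's analysis-selection atoms.
#'
#' @param model a [PCAModel] with `retained >= 1`.
#' @param topology the [Topology] the model was built on.
#' @param nComponents number of components to sum over (default: the model's
#'   retained K).
#' @return list with `perAtom` (`data.frame`: `atom`, `B`) and `perResidue`
#'   (`data.frame`: `chain`, `resid`, `resname`, `B`), B in Angstrom^2.
#' @export
essentialDynamicsScore <- function(model, topology,
                                   nComponents = model@retained) {
  if (model@retained < 1L && missing(nComponents))
    stop("undefined score: PCA model retained no components (K = 0)")
  if (nComponents < 1L)
    stop("undefined score: at least one component is required")
  nComponents <- min(nComponents, ncol(model@loadings))
  V <- model@loadings[, seq_len(nComponents), drop = FALSE]
  lam <- model@eigenvalues[seq_len(nComponents)]
  m <- length(model@atomIndices)
  # squared loading norm per atom per component
  sq <- V^2
  perAtomComp <- sq[seq(1, 3 * m, 3), , drop = FALSE] +
    sq[seq(2, 3 * m, 3), , drop = FALSE] +
    sq[seq(3, 3 * m, 3), , drop = FALSE]
  B <- (8 * pi^2 / 3) * as.numeric(perAtomComp %*% lam)
  at <- atoms(topology)[model@atomIndices, , drop = FALSE]
  perAtom <- data.frame(atom = model@atomIndices, B = B)
  key <- paste(at$chain, at$resid, at$insert, sep = "|")
  agg <- tapply(B, key, mean)
  first <- !duplicated(key)
  ord <- key[first]
  perResidue <- data.frame(chain = at$chain[first], resid = at$resid[first],
                           resname = at$resname[first],
                           B = as.numeric(agg[ord]))
  perResidue <- perResidue[order(perResidue$chain, perResidue$resid), ]
  rownames(perResidue) <- NULL
  list(perAtom = perAtom, perResidue = perResidue)
}
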