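# essdyn

Temperature-differential essential dynamics of protein trajectory ensembles.

## The problem

Cold-adapted enzymes often keep a conserved active site but change how they
*move*: flexibility shifts at the protein surface and in substrate-anchoring
loops decide whether catalysis still works at low temperature. For CYP152
peroxygenases (P450 fatty-acid decarboxylases with a heme cofactor and a
bound fatty-acid substrate), the question is how conformational dynamics at,
say, 20 °C vs 30 °C reposition the substrate over the heme iron and rewire
the hydrogen-bond network around the catalytic residues.

`essdyn` is an R implementation of the full comparative-dynamics pipeline for
this setting. It consumes MD trajectory ensembles (multi-model PDB) labelled
by condition and replicate, plus tabular spectroscopy data, and provides:

* **Essential dynamics** — backbone-heavy-atom alignment (Kabsch), PCA of all
  heavy-atom coordinates to a cumulative-variance target (75% by default),
  and a per-residue temperature-factor-like score

  B_i = mean over residue atoms of (8π²/3) · Σ_{k≤K} λ_k ‖v_{k,a}‖²,

  with eigenvalues λ_k (Å²) and orthonormal atomic loadings v_k.
* **Conformational states** — HDBSCAN clustering (Manhattan metric, leaf
  selection) of frames in the reduced PC space; per-cluster medoids (the
  member minimizing mean pairwise RMSD); the symmetric medoid RMSD matrix
  over "protein backbone (residues 11–412) + heme + substrate, no hydrogens".
* **Pseudotrajectories** — nearest-neighbour traversal of the medoid RMSD
  matrix, linear morph interpolation with the frame count scaled to the RMSD
  between successive medoids, and Cα RMSF profiles from the morph path.
* **Hydrogen-bond networks** — geometric detection (donor–acceptor ≤ 3.0 Å,
  ≤ 20° deviation from D–H–A linearity), per-residue-pair occupancies, and
  differential A-vs-B edge tables (CSV/SIF export).
* **Substrate coupling** — a per-frame z-score combining the standardized
  Fe–Cβ distance and Cα–Cβ–Fe angle, correlated per residue with Cα
  displacement to locate regions coupled to substrate positioning.
* **Surface composition** — Shrake–Rupley SASA, surface-residue
  classification, and a charged-residue census (R/K/H vs D/E).
* **Spectroscopy fits** — Morrison tight-binding K_d, Boltzmann sigmoidal
  T_m, two-summed-exponential stopped-flow decays, and the kinetic isotope
  effect k_H/k_D.
* **Synthetic data** — seed-deterministic generators that plant known
  covariance modes, metastable states, H-bond occupancy schedules,
  residue–substrate coupling and spectroscopic parameters, returning the
  ground truth alongside every dataset so the whole pipeline is testable
  without running MD.

## Worked example

```r
library(essdyn)

## build a synthetic system with three planted conformational states
toy <- buildToyTopology(10, withCofactors = TRUE)
centers <- makeStateCenters(toy$coords, K = 3, separation = 3, seed = 101)
cold <- generateMetastableEnsemble(toy$topology, centers, framesPerState = 100,
                                   withinStateSd = 0.3, condition = "20C",
                                   temperature = 20, seed = 102)

## essential dynamics: PCA to 75% variance, per-residue score
model <- pcaHeavyAtoms(cold$ensemble, varianceTarget = 0.75)
model
#> PCAModel: 48 atoms, 144 components, retained K = 2 (target 75%)
#>   lambda_1 = 1.507 A^2 (45.5% of variance)
head(essentialDynamicsScore(model, toy$topology)$perResidue, 3)
#>   chain resid resname        B
#> 1     A     1     ALA 1.125427
#> 2     A     2     ALA 1.462539
#> 3     A     3     ALA 1.392132

## conformational states, medoids, morph pseudotrajectory, RMSF
pc <- projectFrames(model, cold$ensemble)
states <- stateDecomposition(cold$ensemble, pc)
states
#> StateDecomposition: 300 frames, 3 clusters, 0 noise frames
ordering <- nearestNeighborOrder(medoidRmsd(states),
                                 traversalStart(stateLabels(states), medoidFrames(states)))
pseudo <- buildPseudotrajectory(cold$ensemble, medoidFrames(states), ordering)
pseudo
#> Pseudotrajectory: 13 frames (3 medoids, 10 interpolated)
head(rmsfCalpha(pseudo), 3)
#>   chain resid resname      rmsf
#> 1     A     1     ALA 0.1607097
#> 2     A     2     ALA 0.1609666
#> 3     A     3     ALA 0.1350390

## stopped-flow kinetics and the kinetic isotope effect
trace <- generateSpectroDataset("kinetics",
            list(A1 = 0.05, k1 = 183, A2 = 0.03, k2 = 24.1, offset = 0.4),
            design = seq(0, 0.2, length.out = 400), seed = 103)
fitDoubleExponential(trace$data$time, trace$data$absorbance)
#> Biexponential fit: kFast = 183 /s, kSlow = 24.1 /s (rss 5.55e-32)
kineticIsotopeEffect(183, 24.1)$kie
#> [1] 7.593361
```

The PCA retains two components here because the three state centers span two
directions of between-state variance; the B profile is flat-ish because the
planted within-state modes are delocalized. The pseudotrajectory walks the
three medoids and inserts `ceiling(10 × RMSD)` interpolated frames per leg.
The biexponential fit recovers the generating rate constants exactly on a
noiseless trace, and their ratio 183/24.1 ≈ 7.6 is the "~8" primary kinetic
isotope effect.

The methods vignette (`vignettes/essential-dynamics.Rmd`) documents the
models, parameter choices, numerical conventions and limitations.

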