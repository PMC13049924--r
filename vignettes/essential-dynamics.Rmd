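---
title: "Methods: temperature-differential essential dynamics"
author: "essdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-differential essential dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essdyn)
```

# Scope and model

`essdyn` compares the conformational dynamics of a protein between two
conditions (canonically two temperatures) from MD trajectory ensembles. The
pipeline is: rigid-body alignment → heavy-atom PCA → per-residue essential
dynamics score → density-based state clustering in PC space → medoid
pseudotrajectories → RMSF, hydrogen-bond occupancy and differential
networks, and a substrate-positioning coupling profile. Independent of the
trajectory stages, the package fits the accompanying spectroscopy
(tight-binding titrations, thermal melts, stopped-flow kinetics).

The intended system is a CYP152 peroxygenase with a heme group (residue name
`HEM`, iron atom `FE`) and a fatty-acid substrate (`PLM`, with `CA`/`CB`
naming its Cα and Cβ); both names are configurable, since force fields vary.
Coordinates are Ångström throughout and temperatures are °C.

## Alignment and PCA

Frames are superposed by the Kabsch algorithm (SVD of the cross-covariance;
reflections excluded by the determinant correction) onto a reference frame
over the protein backbone heavy atoms. The reference defaults to the
ensemble's first frame — any frame works, since RMSD-optimal superposition
is invariant to rigid pre-transformations, and the choice is exposed.

PCA is the eigendecomposition of the sample covariance of the flattened
analysis-selection coordinates (all heavy atoms by default), computed by SVD
of the centered frame matrix. Conventions:

* covariance uses the unbiased F−1 denominator;
* eigenvalue ties keep decomposition order; each loading vector's sign is
  fixed so its largest-magnitude component is positive (determinism);
* the retained count K is the smallest k whose cumulative variance fraction
  reaches the target (default 0.75);
* a zero-variance ensemble yields K = 0 with an explicit warning rather
  than a silent K = 1, so degenerate inputs surface;
* pooled (all-condition) centering is the default when ensembles are
  concatenated; per-condition analyses use `subsetCondition()`.

The per-atom essential dynamics score is
B_a = (8π²/3) Σ_{k≤K} λ_k ‖v_{k,a}‖², the temperature-factor convention
applied to the retained essential subspace, and the per-residue score is the
mean of B_a over the residue's analysis atoms (heavy atoms, consistent with
the PCA atom set). With all components retained, B_a reduces to 8π²/3 times
the atom's total positional variance — a trace identity the test suite
checks to 1e-8.

## State clustering

Frames are projected onto the retained components and clustered with
HDBSCAN (Manhattan metric, leaf cluster selection). No installed R package
provides HDBSCAN, so the package implements the standard construction
directly: core distances from the `minSamples`-th nearest neighbour, mutual
reachability distances, a single-linkage hierarchy, condensation at
`minClusterSize`, and selection of the condensed tree's leaves. Points never
absorbed into a selected leaf are noise (label 0).

Parameter defaults, and why:

* `nComponents = min(20, ncol)` leading PCs — keeps the clustering space at
  most 20-dimensional while honouring the retained-variance subspace.
* `minClusterSize = max(5, ceiling(0.10 F))`, `minSamples = minClusterSize`.
  Leaf selection returns the *finest* density-stable clusters, so the size
  floor is the resolution limit: with a 1% floor, a compact 100-frame state
  shatters into density fluctuations (the reference implementation behaves
  identically), while floors from roughly 7% upward recover planted states
  exactly across seeds. The default treats a state holding under a tenth of
  the frames as unresolved at the given sampling depth.
* Degenerate conventions: a point set that never separates at positive
  mutual-reachability distance is one cluster; a root that sheds points but
  never splits into two valid children yields all-noise (the single-cluster
  case must be unambiguous, matching the reference's refusal to select the
  root).

Medoids minimize the mean pairwise superposed RMSD within their cluster
(ties to the lowest frame index; exhaustive search, verified against brute
force). The medoid RMSD matrix uses the structural selection "protein
backbone of the analysis residue range + HEM + PLM, excluding hydrogens" and
superposes each pair before the RMSD — unfitted RMSD would depend on
arbitrary frame placement. Pairwise-superposed RMSD need not satisfy the
triangle inequality; violations are possible and are not an error.

## Pseudotrajectories and RMSF

The medoid ordering is a greedy nearest-neighbour traversal of the RMSD
matrix starting from the medoid of the most-populated cluster (ties to the
lowest cluster id), giving an ordered sequence of states; the start rule is
a package decision, chosen for reproducibility. Each successive
medoid is superposed onto its predecessor (drift reduction), and
`max(minFrames, ceiling(framesPerAngstrom · d))` linearly interpolated
frames are inserted per leg of RMSD d (defaults: 10 frames/Å, minimum 1 for
d > 0, none for d = 0). Morph frames are geometric, not kinetic: outputs
are indexed by frame, never by time.

RMSF is computed per protein residue's Cα after two passes of
superposition onto the iterated mean structure (RMSF is undefined up to
global motion otherwise). Residues without a Cα are excluded with a
warning.

## Hydrogen bonds

Donors are N/O atoms with a hydrogen within 1.2 Å in the reference frame;
acceptors are all N/O. A bond exists when donor–acceptor distance ≤ 3.0 Å
and the D–H–A angle deviates from linearity by ≤ 20° — the distance is
heavy-atom to heavy-atom and the angle cutoff is a *deviation*, following
the convention of the widely used trajectory tools. Occupancy is the
fraction of frames in which a residue pair has at least one satisfied triad;
heme propionates and the substrate carboxylate participate through their O
atoms under the same rules. Occupancy is computed over pseudotrajectory
frames by default, mirroring the state-centric pipeline; whether "centroid
frames" should mean the medoids alone is genuinely ambiguous, so a raw
ensemble (or the medoid frames only) can be passed instead and the choice is
documented rather than asserted. Differential networks report residue pairs
whose occupancy differs by at least 0.25 between conditions (a conservative
quarter-occupancy switch; configurable), tagged by the enriched condition.

## Substrate coupling

The reaction-geometry series holds, per frame, the Fe–Cβ distance and the
Cα–Cβ–Fe angle (vertex Cβ). The combined z-score standardizes each
descriptor to mean 0/variance 1 over the frames of one condition and
averages them with equal weights. Both choices are open in the source
material and are therefore package decisions kept behind configuration:
weights can be changed, and standardization is deliberately per-condition —
pooling would fold the between-condition contrast into the score itself.
The coupling profile is the Pearson correlation between each residue's
per-frame Cα displacement magnitude (from its ensemble-mean position, on an
aligned ensemble) and the z series; a per-residue heavy-atom RMSD statistic
is available as an alternative.

## Surface composition

SASA uses Shrake–Rupley quadrature on a deterministic golden-spiral point
set (default 960 points, probe 1.4 Å) with standard per-element van der
Waals radii (overridable). A residue is "surface" when its summed SASA
exceeds 2.5 Å², the convention of the common surface-residue scripts. The
census counts R, K, H (positives) and D, E (negatives); histidine is
reported separately because its charge is pH-dependent.

## Spectroscopy fits

All fitters use bounded Levenberg–Marquardt least squares with three
data-driven starts (biexponential fits are initialization-sensitive) and
report Jacobian-based standard errors:

* Morrison tight-binding: ΔA(S) = ΔA_max[(E+S+K_d) − √((E+S+K_d)² − 4ES)]/2E,
  the correct isotherm when enzyme and ligand concentrations are comparable
  to K_d; it reduces to the hyperbola when E ≪ K_d.
* Boltzmann melt: signal(T) = lower + (upper−lower)/(1+exp((T_m−T)/slope)).
* Two-summed exponentials: A(t) = offset + A₁e^(−k₁t) + A₂e^(−k₂t), rates
  reported fast-first; a shared offset and decay-signed amplitudes are the
  package's stated convention (the literature rarely writes it out), and
  near-equal rates trigger a rate-collapse warning. Time zero is the first
  sample; instrument dead time is not modelled.
* KIE = k_H/k_D, reported raw and rounded.

## What the synthetic generators emulate — and what they do not

Every generator is seed-deterministic and returns its planted truth, so
recovery tests never re-derive truth from data:

* `generateModeTrajectory` plants orthonormal covariance modes with strictly
  decreasing amplitudes (so PC order is unambiguous) plus isotropic jitter.
* `generateMetastableEnsemble` plants K equidistant state centers; its
  within-state fluctuation is low-rank (three shared collective modes plus
  10% isotropic jitter) because collective motions dominate real trajectory
  covariance — purely isotropic noise would let uninformative dimensions
  swamp the cumulative-variance target, which no real trajectory does.
  `overlapFactor` interpolates between well-separated compact clusters and
  fully collapsed ones.
* `generateHbondScenario` switches planted triads on/off per frame by
  per-condition occupancy, with bound geometry satisfying the cutoffs and
  unbound geometry violating at least one.
* `generateCoupledSubstrateTrajectory` drives both geometry descriptors and
  one residue's displacement magnitude from a shared latent series; frames
  come in ± pairs so the displacement magnitude is exactly linear in the
  latent and the asymptotic Pearson correlation equals the planted ρ
  (exactly 1 at ρ = 1 with zero noise).
* `generateSpectroDataset` adds Gaussian noise to the named closed-form
  models.

These generators deliberately omit: solvent and thermostat physics, bonded
geometry and sterics, anharmonic and multi-basin within-state dynamics,
correlated H-bond switching, and kinetic (time-ordered) structure. A passing
suite therefore certifies the *estimators* — that PCA recovers planted
spectra, clustering recovers planted states, occupancies and couplings
converge to planted values, fits recover generating parameters — not that
any particular biological conclusion holds for real trajectories.

## Problem sizes and numerical conventions

The test and acceptance workloads use toy chains of 4–10 residues (20–70
atoms), ensembles of 50–4000 frames, 200 frames per condition for occupancy
statistics, and 2000 frames for coupling convergence — sizes chosen so the
full suite runs in seconds while the law-of-large-numbers checks still bite.
Key tolerances: PCA against dense eigendecomposition, 1e-8; morph
interpolation convexity, 1e-12; standardization identities, 1e-9; medoid
and traversal oracles, exact. Medoids at numerically identical RMSD
(< 1e-9 Å) are treated as coincident, receiving no interpolated frames.

## Known limitations

* PDB is the only trajectory interchange format built in; binary formats
  (XTC/DCD) would slot behind the same reader contract but are not shipped.
* HDBSCAN is exact but O(F²) in memory and time — appropriate for the
  10³–10⁴-frame analyses the pipeline targets, not for millions of frames.
* The hydrogen-bond module requires explicit hydrogens (donor assignment is
  geometric); structures without hydrogens yield acceptor-only catalogs and
  a warning.
* The charged-residue census reads residue names; protonation-state nuance
  (HID/HIE/HSP variants, terminal charges) is out of scope.
* The pipeline quantifies *geometry*; free energies, kinetics between
  states, and causality of the coupling profile are outside its claims.
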