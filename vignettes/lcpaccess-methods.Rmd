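---
title: "Methods: substrate access and binding analysis for latex clearing protein"
author: "lcpaccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substrate access and binding analysis for latex clearing protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcpaccess)
```

## Scope and scientific setting

Latex clearing protein (Lcp) is a heme *b* enzyme that cleaves the C=C
bonds of cis-1,4-polyisoprene (natural rubber) into oligoisoprenoids of a
characteristic size distribution. Its active site is buried in a
globin-like fold, so the catalytically relevant questions are geometric:
which tunnels admit a polymer chain, which pockets near the heme can hold
it, which of its double bonds spend time close enough to the heme-bound
distal O₂ to react, and which energy terms hold the complex together.
This package implements that analysis chain — tunnel and pocket
detection, trajectory metrics, contact and conformation profiling,
near-attack-conformation (NAC) cleavage prediction, and linear
interaction energy (LIE) decomposition — together with synthetic
generators that plant analytically known truths so each stage can be
validated end to end.

Protein structures are read from PDB (altloc duplicates resolved to the
highest-occupancy record, ties by label order; HETATM cofactors
retained), trajectories from multi-MODEL PDB or XYZ. In typical use the
crystal structure is reduced to one monomer (`read_pdb(chain_filter =
"A")`) and co-crystallized species other than heme (waters, imidazole,
diols) are removed with `strip_species()`, since the dimer interface is
far from the active site.

## The substrate model

`build_polyisoprene(n)` constructs a hydrogen-capped cis-1,4-polyisoprene
n-mer with idealized internal coordinates (C–C 1.54 Å, C=C 1.34 Å, sp²
angles 120°, sp³ angles 109.5°, C–H 1.09 Å), built atom by atom with the
standard NeRF placement. At n = 10 this gives the C₅₀H₈₂ model used in
docking-scale studies. Double bonds are numbered 1..n from the dimethyl
terminus (the chain end R–CH=C(CH₃)₂), which fixes the bookkeeping for
cleavage sites. All single-bond backbone torsions default to trans
(180°); we verified numerically that the resulting planar chain is
straight and clash-free up to at least n = 20 — the in-plane turns of the
cis kink cancel within each repeat — so no skew pattern is needed for the
extended build. Individual torsions can be overridden to build folded
test poses.

Chain width is defined as the maximum heavy-atom extent perpendicular to
the chain's principal axis plus a 1.1 Å hydrogen allowance. The exact
width convention in the literature is estimated from carbon–carbon
contact distances plus a C–H increment; since the full procedure is
underdetermined, we chose the perpendicular-extent definition because it
is coordinate-frame independent and trivially testable against a
brute-force pairwise maximum.

Oxidative cleavage at bond k of an n-mer destroys that bond's C=C and
yields fragments with k−1 and n−k intact double bonds. This (k−1, n−k)
rule reproduces the 4- and 5-unit oligomers expected for cleavage at the
central bonds of the 10-mer and conserves total intact bonds (n−1).

## Tunnel detection

`find_tunnels()` discretizes space on a regular grid (default spacing
0.4 Å; fixtures in the test-suite use 0.5 Å) storing per voxel the free
radius — distance to the nearest atom surface, negative inside an atom.
Atoms are exact spheres of their van der Waals radius; we do not
reproduce the multi-sphere atom approximation some tunnel tools use for
speed, since exact spheres are strictly more accurate and simpler to
test. Two bundled, editable radius tables are provided (Bondi all-atom,
the default, and a united-atom set for hydrogen-free geometry); the
choice is a documented configuration because published tunnel
calculations rarely state their radius set.

The search works as follows:

1. **Bulk region.** Voxels with free radius ≥ shell_radius (3 Å)
   connected to the grid boundary form the outer solvent; this region is
   dilated shell_depth (4 Å) inward. The dilation is morphological
   (Chebyshev steps on the 26-neighbourhood), which can move the tunnel
   termination boundary by about one voxel relative to exact Euclidean
   erosion — well below the grid-level accuracy of the reported lengths.
2. **Start voxel.** The user's start point (e.g. the heme iron) is
   snapped to the highest-free-radius voxel within 3 Å, which avoids
   starting inside an atom without a separate optimization step.
3. **Dijkstra search.** On the 26-connected graph of accessible voxels,
   edge cost is ds·½(1/r_a² + 1/r_b²) with r floored at ε = 0.05 Å to
   avoid blow-up at the prune boundary and capped at 6 Å (values above
   the cap cannot affect tunnel ranking since such regions are already
   bulk-like; the cap keeps the field computation local and fast). Paths
   terminate at the first bulk voxel; distinct bulk-contact patches give
   distinct tunnels, and exits whose best voxels lie within shell_radius
   of each other are merged keeping the cheaper path.
4. **Metrics and pruning.** Each path reports its radius profile,
   bottleneck (minimum free radius along the centerline), length,
   curvature = length / straight start-to-exit distance (≥ 1), and
   throughput = exp(−cost·r²_ref/L_straight) with r_ref = 1 Å, a
   dimensionless score in (0, 1] that increases with width and decreases
   with length and curvature. Paths with bottleneck < min_probe (0.9 Å)
   are discarded. The throughput formula is this package's own
   normalization: published tunnel tools do not document their exact
   expression, so tests and comparisons rely on ordering and
   monotonicity, never on absolute throughput values.

Snapshot tunnels are clustered with average-linkage hierarchical
clustering (`hclust`, Murtagh's algorithm) on the mean Euclidean distance
between corresponding equal-arclength resampled centerline points, cut at
threshold 3.5. Clusters report average/sd/max bottleneck, length,
curvature, throughput, and two ranking quantities side by side: priority
(sum of member throughputs over all snapshots divided by the snapshot
count, so absent snapshots contribute zero) and occurrence (fraction of
snapshots with at least one member). Both definitions appear in the
literature describing cluster ranking; we compute both and make no claim
about which underlies any particular published percentage.

Validation uses wall-atom channel fixtures with analytic clearance: the
recovered bottleneck must match the planted clearance within one grid
spacing, sub-probe channels must vanish, wider channels must outrank
narrower ones, and the Dijkstra cost must not exceed that of any sampled
alternative monotone lattice path (randomized optimality oracle).
Halving the grid spacing must change the recovered bottleneck by less
than the coarser spacing (convergence).

## Pocket detection

An alpha sphere is a sphere tangent to four atoms and empty of all
others — a Voronoi vertex of the heavy-atom centers, with radius measured
to atom centers (the convention implied by the standard 3.4–6.2 Å
bounds). Because no 3-D computational-geometry backend is available to
the package, vertices are found by enumerating candidate quadruples from
each atom's k = 16 nearest neighbours, computing circumcenters in closed
form, and keeping exactly those that satisfy the empty-circumsphere
(Delaunay) condition against *every* atom. The validity check is exact;
the neighbourhood size only bounds the enumeration, and tests compare
against brute-force enumeration over all quadruples on small clouds.
Spheres whose centers fall outside the convex hull of the structure are
discarded; the hull test (and the burial depth used for conformation
classification) uses a sampled support function over 256 quasi-uniform
directions, an approximation that is exact in the dense-direction limit
and accurate to well under 0.1 Å for protein-sized clouds.

Pockets are single-linkage clusters of sphere centers at a 1.8 Å cutoff
(the linkage method is standard for this task; the cutoff itself is a
package default, exposed in the API, because published values are not
stated), discarding clusters with fewer than 15 spheres. Volumes are
Monte-Carlo estimates over the sphere union's bounding box, counting
samples inside at least one alpha sphere and outside every atom — i.e.
solvent-accessible void volume — with binomial standard error and
bit-reproducibility at fixed seed. Hydrophobicity is the fraction of
apolar (C, S by element) atoms lining the spheres within 2.2 Å of a
sphere surface; it is a proxy score on this package's own scale and is
never compared numerically to external tools' hydrophobicity scores, nor
are absolute pocket volumes from other software used as oracles. Pocket
ranking is by sphere count. Pockets can be filtered by centroid proximity
to the heme (`pockets_near`) and tracked across trajectory frames by
centroid matching within 3 Å.

## Trajectory metrics

Superposition uses the closed-form Kabsch fit (proper rotation via SVD).
RMSF and PCA superpose all frames on the ensemble mean, iterated twice —
standard essential-dynamics practice; the reference literature does not
state its superposition target, and the choice only affects results at
the sub-percent level for well-converged ensembles. RMSF is reported per
residue via the C-alpha atom when present. PCA pools one or more
trajectories (frames tagged by source, so bound/unbound or open/closed
sets can be projected separately), eigen-decomposes the positional
covariance of the selected atoms — typically backbone N, CA, C, O — and
fixes each mode's sign so its largest component is positive; projections
and eigenvalues satisfy the trace identity (Σλ = total positional
variance). Porcupine output scales each mode by √λ and suppresses
vectors shorter than 2 Å, mirroring the usual "motions longer than 2 Å"
drawing rule.

Two caveats matter when validating against planted truths, and both are
consequences of superposition being blind to rigid-body motion. First,
fitting removes six degrees of freedom, shrinking recovered RMSF by the
factor √(1 − 6/3N) for N fitted atoms; recovery tests therefore use
enough probe atoms (N = 60) that the bias is under 2 %. Second, a planted
two-state displacement must be orthogonal to the rigid-body subspace for
its direction to be recoverable by PCA;
`orthogonalize_displacement()` projects out net translation and
infinitesimal rotation and is applied when constructing such fixtures.

The radial distribution function histograms pair distances normalized by
ideal-shell volume and bulk density. With a periodic box the
minimum-image convention is applied and density defaults to the mean box
density — without imaging, a finite box depresses g(r) at mid range even
for an ideal gas. For non-periodic input a density override is required
rather than guessed. Trajectory smoothing is a centered moving average
(default window 5 frames, matching common visualization practice) with
symmetric window shrinkage at the ends, leaving the frame count
unchanged; its frequency response is the analytic Dirichlet kernel, which
the tests check against a planted sinusoid.

## Binding analyses

**Contacts.** A residue is in contact in a frame when its minimum
heavy-atom distance to the ligand is ≤ 5 Å; fractions below the 4.5 %
report threshold are suppressed from reports but retained internally.
Profiles from poses of one conformational class can be averaged with the
threshold applied *after* averaging (`average_contact_profiles`), so
consistently present but individually sub-threshold residues survive;
this ordering is stated in the output because the alternative
(threshold-then-average) is also computable.

**Conformations.** A terminus is "in the pocket" within 2.5 Å of an
alpha-sphere center and "at the surface" when its burial depth (inward
distance from the protein convex hull) is ≤ 3 Å; extended = exactly one
terminus in the pocket and the other at the surface, folded = both
termini at the surface with the ligand centroid within 12 Å of the heme,
else extended-like. The published definitions are qualitative; the three
numeric thresholds here are calibration constants exposed as arguments.

**NAC profiling.** For every frame and double bond the distance to the
distal O₂ is the minimum over the bond's two carbons (a midpoint mode is
provided for sensitivity analysis, since per-carbon tabulations leave the
histogram convention open); bond k's NAC count is the number of frames
strictly below 4 Å, the strict reading of "below 4 Å", with the threshold
configurable for the softer "around 4 Å" reading. The fragment spectrum
assigns each event at bond k to sizes k−1 and n−k and normalizes; total
unnormalized mass is exactly twice the event count.

**LIE.** Per frame, over all ligand–environment pairs: E_vdW =
Σ ε_ij[(R_min,ij/r)¹² − 2(R_min,ij/r)⁶] with ε_ij = √(ε_i ε_j) and
R_min,ij = R_min,i/2 + R_min,j/2, and E_ele = k_e Σ q_i q_j/r with k_e =
332.0636 kcal·Å·mol⁻¹·e⁻². All pairs, no cutoff, vacuum dielectric:
this makes the computation exactly reproducible and checkable against a
naive double-loop oracle, whereas cutoff/periodic schemes would import
engine-specific choices. The percentage split reported for the two terms
is of absolute ensemble means, 100·|Ē_vdW|/(|Ē_vdW|+|Ē_ele|), stated in
the output metadata since percentage bases are often left undefined.
Implicit-solvent binding energies (MM/GBSA-style) are intentionally out
of scope; the report accepts externally supplied per-frame binding
energies instead.

## Synthetic data: what it emulates and what it does not

Each generator produces valid structures/trajectories in the same
PDB/XYZ formats the pipeline reads, is deterministic at fixed seed, and
records every planted truth in a manifest (`manifest()`,
`write_manifest()`); analysis tests read only the manifest.

* `make_channel()`: double-layer wall-atom shells around a sealed cavity
  with one or two cylindrical exits of analytic clearance — emulates the
  enclosed-cavity-plus-tunnel topology of a buried active site, not
  protein surface roughness or gating.
* `make_cavity()`: a jittered spherical shell with a known inscribed void
  — emulates a binding pocket of controlled alpha-sphere radius.
* `make_binding_trajectory()`: probe residues approach the ligand on
  deterministic schedules realizing exact contact fractions; planned
  double-bond carbons orbit a fixed distal-O₂ pseudo-atom realizing exact
  NAC counts; everything else receives optional Gaussian jitter
  (scheduled atoms are jitter-free so the planted counts stay exact;
  deterministic schedules support exact-recovery tests and stochastic
  variants support statistical-bound tests). Geometrically the zones are
  deliberately separated, so this fixture validates bookkeeping and
  thresholds, not physical binding geometry.
* `make_two_state_trajectory()`: reference ± displacement with Gaussian
  noise and Bernoulli state assignment — emulates an open/closed
  conformational equilibrium at PCA level.
* `make_uniform_gas()`: an ideal gas in a periodic box for RDF
  normalization checks.

None of the generators emulate force-field dynamics, solvent structure,
correlated motions or realistic contact geometry; a pipeline that passes
all planted-truth tests is verified as *correctly measuring* the planted
quantities, which is a statement about the analysis code, not about any
real protein.

## Problem sizes, tolerances and limitations

The validation suite runs at desk scale by choice: channel fixtures use
0.5 Å grids over ~30 Å boxes (the API default spacing is 0.4 Å),
RMSF/PCA recovery uses 400–2000 frames, the gas RDF uses 800 atoms × 30
frames, and Monte-Carlo volumes use 10⁵–10⁶ samples. Statistical
assertions use bounds derived from the construction (binomial/3-sigma,
±5 % for RMSF at 2000 frames, ±0.05 for the gas RDF); exact assertions
(contact fractions, NAC counts, LIE vs oracle at 10⁻⁹ relative) rely on
the deterministic schedules described above.

Known limitations: the tunnel backend is a grid method — bottlenecks are
accurate to the grid spacing and very narrow (sub-spacing) channels may
not be grid-connected; throughput is a package-specific normalization;
the Voronoi-vertex enumeration is k-neighbourhood-bounded (exactness
verified only per candidate); the convex hull is direction-sampled; RDF
supports orthorhombic boxes only; no mmCIF or binary trajectory formats
(DCD/XTC) are read; and protonation, docking and MD propagation are
explicitly out of scope — poses and trajectories are consumed as input.
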