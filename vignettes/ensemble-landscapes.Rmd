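---
title: "Characterising disordered-domain ensembles: descriptors, clustering, free-energy landscapes and folding dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising disordered-domain ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enscape)
```

## Scope and model

Intrinsically disordered protein regions (IDRs) do not fold into a single
structure: a molecular-dynamics (MD) simulation of such a region produces a
heterogeneous *conformational ensemble*, and any single conformation is close
to meaningless on its own. `enscape` implements the statistical machinery to
characterise such ensembles, developed around the working example of an
80-residue kinase-insert domain (KID, residues numbered 689-768, carrying
phosphotyrosines Y703/Y721/Y730/Y747) simulated in replicated trajectories
forming three groups (4 + 2 + 2: a cleaved polypeptide, the domain in its
native kinase context, and a cleaved polypeptide with restrained termini).

The package operates on `conf_ensemble` objects: ordered frames of Cartesian
coordinates (Angstrom) over a fixed atom topology, read from multi-model PDB
files or generated synthetically. The analysis stages mirror the standard MD
post-processing sequence:

1. **Superposition** (`superpose`): each frame is least-squares fitted
   (Kabsch algorithm, proper rotations only) to a reference conformation on a
   selection, by default the C-alpha atoms and frame 1 — removing rigid-body
   motion so that every later descriptor reflects internal change only.
   Fitting happens *before* replica concatenation; by default all replicas
   are fitted to the same reference (frame 1 of the first replica), which is
   configurable because a per-replica reference is equally defensible when
   replicas start from one structure.
2. **Equilibration removal** (`drop_equilibration`): the leading
   not-yet-equilibrated frames are discarded before statistics.
3. **Descriptors**: RMSD to the initial model, per-residue RMSF, radius of
   gyration, solvent-accessible surface area, inter-residue distance
   geometry, histograms.
4. **Secondary structure** (`assign_dssp`): per-frame 8-state assignment
   from backbone hydrogen-bond energies; helical fraction and helix-segment
   lifetimes.
5. **Interactions**: dynamic contact maps, hydrogen bonds, hydrophobic
   contacts, with occurrence statistics and anchor-segment filtering.
6. **Ensemble clustering** (`cluster_ensemble`): the reference-harvesting
   RMSD clustering described below.
7. **Free-energy landscapes** (`free_energy_landscape`, `find_wells`):
   relative Gibbs free energy over reaction-coordinate pairs via
   k-nearest-neighbour density estimation.
8. **Folding dynamics** (`transition_matrices`, `fisher_rao_distance`,
   `classical_mds`): per-residue Markov models of secondary-structure
   dynamics compared across replicas.

`run_pipeline()` binds the stages together, writes every table as TSV and a
JSON manifest of parameters and seeds; rerunning with the same inputs is
byte-identical. The package's functions are the intended interface — the
pipeline is a convenience wrapper, not a separate tool.

## Descriptors and their conventions

**RMSD / RMSF.** Both are computed on C-alpha atoms of the superposed
ensemble. RMSD is measured against the initial model (frame 1) — the
convention for monitoring global stability. RMSF offers two modes: the
standard fluctuation about the time-averaged position (`about_mean`,
default), and fluctuation about the initial model (`about_reference`).
Protocols in the literature state the initial model as the RMSF reference
even though the mean-referenced quantity is the conventional fluctuation;
rather than guessing intent, both are provided and the default is the
standard statistical definition.

**Radius of gyration.** `Rg = sqrt(sum_i m_i r_i^2 / sum_i m_i)` with `r_i`
the distance from the selection's centre of mass. Two modes: mass-weighted
over all atoms (the physical definition) and unweighted over C-alpha atoms
(default), which is the variant used as a landscape reaction coordinate.
Compactness classes follow the reported mean-value bins — compact
11.2-11.6 A, semi-compact 11.7-12.2 A, loose 12.3-12.8 A. The printed bins
leave 0.1 A gaps; values falling in a gap are assigned to the nearer bin by
midpoint so the classification is total, since refusing valid Rg values
between bins would be worse than an arbitrary-but-documented rounding rule.

**SASA.** Shrake-Rupley sphere sampling with probe radius 1.4 A (water) and
960 test points per atom by default (a Fibonacci sphere lattice; 960 points
give isolated-sphere areas within a fraction of a percent of `4*pi*r^2`).
Van der Waals radii: C 1.7, N 1.55, O 1.52, S 1.8, H 1.2 A. Absolute SASA
values differ by a few percent between algorithms (e.g. versus LCPO-based
codes); since SASA serves as a *relative* reaction coordinate this is
immaterial — free-energy differences are invariant under the per-axis
standardisation described below.

## Secondary structure

`assign_dssp` implements the classic backbone hydrogen-bond-energy
assignment: the electrostatic energy of a donor amide N-H of residue *i*
and acceptor carbonyl C=O of residue *j* is

    E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)  kcal/mol

with a bond when `E < -0.5` kcal/mol. Two consecutive n-turns define
helices (3_10 `G`: i to i+3; alpha `H`: i to i+4; pi `I`: i to i+5), bridge
patterns give `E`/`B`, remaining turn residues `T`, C-alpha chain kinks
above 70 degrees `S`, otherwise coil `C`, with priority
H > E/B > G > I > T > S. Amide hydrogens are reconstructed 1.01 A from N
along the preceding C=O direction when absent, since most ensembles (and
the synthetic builder's strict backbone) carry no explicit hydrogens; the
first residue and prolines donate nothing. Exact parity with any particular
`dssp` executable is not promised — correctness is pinned instead to the
hydrogen-bond energy pattern itself, which the tests verify directly on
ideal-geometry helices.

The helical fraction Hfp (per-frame percentage of residues in `{H, G}`)
excludes the pi-helix state by default because the systems of interest
alternate between alpha- and 3_10-helices; the state set is an argument.
Helix segments are maximal per-frame `{H,G}` runs of at least 3 residues,
merged across frames when their residue spans overlap, labelled H1..Hn from
the N-terminus, with lifetime the fraction of frames in which the merged
segment appears. Turn/bend states are reported separately rather than
folded into helix lifetimes.

## Interactions

Contact maps count frames with C-alpha pairs strictly closer than 10 A,
normalised to frequencies. Sequence neighbours `|i-j| <= 2` are masked by
default: the covalent band is trivially in contact and would dominate
occurrence statistics; `exclude_neighbours = 0` restores the strict map.
Hydrogen bonds use the geometric criteria of heavy-atom (N/O/S) distance
<= 3.6 A and donor-H-acceptor angle >= 120 degrees measured at the
hydrogen; records based on reconstructed hydrogens are flagged. Backbone
i,i+3/i+4 bonds — the helix-internal ones — are excluded from the tertiary
interaction report by default (toggleable), and hydrophobic contacts
require side-chain heavy atoms of two hydrophobic residues (A, V, L, I, P,
F, M, W) within 4 A. `segment_contacts` filters any record set to
interactions anchored in given residue spans (e.g. low-RMSF "pseudo-rigid"
segments) with occurrence strictly above 80%.

All-pairs distance evaluation is used directly (the systems are small);
the contract that results equal a brute-force oracle is part of the test
suite rather than an optimised spatial index with an equivalence proof.

## Ensemble-based clustering

The clustering is deliberately the simple reference-harvesting procedure,
not k-means or hierarchical clustering: (i) draw a reference frame
uniformly at random from the remaining conformations, remove everything
within C-alpha RMSD `r` of it (including itself), repeat until no frames
remain — leaving references pairwise at least `r` apart; (ii) assign every
frame to its nearest reference, ties to the earlier-harvested reference.
The RNG protocol is fixed (one `sample.int` draw per harvest, frames kept
in increasing order) precisely so an independent implementation can replay
it draw-for-draw; the seed is recorded in the output. A conformation
removed in step (i) can never become a reference later — the literal
reading of the procedure. Typical cutoffs for disordered domains are
r = 3-5 A, and the cluster count is non-increasing in `r`.

## Free-energy landscapes

For two reaction coordinates `(R1, R2)` the relative Gibbs free energy is

    deltaG(R1, R2) = -kB * T * ln( P(R1, R2) / Pmax )

with `kB = 0.0019872041 kcal/(mol K)` and `T = 310 K` by default (the
simulation temperature). The probability density is estimated with a
k-nearest-neighbour scheme: at an evaluation point, `P = k / (N pi d_k^2)`
where `d_k` is the distance to the k-th nearest of the `N` frames. Choices
made here, since the method leaves them open:

* **k**: `ceiling(sqrt(N))` by default — the standard bias/variance
  compromise for kNN density estimation, validated in the tests against
  uniform and Gaussian closed forms.
* **Standardisation**: each axis is z-scored before density estimation
  because the coordinates carry incommensurate units (A, %, A^2); reported
  grids carry both scales. Free-energy *differences* are invariant under
  any affine rescaling of a raw coordinate, which the tests assert.
* **Evaluation**: on a regular grid (default 100 x 100 over the bounding
  box padded 5%) for plottable output; frame-level basin membership uses
  the frames' own standardised coordinates mapped to grid cells. Grid
  nodes farther than two grid spacings from every sample are undefined —
  extrapolated free energies there would be pure estimator artifact.
* **Wells**: basins are grown by flooding defined cells in order of
  increasing free energy (8-neighbour connectivity). When a basin first
  meets a deeper one, it is merged if its persistence (saddle minus its
  minimum) is below `min_depth = 0.5` kcal/mol — the literature reports
  well counts but no criterion, so the threshold is exposed in the
  configuration. Basins holding under 1% of the sample mass are discarded:
  disconnected islands formed by a few stray tail frames have no saddle to
  a deeper basin, so the persistence rule cannot touch them, yet they are
  sampling artifacts rather than metastable states. A caveat follows from
  the estimator itself: a well whose true barrier sits within the kNN
  noise of `min_depth` is genuinely ambiguous and may resolve either way
  between samples; well counts should be read with the barrier scale in
  mind.

The landscapes are built for the pairs (RMSD, Rg), (Hfp, Rg) and
(SASA, Rg) in the pipeline. `deepest_well_members` extracts the frames of
the global minimum's basin and a representative conformation (the frame
nearest the minimum in standardised coordinates).

## Folding dynamics across replicas

For each residue the sequence of 8-state secondary-structure labels is
modelled as a first-order Markov chain: transition counts between
consecutive frames (lag configurable — assignments made every 10 versus 20
ps give different chains, so the lag is a parameter, not a constant),
smoothed with a Jeffreys pseudo-count `alpha = 0.5` so that rarely-visited
rows remain proper distributions, then row-normalised. Replicas are
compared by the Fisher-Rao metric: for categorical distributions the
geodesic distance is `2 * acos( sum_s sqrt(p_s q_s) )` — twice the
Bhattacharyya angle, bounded by pi. The method literature does not fix how
row distances aggregate into one number per replica pair; the package's
documented choice is an occupancy-weighted mean over the 8 rows of each
residue (rows never visited in either replica carry no information and are
skipped) followed by a uniform mean over residues. Alternatives (uniform
row weights, stationary-distribution weights) would also be defensible;
occupancy weighting was chosen because smoothing noise in empty rows would
otherwise dominate the distance.

The replica-by-replica distance matrix is embedded in 2D by classical
(Torgerson) multidimensional scaling — double centering plus
eigendecomposition, deterministic, with negative eigenvalues clipped and a
relative stress reported — rather than iterative SMACOF, matching the "as
isometric as possible" goal with a reproducible algorithm.

## The synthetic-data generators

Real trajectories of the original study are not redistributable, so the
package ships generators that emulate their statistical structure and carry
ground truth for every downstream estimator:

* `simulate_ss_chain`: independent per-residue 8-state chains.
  `ss_mixing_matrix(pi, rho)` builds `P = rho I + (1 - rho) 1 pi'`, whose
  stationary law is exactly `pi` — so helical content and transition
  probabilities are known by construction. Per-residue independence is a
  deliberate simplification: it suffices for testing estimators of
  per-residue chains, while spatial coupling between residues is out of
  scope, so pipeline results on synthetic tracks say nothing about
  cooperative folding in real data.
* `build_peptide_ensemble`: ideal-geometry backbones (internal-coordinate
  chain extension; alpha-helix phi/psi = -57/-47 degrees, 3_10 -49/-26,
  strand -135/135, coil sampled from phi ~ N(-120, 30), psi ~ N(130, 30)
  degrees — a broad coil basin that produces non-helical assignments
  without sheet partners), amide H and C-beta by ideal geometry, optional
  Gaussian coordinate jitter. The builder realises prescribed
  secondary-structure tracks well enough that the assignment recovers over
  90% of interior helical states at zero jitter, which is what the
  round-trip tests rely on.
* `gaussian_mixture_samples` / `multi_basin_ensemble`: labelled 2D mixtures
  for landscape validation, and template-plus-jitter coordinate ensembles
  reproducing the bimodal RMSD structure (main peaks separated by a few A)
  seen in disordered-domain replicas.
* `kid_replica_tracks`: the default 80-residue fixture, numbered 689-768
  with F689/D768 termini and the four tyrosines, 8 replicas in groups
  4 + 2 + 2. Group helix profiles target the reported helical-content
  ranges — about 44-56% for the unconstrained cleaved group, 25-30% for
  the domain group, 30-35% for the restrained group — with a long-lived
  all-alpha H1 and shorter transient helices splitting mass between alpha
  and 3_10 states. Chain persistence `rho = 0.9` makes states last ~10
  frames, a plausible dwell relative to the analysis stride.

What the generators do *not* emulate: excluded volume, side-chain packing,
solvent, cooperative transitions, and the 1-3 A basin separations of real
RMSD distributions arising from continuous structural change rather than
template hopping. Passing tests therefore demonstrate estimator
correctness, not force-field-level realism.

## Problem sizes and determinism

The test-suite and acceptance fixtures use 20,000-50,000 points for
landscape and Markov validation (where closed-form tolerances need that
much data) and tens of frames times 80 residues for structural round
trips — sizes chosen so the full suite completes in a couple of minutes on
one core while keeping Monte-Carlo tolerances honest. Every stochastic
step takes an explicit seed, and every generator is a pure function of its
spec and seed; the pipeline manifest records parameters and seeds so any
output can be regenerated exactly.

## Known limitations

* No binary trajectory formats (DCD/XTC/NetCDF): multi-model PDB only.
* The structure assignment targets helix/coil systems; the bridge (`E`/`B`)
  logic is implemented but unexercised by sheet-rich topologies, and
  polyproline-II is not detected.
* The Fisher-Rao aggregation is one documented choice among several
  reasonable ones; distances are comparable within a study, not across
  different aggregation conventions.
* kNN landscapes inherit the estimator's bias at sharp density features;
  well depths below ~0.1 kcal/mol are not meaningful at the default
  sample sizes.
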