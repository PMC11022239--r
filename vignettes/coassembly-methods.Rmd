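---
title: "Methods: contact-based cluster analysis of peptide-drug-ion co-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-based cluster analysis of peptide-drug-ion co-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coassembly)
```

## The analysis model

`coassembly` quantifies the joint aggregation of cyclic dihistidine
peptides, small-molecule drugs and ions (Zn^2+^, NO~3~^-^, and Cl^-^ for
positively charged drugs) in snapshots of a cubic periodic box. The
primitive is the *contact*: two components (molecules or ions) interact in
a snapshot when any pair of their atoms lies strictly closer than a cutoff
`d_c` under the minimum-image convention. The default `d_c = 3.5` Å is the
conventional heavy-atom interaction distance for coordination and
hydrogen-bond-range contacts. A *cluster* is a connected component of the
resulting contact graph with at least two members; a lone molecule is not
an assembly. The cluster *size* counts member components, not atoms. All
sub-cutoff pairs are edges: no nearest-neighbor prioritization is applied,
so a zinc bridging two peptides contributes all three pairwise contacts
explicitly.

Cluster-level statistics follow directly from this definition:

* **Composition percentages** per component kind (peptide, drug, Zn^2+^,
  NO~3~^-^, Cl^-^), summing to 100.
* **Encapsulation**: the probability that a cluster carries zero, at least
  one, or at least two drugs, and the percentage of all drug copies in the
  system residing in one cluster.
* **Count ratios** of drugs and Zn^2+^ to peptides; undefined (returned as
  `NA` with a warning) when a cluster has no peptide.
* **Radius of gyration** of the unwrapped cluster, with uniform atom
  weights: the pseudo-atoms of the coarse templates carry no masses, so a
  mass-weighted variant (as computed by common trajectory tools) is
  deliberately not used.
* **SASA burial**: Shrake-Rupley solvent-accessible surface area with a
  deterministic Fibonacci point lattice. The *ratio* for a component is its
  SASA computed against all atoms of its cluster divided by its SASA in
  isolation, as a percentage. The denominator convention ("total surface
  area per component") is genuinely ambiguous; taking the isolated-component
  SASA makes 100% mean "fully exposed" and 0% "fully buried", which is the
  interpretation used throughout. The probe radius defaults to 2.6 Å, a
  configurable stand-in for an isopropanol-sized solvent probe; no
  authoritative printed value exists for it.

## Periodic boundaries

Contacts use the minimum image in a cubic box of edge `L`; the cutoff must
satisfy `d_c < L/2`. Cluster-level geometry (Rg, SASA) needs contiguous
coordinates, so clusters are unwrapped by breadth-first traversal of their
contact edges: each newly visited component is translated by the lattice
vector realizing the minimum-image distance to its placed neighbor, after
first making every molecule internally contiguous (wrapped storage can
split a molecule across opposite box faces). Unwrapping verifies that every
edge's plain Euclidean distance then equals its minimum-image distance and
refuses clusters that percolate the box, where no consistent unwrapping
exists.

## Interaction motifs

Beyond pair contacts, the analysis counts *mediated triplets*: a component
`m` simultaneously in contact with two peptide/drug flanks. Labels are
written flank-middle-flank with flanks ordered P before D, giving twelve
canonical patterns - six molecule-mediated (PPP, PDP, PPD, PDD, DPD, DDD)
and six ion-mediated (PZP, PZD, DZD, PNP, PND, DND); DNP is canonicalized
to PND. Flanks are not required to avoid contacting each other, because
concurrent interactions are counted explicitly. Per-cluster probabilities
normalize over all triplets observed in the cluster and ensembles average
clusters with equal weight; a per-mediator-kind normalization is available
as an option since the normalization convention is not uniquely determined
by the problem. Pairwise interaction probabilities exclude the repulsive
like-ion pairs Zn^2+^-Zn^2+^ and NO~3~^-^-NO~3~^-^. The per-kind mediation
probability is the fraction of components of that kind with at least two
peptide/drug neighbors, averaged over clusters containing the kind.

Chemical-group contact profiles decompose peptide/drug contacts to named
groups (peptide: two imidazoles and the diketopiperazine ring; drug:
charged, polar and hydrophobic groups by default). A group contacts a
partner (an ion kind or a group of another molecule) when any of its atoms
is within `d_c` of any partner atom; per source group, partner counts are
normalized to probabilities. The default grouping is a coarse placeholder
- real systems should supply their own group map.

## The synthetic generators

No deposited trajectories exist for this class of systems, so the package
generates its own test beds at the standard composition: 48 peptides, 12
drug copies, 48 Zn^2+^ and neutralizing counterions in an 83 Å cubic box.
Neutralization is arithmetic: nitrate absorbs the Zn^2+^ charge and any
negative drug charge (96 NO~3~^-^ for neutral or positive drugs, 72 for a
-2 drug), chloride balances positive drug charge (12 Cl^-^ for a +1 drug).

**Planted configurations** provide exact ground truth for the detector.
Each requested cluster is grown by sequential attachment - every new member
is placed with its minimum inter-atom distance to an existing member drawn
uniformly from `[sigma, d_c)` - and whole clusters plus all scattered
components are placed with pairwise separation above `d_c + 1` Å. Recovery
of the planted partition is therefore an exact requirement, not a
statistical one.

**Monte Carlo co-assembly** emulates the qualitative physics with rigid
coarse templates (peptide: 10 pseudo-atoms; drug: 8; nitrate: 4; ions: 1)
and a square-well component-pair energy: hard core at `sigma = 2` Å,
attraction `-eps(kind_a, kind_b)` for any-atom distance below
`r_well = 3.5` Å (deliberately equal to `d_c`, so "interacting" means the
same thing to the generator and the analyzer), plus a repulsion penalty for
like-ion pairs within the well. Moves are single-component random
translations (default up to 2 Å) and rotations (up to pi/2), accepted by
the Metropolis criterion at `kT = 1`; volume is fixed. Three affinity
presets encode the qualitative drug classes: `no3_affine` (drug coordinates
nitrate, the epirubicin/doxorubicin-like signature), `zn_affine` (drug
coordinates zinc, methotrexate-like) and `inert` (no drug affinity,
cisplatin-like), on a common peptide/ion scaffold (peptide-peptide 2,
peptide-Zn 2.5, Zn-NO~3~ 3, peptide-NO~3~ 1.5 kT). The well depths were
chosen once as a plausible few-kT coordination scale: strong enough to
drive assembly within hundreds of sweeps, weak enough to keep the system
reversible at `kT = 1`.

What the generator does *not* emulate matters for interpreting green
tests: there is no explicit solvent, no electrostatics beyond the
square-well caricature, no conformational flexibility, and the Monte Carlo
ensembles at a few hundred sweeps are small and only locally equilibrated.
Passing the affinity-recovery checks shows the analysis chain faithfully
measures what the generator planted - it says nothing quantitative about
all-atom trajectories of the real systems, whose published profiles are
out of reach at desk scale.

## Feature vectors and the classifier

Each cluster yields a 16-feature vector: mean SASA burial ratio per kind
(peptide, drug, Zn^2+^, NO~3~^-^) and the twelve triplet probabilities. A
kind absent from a cluster has no SASA ratio and is imputed as 0, as are
unobserved patterns; this keeps vectors finite and fixed-dimensional at the
cost of conflating "absent" with "fully buried", acceptable because
absence itself is class-informative. The classifier is a one-vs-one
multiclass SVM built from linear-kernel binary learners (`e1071::svm`,
cost 1 by default; the learner choice "binary learners per class pair"
is the specified structure, the kernel and cost are open choices left
configurable). Features are standardized with training-set means and
standard deviations only; prediction is by majority vote with ties broken
toward the lowest class index; per-pair decision values and linear weights
are exported so the features driving each separation can be inspected.
The intended class layout is CLASS1 = {EPI, DOX}, CLASS2 = {MTX},
CLASS3 = {MIT, 5FU}, with cisplatin-like systems excluded.

## Numerical choices and degenerate inputs

* Contact edges use strict inequality (`< d_c`); ties exactly at the
  cutoff are excluded so the detector agrees bitwise with an all-pairs
  oracle.
* "More than 30 components" is read strictly: the size filter keeps
  clusters of size >= 31 by default and is configurable.
* The contact search uses a cell list when the box admits at least four
  cells per axis and falls back to all pairs otherwise; the edge set is
  identical either way.
* SASA test points come from a deterministic Fibonacci lattice, so
  results are exactly reproducible at fixed `n_points` (default 960; the
  single-sphere closed form is recovered to well under 1% there).
* The Monte Carlo engine tracks energy incrementally and can audit itself
  against full recomputation every `check_every` moves; the square-well
  energy makes the drift exactly zero in practice, and the suite enforces
  `< 1e-8`.
* Empty inputs raise errors where a silent zero would be misleading
  (encapsulation of an empty ensemble, ratios of a peptide-free cluster,
  single-class training sets); single-member bins report sd 0 with an
  explicit `sd_defined = FALSE` flag.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
200 random frames of 300 components for the oracle-equivalence check, 50
planted configurations at the standard 83 Å composition, 100 random
graphs for the motif oracle, and 8-10 Monte Carlo ensembles per affinity
condition at 500 sweeps (sampling the last three frames of five). These
sizes were chosen as the smallest ensembles at which the affinity-recovery
orderings are stable across seeds.

## Known limitations

* Cubic orthorhombic boxes only.
* Clusters that percolate the box cannot be unwrapped and raise an error
  rather than returning approximate geometry.
* Cross-frame cluster tracking (residence times, kinetics) is out of
  scope; clusters are per-snapshot objects.
* The default chemical-group map is a coarse placeholder; group-level
  conclusions require a user-supplied map matching the real chemistry.
* Association free energies and any reproduction of published
  trajectory-derived percentages are out of scope.
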