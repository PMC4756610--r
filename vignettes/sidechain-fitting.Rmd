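---
title: "Side-chain rebuilding into electron density: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Side-chain rebuilding into electron density: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotafit)
```

## The problem

Given a crystallographic protein model with a trusted backbone and a
real-space electron-density map (a 2mFo−DFc-style map in r.m.s.d.
units), `rotafit` rebuilds every amino-acid side chain: it selects, for
each residue, a discrete conformation from a rotamer library such that
the joint assignment maximizes agreement with the density, respects
prior knowledge of rotamer frequencies, and is sterically consistent —
including contacts with crystallographic symmetry mates. The same
machinery doubles as a validation tool: residues for which no
conformation can be placed without collisions flag likely main-chain or
sequence-assignment errors, and residues whose rebuilt conformation
occupies clearly better density flag suboptimal conformer choices in
the input model.

## The energy model

The total energy of a joint assignment $\mathbf{C} = (c_1,\dots,c_N)$ is

$$E(\mathbf{C}) \;=\; \sum_i E_\mathrm{self}(c_i) \;+\;
  \sum_{i<j} E_\mathrm{pair}(c_i, c_j),$$

with the self energy of conformation $s$ of residue $i$

$$E_\mathrm{self}(c_{i,s}) = w_d\,\bigl[\max_n D(c_{i,n}) - D(c_{i,s})\bigr]
 \;+\; w_p\,\bigl[-\log p(c_{i,s})/\max_n p(c_{i,n})\bigr]
 \;+\; E_\mathrm{backbone}(c_{i,s}).$$

Both relative terms are non-negative and vanish for the best-fitting
and the most frequent conformation respectively, so a residue whose
best rotamer also fits best has self energy equal to its backbone
interaction alone.

**Density fit.** $D(c)$ sums, over the side-chain atoms, the normalized
density $\rho'(a)$: the map interpolated trilinearly at the atom and at
six points displaced by $r$ Å along each Cartesian axis, averaged, the
map mean subtracted, and the result divided by the map r.m.s.d. (the
same scale as the familiar "1 σ" contour level). Atoms whose density
falls below a threshold $k_t$ contribute $k_t - k_f (k_t - \rho')$, so
$k_f = 1$ is exactly neutral and $k_f > 1$ penalizes conformations that
leave continuous density. Defaults are the neutral values $r = 0$,
$k_t = 0$, $k_f = 1$; resolution- or type-dependent tables can be
supplied through `density_params()` when a user has calibrated them.

**Rotamer frequency.** Each library conformation carries a probability
$p(c)$ interpolated from a backbone-independent rotamer-frequency table
by inverse-distance weighting in χ space (torus metric in degrees,
exponent $q = 2$, all samples of the type; an exact χ match takes the
sample's mass). Frequencies are normalized to sum to one per residue
type. The bundled table (`rotamer_frequencies_synthetic.txt`) is a
synthetic stand-in built from canonical gauche/trans wells; any
whitespace table of `(res_type, chi1..chi4, probability)` rows can be
substituted. Because $p$ can be zero for conformations outside every
well, the $-\log$ term is capped (default 20) so strong density can
always rescue an unusual rotamer.

**Nonbonded interactions.** $E_\mathrm{pair}$ and
$E_\mathrm{backbone}$ use a united-atom scheme (nonpolar hydrogens
implicit, polar hydrogens explicit): Lennard-Jones 12-6 with geometric
combining plus Coulomb with a distance-independent dielectric
(default 4), truncated at 8 Å. The residue's own 1-2/1-3/1-4 backbone
neighborhood is excluded. Two numerical choices matter:

* *Soft repulsion.* Any single atom-pair energy is capped (default
  10 kcal/mol). Discrete rotamers placed on a real backbone routinely
  show tenth-of-Ångström contact imprecision, and an uncapped
  $r^{-12}$ wall lets one such contact overwhelm tens of r.m.s.d. units
  of density signal; hard steric exclusion is the clash model's job,
  not the energy's. This is the soft-core convention of side-chain
  packing programs generally.
* *Symmetry images.* Interactions with crystallographic copies within
  the cutoff are included; a residue's interaction with its **own**
  image depends only on that residue's conformation and is therefore
  folded into $E_\mathrm{self}$ (halved to count each unordered image
  pair once), which keeps the pairwise decomposition exact for
  dead-end elimination.

Polar-hydrogen placement follows standard geometric criteria: Ser/Thr
hydroxyls at X–X–O–H torsions of −60/60/180°, Tyr at 0/180°, and all
three His protonation states; each variant is a separate candidate
conformation. For Asn/Gln/His the terminal amide/imidazole flip (atom
identities exchanged at unchanged heavy-atom positions) is likewise
enumerated, since the density cannot distinguish the two orientations
but the electrostatics can.

## The conformer library

The library is built from coordinate sets (`build_library()`):
alternate locations collapse to the higher-occupancy/lower-B copy;
nomenclature of symmetric residues (Asp, Glu, Phe, Tyr, Arg) is
normalized by swapping the symmetric atom names whenever the governing
terminal torsion falls outside [−90°, 90°]; Leu/Val pseudo-chirality is
normalized the same way, and Thr/Ile with inverted chirality are
rejected outright. Conformations are screened against van der Waals
overlaps with their context (> 0.4 Å rejected), against ideal
bond/angle targets (> 6 σ rejected) and against the type-mean CB
position (> 5 σ rejected); the stereochemical targets are derived from
the package's own internal-coordinate templates, which also generate
all synthetic fixtures, so the screen and the generators share one
geometry definition. When maps are available a density-significance
screen (mean side-chain ρ′ > 1) can be applied as a simplified
substitute for full real-space-statistics filtering.

Redundancy is removed by a greedy pass in source-quality order: a
conformation is kept only if its side-chain r.m.s.d. (all atoms beyond
CB, after main-chain N/CA/C superposition) to every kept conformation
exceeds 0.1 Å; otherwise it increments the count of its nearest kept
neighbor, so medoid weighting still sees the full observation mass.

The kept conformations are clustered per residue type by complete-
linkage agglomerative hierarchical clustering under the same r.m.s.d.
metric. Cutting the dendrogram at height $X$ yields the **clX**
library: clusters whose maximum pairwise r.m.s.d. is at most $X$ Å,
each represented by its occurrence-weighted medoid. Smaller cuts refine
larger ones, which enables local expansion: given a conformation chosen
at the search level (default cl0.7), the tree is ascended to its
superset cluster at a coarse level (default cl1.5) and descended again
to all fine-level (default cl0.4) medoids below that superset — a
cheap, focused densification around the current answer. The library is
stored in a versioned JSON container (coordinates, counts, linkage,
frequencies, one group per residue type) that supports partial reads.

## The three-stage search

*Stage I — independent fitting.* With the backbone term dropped
(`e_self_simplified()`), residues decouple, and minimizing the total
energy reduces to picking each residue's lowest simplified self-energy
conformation — dominance elimination degenerates to simple selection.
Conformations are checked lazily against the fixed environment
(main-chain, CB, heteroatoms, and symmetry images, under the clash
model's element-pair cutoffs reduced by an adjustable 0.3 Å): a
conformation is tested only when it is about to be selected, so if the
best one is clean no others are ever examined. Residues whose every
conformation clashes keep their best conformation flagged as
unfittable candidates.

*Stage II — collision resolution.* Side-chain/side-chain collisions —
detected between all residue pairs and all symmetry images across the
27 neighboring unit cells, with bounding-sphere pruning before exact
atom-pair checks — are resolved by best-first search over a directed
graph. A node holds a joint assignment and a focus residue and offers
at most two moves: the *horizontal* edge advances the focus to its
next-ranked conformation; the *vertical* edge binds the focus's clash
partner to its best compatible conformation at or above its current
rank, and the focus shifts to the partner. The cost $g$ of a node is
the total simplified energy above the unconstrained minimum; nodes are
expanded in order of $g$ (ties: fewer clashes, then lexicographic), a
collision-free node is terminal, and the search stops once every open
node's estimate $f = g + h$ reaches the best terminal cost, where $h$
is the smaller of the node's two move costs. Because both moves only
increase conformation ranks, $h$ never overestimates the true
remaining cost, and any collision-free assignment is reachable by
rank-monotone moves, so the first accepted terminal is the optimal
collision-free assignment under the simplified energy; both properties
are enforced by enumeration in the test suite. Rank lists also allow
wholesale pruning: once a residue's ranked energy exceeds the
incumbent terminal's cost, the rest of its list can never help.

*Stage III — refinement with pairwise interactions.* Candidate sets
are rebuilt around the stage-II answer (cluster expansion, flips,
polar-H variants; a per-residue cap falls back to the unexpanded set),
full self-energies and sparse pairwise tables are computed, and the
global minimum-energy assignment is extracted exactly: Goldstein
elimination, then single-residue split elimination, then two-residue
split elimination, each iterated to a fixed point; remaining residues
are grouped into interaction clusters (connected components under
|E_pair| > 10⁻⁶); clusters smaller than 15 residues are solved by A*
over partial assignments with the standard admissible
minimum-completion heuristic, larger ones first get a pairs-elimination
cycle and repeated singles elimination. A safety cap on A* expansions
falls back to exhaustive enumeration over the survivors, preserving
exactness. A final collision audit demotes any residue still involved
in contacts to unfittable status.

## Fixture generation and what it does (not) show

All benchmarks are synthetic and generated in code. Chains are built on
ideal extended backbones with side chains drawn from the rotamer table
(χ jitter 8°); libraries are built from 40 such chains of 25 residues;
ground-truth models plant library rotamers drawn by occurrence weight
with rejection of sterically impossible draws (a refined structure
contains none); maps are Gaussian-sum densities (atom Gaussians scaled
by electron count; σ = 0.7 Å ≈ 1.6 Å resolution by the σ ≈ 0.425·d
heuristic, 0.3 Å grid) with optional i.i.d. noise stated in map-r.m.s.d.
units. Test sets follow the TS_dX_rY convention: an X-fraction of
eligible residues stripped past CB, a disjoint Y-fraction with every χ
rotated by independent U(−40°, 40°) draws; Ala/Gly/Pro are exempt (Pro
ring sampling is degenerate). The headline benchmark perturbs a
30-residue planted model with X = 0.2, Y = 0.5 and measures the
fraction of eligible residues recovered within 0.5 Å side-chain
r.m.s.d., at noise levels 0, 4 and 10 (spanning clean maps to noise
well above signal for single atoms).

Passing these benchmarks shows that the machinery — scoring, library,
elimination and search — is internally correct and that density-driven
recovery works when the truth is representable by the library. It does
**not** show performance on experimental maps: synthetic maps have no
phase error, no solvent, no series-termination effects, the synthetic
library is far sparser than one harvested from the PDB, and extended
synthetic chains are less tightly packed than native cores.

## Numerical and design choices

* Canonical frame: CA at the origin, N along −x, C in the xy-plane
  with positive y. All conformer coordinates and r.m.s.d. comparisons
  live in this frame; Gly/Ala are excluded from accuracy metrics.
* χ deviations of two-fold symmetric terminal groups (Asp, Glu, Phe,
  Tyr; Asn/Gln/His under symmetric treatment) are compared modulo 180°,
  matching the name-swap equivalence.
* Tie-breaks are deterministic everywhere (stable order by energy then
  index; lexicographic assignments in searches), so identical inputs
  produce bit-identical solutions; the exhaustive oracle breaks ties
  toward the lexicographically smallest assignment.
* Map interpolation is trilinear; degenerate maps (zero r.m.s.d.) are
  rejected at query time. Non-periodic maps refuse out-of-bounds
  queries rather than extrapolate.
* Elimination uses a 10⁻⁹ guard on strict inequalities so floating-
  point ties never discard a co-optimal conformation.
* The problem sizes in tests (30-residue models, ≤ 8 conformations per
  residue in random instances, 200-conformer library fixtures) keep
  every oracle comparison exhaustive and the full suite fast while
  exercising all code paths, including the large-cluster pairs-DEE
  route via a lowered cluster threshold.

## Known limitations

Pro side chains are never refit (ring closure cannot be expressed as
free χ sampling). Altloc targets are rebuilt as single conformations.
The density-significance score is a simplified support proxy, not a
full real-space statistics package; difference-map peak screening is
not implemented. Maps are synthesized only for orthogonal cells (any
cell is accepted when reading CCP4/MRC files). Nonbonded parameters are
a compact united-atom set adequate for discriminating orientations and
flips, not a calibrated force field; the trained resolution-dependent
weight tables of a production deployment are accepted as configuration
but not shipped.
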