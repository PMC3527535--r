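---
title: "Folding a knotted lattice protein: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding a knotted lattice protein: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`knotfold` simulates a cubic-lattice protein: `N` beads on integer lattice
sites, unit bonds between consecutive beads, and hard excluded volume (one
bead per site). Energetics follow the Gō prescription: a conformation's
energy is

$$E = \varepsilon \sum_{i<j} \Delta_{ij}\,\delta_{ij},$$

where $\Delta_{ij}$ marks the pairs that are in contact in the native
structure, $\delta_{ij}$ marks pairs that are currently non-bonded nearest
lattice neighbours, and $\varepsilon = -1$ sets the energy unit. Non-native
contacts are sterically allowed but energetically silent, so with 40 native
contacts the energy is exactly $-40\,Q$ where $Q$ is the fraction of native
contacts formed. Temperature is measured in units of
$|\varepsilon|/k_\mathrm{B}$ with $k_\mathrm{B} = 1$.

A *contact* is a non-bonded nearest-neighbour pair. On the cubic lattice
such pairs necessarily have odd sequence separation, and the smallest
geometrically possible separation is $|i-j| = 3$; this is the definition
`compute_contacts()` enforces.

Dynamics are Metropolis Monte Carlo over the standard local move set:
corner flips for interior beads, end moves for the two termini, and
crankshaft rotations of two interior beads about a lattice axis. One MCS
(the time unit) is one *attempted* elementary move. The proposal mixture
(`p_crank = 0.2` by default) and the uniform draws over fixed index ranges
make the proposal distribution symmetric: infeasible draws count as
rejected attempts rather than being redrawn, and end-move targets are drawn
uniformly over the vacant neighbours of the pivot, a set whose size the
move itself cannot change. Detailed balance therefore holds for any
`p_crank`, which the test suite verifies by recovering the exact Boltzmann
distribution on a fully enumerable 5-bead system.

Crucially for this package's topic, crankshafts and end moves can pass one
strand through another (excluded volume only constrains bead *sites*), so
the chain can knot and unknot during a simulation. Corner flips cannot: the
unit lattice square a corner flip sweeps can never be pierced by a lattice
bond. That asymmetry is exploited by both the structure designer and the
tests.

## Folding setups

Three setups reproduce the study conditions:

* `bulk` — free folding;
* `plane_tether` — one terminus is joined to a chemically inert plane at
  $z=0$ by a linker of one lattice spacing: the anchored bead is fixed at
  $(0,0,1)$, every bead must keep $z \ge 1$ (the wall is purely steric),
  and the anchored terminus loses its end move;
* `point_tether` — the anchored bead is fixed but there is no wall; the
  control that separates losing terminus mobility from the steric effect
  of the surface.

By the field's convention for trefoil proteins the terminus closest to the
knotted core is called the C-terminus and is bead 1.

# The model systems

Protein K is a 41-bead chain whose native state is a compact cuboid-like
conformation with 40 native contacts, a backbone trefoil knot whose minimal
knotted segment spans beads 3–22 and contains 8 of the contacts, an
absolute contact order (mean $|i-j|$ over contacts) of 17.2, and the first
terminus extended above the body so the chain closure is unambiguous.
Protein U is its unknotted control: one bead shorter, also 40 contacts,
contact order 16, and a 90% bead-site overlap with protein K under optimal
superposition. Both are bundled as plain-text fixtures
(`protein_k()`, `protein_u()`) together with the seeds that produced them,
and both pass `verify_native()`, which re-derives every constraint from the
raw coordinates.

## How the designer works

Plain simulated annealing cannot design protein K. Two failure modes are
intrinsic: a compact self-avoiding chain essentially never crosses into the
knotted sector through local moves (the knot penalty just stalls), and the
rare chains that do knot spontaneously carry a knot delocalized over the
whole backbone, whereas the target needs a tight core at beads 3–22.
`design_knotted_native()` therefore builds the topology first:

1. a lattice trefoil is traced by walking the lattice along the smooth
   parametric $(2,3)$ torus knot;
2. the closed polygon is shortened by *knot-safe* moves only — corner
   flips and excision of doubled corners (two antiparallel consecutive
   bonds). Neither move's swept unit square can be pierced by a lattice
   bond, so knot type is provably preserved; the polygon shrinks to the
   24-edge minimum;
3. the minimal polygon is opened at every cyclic offset, keeping the
   20-bead open segments that remain trefoil-knotted under radial closure
   and are *minimally* knotted (deleting either end bead unties them);
4. verified corner-flip shuffling tunes such a segment to exactly 8
   internal contacts while re-checking the topology after every accepted
   flip;
5. the tuned segment is frozen as beads 3–22, the terminal beads and the
   19-bead tail are grown around it by randomized depth-first search
   inside the target box, and constrained annealing — which never moves
   the frozen core — optimizes contact count, summed contact separation
   (contact order × contacts must equal 688 exactly), compactness and
   terminus extension, with the Alexander determinant evaluated on every
   candidate so the knot is never lost;
6. reheat cycles polish the last violations; a candidate is accepted only
   when `verify_native()` is clean.

Protein U is designed from protein K by `design_unknotted_from()`: the
extended terminus is dropped and the remaining chain is annealed towards
the unknot under a site-coincidence restraint against the parent (at most
four rerouted backbone segments). The annealer controls coincidence in the
parent's frame only, while the 90% requirement concerns the *optimal*
superposition over all 24 proper rotations and translations, so candidates
are accepted only after full verification; reflections are excluded from
the superposition because they flip knot chirality.

# Knot detection

Knottedness of an open chain is only defined relative to a closure.
`close_chain()` extends both termini radially outward from the chain
centroid to a sphere of three times the chain's maximal extent and joins
them with an arc on that sphere — a deterministic closure, so every
conformation has a definite knot state. Lattice chains often place beads
exactly on the outgoing ray; closure directions are therefore perturbed
deterministically, in increasing steps, until every closure segment clears
the chain by a margin, and the resulting polygon is verified to be simple.

`kmt_reduce()` deletes a vertex whenever the triangle spanned with its two
neighbours is intersected by no other segment, iterating to a fixed point.
The intersection predicate is *conservative*: coplanar and near-degenerate
cases count as intersections, so a doubtful deletion is skipped rather than
risked — the reduction may stop early but can never change the knot type.

`alexander_det()` projects the (reduced) polygon along a generic direction,
builds the crossing diagram, and evaluates the Alexander determinant
$|\Delta(-1)|$: 1 for the unknot, 3 for the trefoil, 5 for the figure-eight
knot. Projection directions are drawn from a deterministic low-discrepancy
sequence and rejected while degenerate (near-parallel overlapping images,
crossings too close to vertices, ambiguous depth); three independent
directions must agree or the computation aborts loudly. The determinant is
chirality-blind, which suffices to distinguish the classes this study
needs. The test suite cross-checks it against textbook parametric knots and
against an independent brute-force Fox p-colouring oracle.

`find_knot_core()` shrinks a knotted chain to the smallest contiguous bead
range whose sub-chain, re-closed by the same convention, stays knotted,
deleting beads from alternating ends. On chains up to 30 beads the result
is tested to agree with exhaustive search over all contiguous sub-ranges.

# Thermodynamics

Replica exchange runs a strictly increasing temperature grid (geometric
spacing; `build_temperature_grid()`), attempting swaps between random
adjacent pairs with the standard acceptance
$\min\{1, \exp[(\beta_i-\beta_j)(E_i-E_j)]\}$. The grid should be dense
enough that swaps essentially always succeed; with the bundled protein K a
56-temperature grid over $[0.5, 0.95]$ keeps the mean adjacent-pair
acceptance above 0.95, the bottleneck being the sharp folding transition
where energy fluctuations peak. The first 20% of sweeps is discarded as
equilibration by default. Replicate runs over the same grid can be pooled
with `pool_replica_exchange()`, mirroring the practice of averaging several
independent replica-exchange simulations.

Heat capacity comes from energy fluctuations,
$C_v = (\langle E^2\rangle - \langle E\rangle^2)/T^2$, and the melting
temperature `estimate_tm()` is the grid temperature of the $C_v$ maximum
(ties resolved to the lower temperature, with a message). Free energies use
the standard multiple-histogram (WHAM) estimator: per-temperature shifts
iterated to self-consistency (tolerance $10^{-7}$, at most $10^5$
iterations, with a diagnostic error naming any non-overlapping adjacent
histograms), then a reweighted density over the requested coordinate at the
target temperature, $F = -T\log(\text{density})$, shifted so the minimum is
zero. Binning follows the discreteness of the model: energy at its integer
levels, $Q$ at multiples of $1/40$, and the gyration radius in 0.5 Å bins
(lattice units are converted at 3.8 Å per spacing, the Cα–Cα distance, for
reporting only). Cells without support are `NA`, never zero. Statistical
inefficiency corrections are not applied; samples are thinned by the
recording interval instead.

# Kinetics

`run_folding()` starts from a random unfolded conformation (seeded chain
growth, restarted on dead ends, rejecting starts with $Q > 0.2$) and stops
at the first passage to $Q = 1$. `collect_fpts()` aggregates independent
runs; *foldicity* is the fraction that folded within budget. The folding
rate is the negative slope of an unweighted least-squares fit of
$\log P_\mathrm{unfolded}(t)$ over the window
$P_\mathrm{unfolded} \in [0.05, 1)$; censored (unfolded-at-budget) runs
keep the survival curve up, which lets rates be estimated at incomplete
foldicity, and the far tail is excluded as noise-dominated. Fits are
refused below a configurable floor of folded runs (default 50). Parameter
recovery on synthetic exponential first-passage times (within 5% without
censoring and 15% with 30% censoring at $n = 2000$) is the accuracy
contract; absolute rates are structure- and budget-specific.

# Ensembles and clustering

`harvest_ensemble()` collects conformations with an exact native-contact
count from trajectory snapshots, enforcing a minimal intra-trajectory time
gap. The function default (10·N MCS) decorrelates local geometry; analyses
of *knotting* use a much larger gap (5×10⁴ MCS) because topology outlives
local relaxation by orders of magnitude — with short gaps a single early
knotting event would contaminate a whole bin with correlated copies.
Membership is re-verified by contact enumeration.

Clustering is agglomerative with average linkage on the contact-map
distance — the symmetric-difference (Hamming) count, exact for binary
contact sets; Jaccard is available behind a flag. The tree is cut at the
height yielding at most 8 clusters; cutting by height rather than by count
keeps zero-distance ties together instead of splitting them arbitrarily.
Clusters below 5% occupancy are merged into their nearest cluster so the
reported classes are the relevant ones. Each cluster reports a contact
probability map over all pairs and a representative — the member minimizing
the summed distance to the cluster (closest to the centroid), lowest index
winning ties. Chains of representatives across Q are exposed as ordered
conformation dumps; deciding which representatives can interconvert
without major rearrangement is left to the user.

# Design decisions on open points

* **Time unit.** 1 MCS = one attempted move; "MC steps per residue" =
  MCS/N. All budgets are plain MCS in configuration.
* **Tether geometry.** The anchor sits at the origin on the wall plane;
  the anchored bead is permanently fixed at $(0,0,1)$ — tethering removes
  that terminus's end move, so it never relocates.
* **Closure convention.** A single deterministic radial closure (not a
  stochastic majority) keeps per-conformation knot states, hence
  $p_\mathrm{knot}$, deterministic.
* **Engine internals.** Occupancy lives on a dense 128³ grid (2 MB per
  chain); in bulk the chain is re-centred on its centroid when it drifts,
  which no observable depends on. Contact bookkeeping is incremental, with
  a from-scratch recount available as a debug oracle at every recording
  point. The RNG is a self-contained xoshiro256** so trajectories are
  bit-reproducible across platforms for a given seed.
* **Problem sizes.** The test suite and the reproduction script run
  desk-scale versions of the study: replica exchange with 24 temperatures
  × 4000-step sweeps × 800 sweeps; kinetics with 200 bulk runs (budget
  2×10⁷ MCS) and 24 tethered runs (4×10⁷ MCS); ensembles of at least 200
  conformations per Q bin harvested from 16–40 independent trajectories.
  These sizes resolve the bounds and orderings of interest; full-scale
  configurations are a matter of changing numbers in `study_config()`.

# What the synthetic systems do and do not show

The designed structures satisfy every *printed* constraint of the study's
model systems, but the literal coordinates of the originals were never
published; all downstream numbers are therefore reproduced on
spec-equivalent structures. Quantities pinned by the specification (contact
counts, core range and contacts, contact orders, overlap) are exact.
Emergent quantities can differ in detail:

* The designed protein K folds and knots fast enough that the full
  thermodynamics and kinetics are observable at desk scale; absolute rates
  and melting temperatures are properties of this structure, not of the
  original.
* The grid-resolution melting temperature of bulk protein K is
  reproducibly near $T \approx 0.6$, but with desk-scale replica-exchange
  budgets the $C_v$-argmax can move by one grid point between seeds.
* The $Q = 1$ level of this design is not unique: rare conformations form
  all 40 native contacts plus extra non-native ones. All such states seen
  in testing are trefoil-knotted, and first passage to $Q = 1$ remains a
  well-defined folding criterion, but "the native state is a single
  conformation" holds only up to this degeneracy.
* The surface-tethered free-energy profile develops the expected
  post-transition intermediate basin, but on this structure the basin is
  broad over $Q \approx 0.70$–$0.78$ and its discrete-bin minimum
  fluctuates between 0.700 and 0.775 with desk-scale sampling rather than
  sitting firmly at 0.75.

More generally, the lattice Gō model abstracts away side chains,
non-native energetics and solvent; passing tests show the machinery is
faithful to the model, not that the model is faithful to any particular
real protein.
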