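---
title: "Multistate design on a bead-rotamer model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate design on a bead-rotamer model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdesign)
```

## The problem

Single-state protein design asks for the sequence of lowest energy on one
fixed backbone.  Specificity problems cannot be phrased that way: to turn an
obligate homodimer into an obligate heterodimer, or to make a promiscuous
hub bind exactly one of its partners, a single sequence must simultaneously
score *well* on the desired complex (a positive state) and *poorly* on each
undesired complex (negative states).  `msdesign` implements this multistate
formulation end to end: an elitist genetic algorithm (GA) proposes entity
sequences; every candidate sequence is threaded onto each state and its side
chains are re-optimized there by discrete rotamer packing; a small
programmable fitness language combines the per-state energies into one
scalar that the GA minimizes; and an outer iterative protocol redocks the
negative complexes and feeds the low-energy docked conformations back in as
additional negative states.

## The bead-rotamer energy model

All-atom force fields and empirical rotamer libraries are deliberately out
of scope.  Instead each residue contributes one fixed backbone sphere at its
C-alpha anchor (radius 1.7 A) and, if packable, a set of discrete side-chain
placements: one sphere per orientation, six orientations along the positive
and negative local frame axes (glycine, with no side-chain heavy atoms, has
a single degenerate placement at the anchor).  For amino acid `a` with
side-chain heavy-atom count `c(a)`:

* bead radius `r = 1.0 + 0.25 c^(1/3)` A,
* center offset from the anchor `0.5 + 0.35 sqrt(c)` A along the
  orientation axis,
* hydrophobicity `h = KyteDoolittle(a) / 4.5`, dimensionless in [-1, 1].

Two beads at center distance `d` with `sigma = r_i + r_j` interact by a
12-6 well,

    E = eps_ij * ((sigma/d)^12 - 2 (sigma/d)^6),   eps_ij = eps0 (1 + h_i h_j),

zero beyond a 6 A cutoff, with `eps0 = 0.5` REU (we keep the name "REU" for
the model's arbitrary energy unit).  The one-body energy of a rotamer is its
summed interaction with every other residue's backbone sphere; the constant
backbone-backbone background is carried separately.  The model is exactly
specified — every constant above comes from a standard table or is stated
here — and it preserves the combinatorial structure that packing algorithms
actually manipulate: one-body plus sparse two-body terms, hard clashes,
burial-dependent contact counts.  What it does *not* model is equally
important for interpreting results: no electrostatics, hydrogen bonding,
solvation, or backbone flexibility, and no attempt to match any published
all-atom energy value.

Rotamer geometry depends only on (amino acid, anchor, local frame), and in
multistate mode the backbone-clash filter ("bump check") is forced off and
the full orientation set is always built.  Both choices are safeguards
against the *missing rotamer problem*: if a rotamer exists in a positive
state but is absent from the matching negative state, the search will
exploit the hole and report a spuriously favorable fitness.  Identical
rotamer sets across states with matching local geometry close that hole by
construction, and a dedicated test asserts it.

## Packing: problems, the interaction graph, and the optimizer family

For a given sequence on a given state, designed residues carry rotamers of
their assigned amino acid only, secondary ("repack-only") residues carry
wildtype rotamers, and everything else is folded into the fixed background.
Pair-energy submatrices are computed lazily at (position, amino acid) x
(position, amino acid) granularity and cached in an interaction graph.  The
cache honors an optional memory ceiling (8 bytes per stored entry, exact):
storing past the ceiling evicts the submatrix whose most recent access lies
furthest in the past, and evicted submatrices are recomputed on demand.
Because each submatrix is a pure function of geometry, eviction is
semantically invisible — packing results are bit-identical under unlimited
and minimal ceilings, which the test suite checks rather than assumes.
Across a GA run the laziness pays because only amino-acid pairs that
actually co-occur in proposed sequences are ever computed;
`graph_stats()` reports the measured saving.

The optimizer family, all seeded and deterministic:

* `bmec()` — each position takes its best one-body rotamer (ties to the
  lowest index); `quench()` — fixed-order sweeps accepting only strictly
  energy-lowering single substitutions.
* `pack_faster()` — BMEC seeding followed by single-residue
  perturbation/relaxation sweeps: tentatively fix each rotamer, relax the
  at most ten neighbors with greatest-magnitude interaction with it
  (repeated optimal single-residue passes, capped at ten), accept on strict
  net decrease.  The sweep cap (30) and strict-decrease rule guarantee
  termination without cycling.
* `pack_standard_anneal()` — Metropolis substitutions over a geometric
  cooling trajectory, kT 100 to 0.3 across 19 outer iterations, with a
  reheat to kT = 100 whenever the end-of-iteration energy fails to drop at
  least 1 REU below the mean of the previous three; finishes by restoring
  the best assignment and quenching.
* `pack_multicool()` — cooling kT 10 to 0.2 in 20 iterations with three
  quench-and-restore operations per temperature (60 in total), keeping the
  ten lowest-energy distinct quenched assignments; then six low-temperature
  trajectories (kT 0.25 to 0.05 over ten temperatures, quench-and-restore
  closing each) started from the best six saved.  The pairing of six
  trajectories with ten saved assignments is genuinely open; we start the
  six trajectories from the six best in energy order, and reuse the best
  available (with a warning) when fewer than six distinct quenched minima
  exist, as happens on tiny problems.
* `pack_hybrid()` — shortened annealing (a fraction of the per-temperature
  substitution count) followed by relaxation to convergence, best over `N`
  restarts.  Restart `r` derives its stream as `stable_mix(seed, r)`, so
  the 8-restart run extends — never reshuffles — the 4-restart run, which
  makes "more restarts never hurt" a theorem rather than a tendency.
* `pack_exhaustive()` — the oracle: exact enumeration (capped at 1e7
  assignments), lexicographic tie-break.

Per-temperature substitution counts are not derivable from first
principles; the default is five times the total rotamer count,
configurable through `anneal_schedule()`.  Incremental energy bookkeeping
is audited against full recomputation once per temperature, and every
returned result re-validates its cached energy to 1e-6 REU.

On 200 random frustrated instances (six positions, up to six rotamers,
occasional +8 REU clash entries), all packers stay at or above the
exhaustive minimum — a zero-tolerance invariant — and the family ranks the
way a practitioner would expect: the standard annealer reaches the optimum
least often, the multi-cool annealer and the multi-restart hybrids most
often.  `benchmark_packers()` tabulates the comparison (fraction at the
consensus energy, within 1e-3/0.1/1 REU, failures beyond 100 REU, mean and
relative times) for all fifteen variants.

## States, threading, and the order-independence contract

A state is a structure plus a *correspondence map* (which residues take
their identity from which entity-sequence positions; one entity position
may feed several residues, as in a homodimer whose two chains share
letters) plus a *secondary resfile* of repack-only boundary residues, plus
a replicate count.  The heterodimer task uses the odd/even convention: odd
entity positions belong to chemical species A, even to species B, indexed
over the same designed residue numbers, so `AB`, `AA` and `BB` states
differ only in their correspondence files.

Replicated packing (`replicates = k`) keeps the best of `k` independent
packer runs, each seeded by `stable_mix(global_seed, state, sequence,
replicate)`.  That mixing rule *is* the distribution contract: there is no
shared RNG stream, so any partitioning or reordering of state evaluations
— serial, reversed, or farmed out — produces bit-identical results, and the
GA's by-sequence fitness cache is exactly semantics-preserving.

## The fitness language

Seven commands (`STATE`, `STATE_VECTOR`, `SCALAR_EXPRESSION`,
`VECTOR_VARIABLE`, `VECTOR_EXPRESSION`, `ENTITY_FUNCTION`, `FITNESS`) build
a straight-line program evaluated per sequence; identifiers must be defined
before use, exactly one `FITNESS` line is allowed, and lower is better.
Expressions support `+ - * /`, unary minus, comparisons, `min`/`max`,
vector reductions `vmin`/`vmax`, `abs`, `pow` and a conditional `ite`;
division and `ite` go slightly beyond basic arithmetic because the
saturating fitness needs a gating indicator.  `vmin` over a
`STATE_VECTOR` is how an ensemble of negative-state conformations enters:
the species' energy is the best over its conformations.

For the heterodimer task (`heterodimer_fitness()`), with
`dG_AB = e_AB - e_A - e_B` and `dG_XX = e_XX - 2 e_X`:

* variant 1: `F = e_AB + w [(dG_AB - min(dG_AA, 0)) + (dG_AB -
  min(dG_BB, 0))] + E_seq`.  The `min(., 0)` caps are the central
  negative-design safeguard: with rigid backbones the search would
  otherwise wedge the largest possible clash into one homodimer (an
  apparent +1000 REU binding energy) instead of honestly destabilizing
  both; a binding energy above zero just means the docked model is no
  longer valid, so no credit is given beyond zero.  The exact algebraic
  form here is a reconstruction; it provably satisfies the one sharp
  property stated for it — at `w = 0.5` the fitness is exactly indifferent
  between 1 REU of heterodimer total energy and 1 REU of heterodimer
  binding energy (`uniroot` on the implemented program recovers 0.5 to
  1e-9), with larger weights favoring binding energy — and `w = 0`
  degenerates to positive-only (single-state) design, which is the control
  arm of the comparison below.
* variant 2: `F = e_AB + max(dG_AB, -24) + w2 * b * [max(-12 - dG_AA, 0) +
  max(-12 - dG_BB, 0)] + E_seq`, `b = ite(dG_AB < gate, 1, 0)`.  The
  binding reward saturates at -24 REU (so total energy is not traded away
  for ever-deeper binding), homodimers are pushed up toward a -12 REU
  target, and the bonus is gated off until the heterodimer itself binds
  well to avoid carving local minima far from useful sequences.  The gate
  threshold is not derivable from the stated properties; the default is
  -20 REU and it is an explicit, logged parameter.

Entity functions score the sequence alone: an identity penalty of 5 REU per
identical designed pair beyond the sixth (steering away from
homodimer-prone symmetric sequences) and a mutation penalty of 1 REU per
mutation beyond the fifth on either chain (biasing toward minimal edits).
The "minimal mutation" term is implemented with penalty sign convention:
extra mutations always score >= 0.

The one-against-many task (`orthogonal_fitness()`) compares each dimer
against monomer states *sharing its backbone conformation*
(`dG_AC = e_AC - e_A(AC backbone) - e_C`), which costs extra states but
keeps every binding energy matched-backbone.

## The genetic algorithm

Population 100, elites 50, 98% of new sequences single-position point
mutants of uniformly chosen elite parents and 2% uniform per-position
crossovers of two distinct members of the previous population; the
generation count defaults to 15 L for sequence length L (the multiplier is
a package choice; the search is insensitive to it on the landscapes here,
and it is configurable).  Elitism makes the best-fitness trace
non-increasing for every seed — asserted as an invariant, not sampled.  On
a separable 4-position, 5-letter landscape whose optimum is known by
enumerating all 625 sequences, the GA at population 20 recovers the optimum
in at least 9 of 10 seeds within the default budget.

## Redocking and the iterative protocol

Negative-state conformations are searched by rigid-body perturb-and-refine
docking (`dock_pert()`): each trajectory perturbs the mobile chain
(per-axis normal translation, default sd 3 A; random-axis rotation, default
sd 8 degrees about the mobile centroid), then runs Metropolis refinement at
kT = 0.8 with 0.2-scaled moves, fully repacking side chains at every pose;
the best of `n_traj` trajectories by packed total energy is kept and its
matched-backbone binding energy computed.  The perturbation magnitudes are
package choices on the toy scale (nothing in the model fixes them) and are
configuration keys.  Because side chains are repacked from scratch at every
pose, the chain-split/repack/concatenate preamble that a full-atom pipeline
needs to relieve stale intra-chain collisions is implicit.  Beyond the 6 A
cutoff all cross-chain terms vanish and the binding energy is exactly
zero, which is the model's version of the "undocked conformation caps
apparent destabilization" argument.

`run_iterative()` then loops: one GA trajectory per (gap weight, positive
conformation) pair; redock each selected design's homodimers and
heterodimer; record the signed error `dG(design) - dG(redock)` per species
(the design-side value is the raw ensemble-minimum binding energy, uncapped
— the cap shapes the fitness, not the report; the absolute-value mean is
reported alongside); admit redocked homodimer conformations with binding
energy at or below `dG_keep` (default -1 REU) that sit at least `rms_min`
(default 0.5 A) mutual C-alpha RMS — computed without superposition, so
rigid-body displacement counts — from everything already kept.  Both
filter thresholds are configuration keys with logged defaults.  Ensembles
never shrink, and the whole run is a pure function of its configuration.

The protocol's headline behavior reproduces qualitatively on the synthetic
system: round 1 designs against a single homodimer conformation and happily
wedges clashes into it, so the design-side binding energies are far above
what redocking finds (large positive mean error); as redocked conformations
accumulate in the ensembles, the design-side minimum approaches the
redocked reality and the mean error shrinks.  With the test configuration
(interface of 2 designed cross-chain pairs, L = 12, GA population 24 for 12
generations, 2 weights, 5 docking trajectories of 10 cycles, 3 rounds —
sizes chosen so the whole protocol is a desk-scale computation) the
per-round mean error falls from about +5.3 REU to under 1 REU in magnitude
by round 3, and the `w > 0` arm ends with homodimers several REU less
bound relative to the heterodimer than the `w = 0` positive-only control.
The test suite asserts exactly the strict round-1-to-round-3 decrease,
ensemble monotonicity and the control comparison; the numbers themselves
are printed by the suite and by `Rscript inst/cli/msdesign.R iterate`.

## Numerical and degenerate-input policy

Ties break toward the lowest index everywhere (rotamers, positions,
assignments — lexicographic in the oracle), so results are reproducible
across platforms.  Packer RNG is an internal splitmix64 stream, independent
of R's RNG; R-side randomness (GA proposals, docking perturbations,
synthetic geometry) is seeded through the same `stable_mix` hashing.
Problems with a single rotamer everywhere short-circuit to the unique
assignment; empty packable sets evaluate to the background energy with a
warning; coincident bead centers, unknown amino acids, absent residues and
malformed files raise errors that name the offender.

## Known limitations

The energy model's simplicity means sequence-level conclusions do not
transfer to real proteins — passing tests demonstrate that the *machinery*
(search, caching, capping, iteration) behaves as specified, not that any
designed sequence would fold or bind.  Docking explores rigid-body space
only, inheriting the fixed-backbone requirement; the synthetic scaffolds
are idealized helices with none of the irregularity of crystal structures;
and the GA's parameters are tuned for the smooth landscapes the toy model
produces.  MPI-style distribution is replaced by the seed contract: the
package runs serially, and parallel execution is correct by construction
but not provided.
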