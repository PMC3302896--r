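---
title: "Predicting beta-sheet topologies by integer linear optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting beta-sheet topologies by integer linear optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheettopo)
```

## The problem

A beta sheet is determined by three nested decisions: which strands pair
with which (the contact set), in which orientation each pair lies
(parallel or antiparallel), and at which register (which residues
hydrogen-bond across the pair). `sheettopo` predicts all three from
sequence and secondary structure alone — no 3D coordinates — and returns a
rank-ordered list of plausible sheet topologies rather than a single
answer. Downstream structure-prediction pipelines consume the residue
pairs of a topology as distance restraints (`export_restraints()`), which
dramatically narrows the conformational search space.

The space being searched is enormous: the number of distinct single-sheet
motifs for $n$ strands (orderings times orientations, one reflection
removed) is $n!/2 \cdot 2^{n-1}$ — already 2,580,480 at $n = 8$
(`count_motifs()`). The package's central claim is that a modest set of
physically motivated linear constraints carves this space down so far
that exact optimization is practical.

## The model

For every ordered strand pair $i < j$ and each orientation, the best
gapless alignment is found by sliding one strand along the other
(`align_pair()`); its summed residue-pair potential, corrected for the
local-contact bias of database-derived potentials, gives scores
$S^A_{ij}$ and $S^P_{ij}$. Binary variables $y^A_{ij}$, $y^P_{ij}$ select
contacts; the objective maximizes the total corrected contact potential
$\sum_{ij} S^A_{ij} y^A_{ij} + S^P_{ij} y^P_{ij}$.

Residue-level contact variables are linked to the strand binaries by
*equality*: because the register of each pair is fixed in advance by the
scoring stage, activating a strand contact activates exactly the residue
pairs of its stored best alignment. This is a deliberate design choice —
with a one-sided link the solver could zero out every residue variable
and the residue-level constraints below would lose all force. It also
lets the implementation substitute the residue variables out: every
residue-level restriction becomes a linear row over the strand binaries
with alignment-derived coefficients, and the residue pairs are
reconstructed when a solution is read out.

The constraint families:

* **Structural.** Each pair takes at most one orientation. Each residue
  joins at most two residue contacts (a backbone donates/accepts on two
  faces). Each strand has between 1 and 3 contacts — two faces, but a
  long strand can host two short partners on one face. A non-barrel
  protein with $N$ strands has at most $N - 1$ contacts.
* **Geometric.** The partner residues aligned against strand $i$ must
  total between $B_{lo}(i)$ and $B_{hi}(i)$: sheets bury their faces, so
  grossly under- or over-covered strands are implausible. Three partners
  of a common strand may not have mutually overlapping footprints (no
  wrap-around), and a strand may keep at most two contacts away from its
  sequence neighbours and the chain-edge strands.
* **Topological.** A non-local contact ($j - i \geq 3$) needs scaffolding:
  it is only allowed if one of its members also contacts a resolved
  sequence neighbour — sheet growth is hierarchical, with local pairings
  zipping first. Crossing "pretzel" quartets are forbidden, every
  non-local contact must be counter-balanced by an interlocking non-local
  partner (the sandwich-protein pattern), and the shortest, least
  hydrophobic strands are pushed toward sheet edges (one terminal set per
  five strands).
* **Hydrogen-bond budget.** The number of realized residue pairs must lie
  within a relative tolerance (default 15%) of $0.638 \cdot n_\beta$,
  where $n_\beta$ is the number of strand residues; 0.638 is the
  least-squares coefficient relating strand residues to backbone
  hydrogen bonds in globular proteins.

Two global properties are *not* written as up-front rows because their
constraint families are exponential: acyclicity of the strand-contact
graph (barrels are excluded by design) and two-colorability of the
contact-incompatibility graph (contacts of a strand must admit a
consistent two-face assignment; `is_two_colorable()` runs a breadth-first
coloring and returns an odd-cycle witness on failure). The ranked loop
(`solve_ranked()`) checks each incumbent, eliminates offenders with
subtour or odd-cycle cuts *without consuming a rank*, and excludes each
accepted topology with the standard integer cut
$\sum_{O} y - \sum_{Z} y \leq |O| - 1$ before re-solving, until `K`
topologies are collected.

## Reading the unreadable: parameter defaults

Several numerical details of the published formulation are hidden in
figures we could not recover, so the package fixes them as documented,
overridable defaults:

* locality weights: 0.9 at separation 1, 1.0 beyond (`locality_weights`);
  only the direction of the correction (down-weight local contacts) is
  established, so the default is deliberately mild;
* residue budgets: $B_{lo} = \max(1, L_i - 2)$, $B_{hi} = 2 L_i$; the
  upper bound is the geometric two-face maximum, the lower bound encodes
  "partners of similar length";
* non-local threshold $j - i \geq 3$, with two extra bridging terms
  $(i, j-1)$ and $(i+1, j)$ admitted to the support set exactly at the
  threshold separation — at that distance a single intervening contact
  already brings the pair together;
* neighbour resolution is circular (the neighbour before strand 1 is
  strand $N$) and skips strands shorter than 4 residues
  (`min_neighbor_length`), which are too small to anchor non-local
  scaffolding;
* the hydrophobic set is {A, V, L, I, M, F, W, C, Y};
* the interlock condition is enforced as *at least one* interlocking
  partner inside the model, with a post-hoc flag for contacts in more
  than one interlock: an exactly-one constraint over quartic index sets
  would explode the model for no predictive gain.

For two contacts of the same strand and orientation, "sharing a residue"
and "overlapping aligned intervals" coincide because alignments are
gapless and footprints therefore contiguous; the
`strict_residue_sharing` switch is kept for interface stability but does
not change behaviour for gapless registers.

## The solver

No integer-programming library is part of the package's dependency
footprint; model sizes here are tens of binaries, so the package ships a
small exact branch-and-bound solver for 0/1 linear programs
(`solve_binary_program()`, C++ core). It prunes on row-activity
intervals, propagates forced assignments to a fixpoint, and bounds the
objective by the best still-selectable positive coefficients under the
global contact-cardinality cap. The search order is fixed, so results
are deterministic; exactly tied optima are returned in discovery order
and share objective values, which is how tie groups should be read in
the ranked output. With zero optimality gap and a single thread, a
25-deep ranked list for an 8-strand protein solves in under a second.

## The potential

The published pipeline consumed trained residue-pair pseudo-potentials
that are not reproducible from the paper; the optimization layer is
therefore potential-agnostic. `default_potential()` ships a transparent
hydrophobicity-sum propensity (scaled Kyte-Doolittle, symmetric 20x20),
adequate for exercising the machinery and for fixtures; any symmetric
20x20 TSV is accepted (`read_potential_table()`), and serious prediction
work should supply a trained table. Non-standard residues map to `X` and
score 0 against everything regardless of the table.

## Synthetic fixtures: what they do and do not show

`make_fixture()` builds proteins with known ("planted") topologies:
strand lengths 3-8, loops 2-5 residues of low-scoring polar types,
strand residues alternating hydrophobic/polar as in real edge-on
strands, and a ladder of adjacent contacts with random orientations
(optionally one interlocked non-local antiparallel pair for $n \geq 5$,
the sandwich motif). The matched table starts from a weakly negative
background and raises the residue-type pairs realized by planted
contacts by 2.0 score units per pair. The generator redraws
deterministically until the planted topology passes the full validator
and — for ladders up to 6 strands — until every planted contact strictly
out-scores every alternative, which makes the planted ladder the unique
optimum and gives an exact recovery target. Beyond 6 strands (and for
interlock fixtures) strict dominance is not constructible over a
20-letter alphabet, so only feasibility is guaranteed.

Fixtures emulate the *combinatorial* structure of the problem, not its
biology: scores are planted rather than learned, strands have no
bulges, registers are exact, and loops carry no signal. Passing the
recovery and oracle-equivalence suites therefore demonstrates that the
optimization, constraint and ranking machinery is correct — it says
nothing about predictive accuracy on real proteins, which is entirely a
property of the supplied potential.

## Verification strategy and problem sizes

Three independent routes are compared in the test suite:

* the model + branch-and-bound route (`solve_ranked()`);
* exhaustive enumeration of all contact sets filtered through the
  post-hoc validator (`brute_force_rank()`), tractable to 6 strands;
* the closed-form motif count against full motif enumeration to
  $n = 7$.

The suite checks ranked-objective equality of the first two routes on 51
seeded fixtures at $n \in \{3,4,5\}$ with $K = 5$, planted-topology
recovery on 50 fixtures at $n = 4$, two-colorability against exhaustive
coloring on 1000 random contact graphs of up to 12 contacts, and the
evaluation formulas (precision, recall, Matthews correlation with fixed
zero-denominator conventions: precision/recall 0, MCC 0, flagged in the
output) on enumerated confusion tables. These sizes keep the default
suite to a few minutes while covering every constraint family; all
bounds are exact, so scale affects coverage, not correctness.

## Degenerate inputs and numerical conventions

Scores are compared with an absolute tolerance of 1e-9 throughout; offset
ties in alignment break toward the smallest absolute offset, then the
smaller signed offset. Proteins with fewer than 3 strands are refused
(single-pair "sheets" are not topologies in any useful sense). Strands
of length 1 are parsed faithfully but merged into coil before modelling
(`min_strand_length`, default 2). If rounding empties the hydrogen-bond
window — possible for very small proteins — the window collapses to the
nearest integer with a warning. A strand with no alignable partner makes
the one-contact-per-strand requirement unsatisfiable and is diagnosed by
name at model-build time.

## Known limitations

* Beta-barrels are excluded by construction, exactly as in the published
  formulation.
* Alignments are strictly gapless: beta-bulges shift registers in real
  sheets and are not modelled.
* The default potential is a hydrophobicity heuristic; headline accuracy
  on real data requires a trained pair potential.
* `brute_force_rank()` is exponential and capped at 6 strands; it is an
  oracle, not a production path.
* Evaluation counts strand pairs, not residues; `aligned_pair_accuracy()`
  adds an exact-register criterion restricted to correctly predicted
  pairs.
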