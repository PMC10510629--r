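---
title: "Disconnection-aware route planning: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disconnection-aware route planning: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroplan)
```

## The problem

Retrosynthesis planning works backwards from a target molecule, repeatedly
replacing a product by plausible precursors until every leaf of the growing
route tree is a purchasable building block. Sequence-to-sequence
retrosynthesis models are usually asked an under-determined question —
"what could this molecule be made from?" — and tend to concentrate their
probability mass on one or two obvious disconnections. The approach
implemented here inverts that control: the *user* (or an enumeration
strategy) marks the atoms where the disconnection should happen, and the
single-step model is conditioned on that choice. Marking is done in a small
SMILES dialect: each candidate reactive atom's token is followed by a `!`
token, so `CC(=O)O!CC` asks for a disconnection at the ester oxygen of
ethyl acetate. Because the tag is a separate token, the atom's own token is
unchanged — hydrogen counts, charges and stereo markers are untouched — and
deleting every `!` recovers the untagged SMILES byte for byte.

This package implements the full orchestration around that idea as running,
testable code: tagged-SMILES handling, reaction-center identification from
atom-mapped reactions, template mining, systematic/template/model site
enumeration, a forward-validated single-step loop behind pluggable
predictor contracts, route scoring, and a memoized best-first multistep
search. The learned models themselves are out of scope; a deterministic
rule-based toy chemistry stands behind the contracts so that every
algorithmic property can be verified exactly.

## Canonical form and the tagged dialect

One canonicalization routine (`canonicalize()`) is used everywhere:
iterative neighborhood refinement over element, aromaticity, charge,
hydrogen count, isotope, ring membership, degree and the atom's distance
spectrum, with ties broken by promoting one member of the smallest tied
class. Atom-map labels never enter the invariant, so mapped and unmapped
forms of a molecule receive the same atom order, which is what lets
`maplabels_to_tags()` carry reacting-atom labels onto canonical tag
positions. Tagged positions are always expressed in canonical atom order,
so equality of tagged molecules is string-comparable — a requirement for
deduplicating sites proposed by different strategies.

Two normal forms coexist deliberately:

* the *serialized form* (`serialize_tagged()`) keeps the untagged canonical
  atom order and inserts `!` tokens, so tag removal is the exact untagged
  SMILES;
* the *symmetry key* (internal) recomputes a canonical labeling with the
  tag flag participating in the invariant, so topologically equivalent
  placements (either terminal carbon of propane, any CH of benzene)
  collapse to one key. Deduplication uses the key and keeps the
  lexicographically smallest serialized representative.

Tetrahedral stereocenters are preserved through every reordering by parity
correction of the `@`/`@@` symbol. Double-bond geometry tokens (`/`, `\`)
are accepted on input but read as plain single bonds; the generator never
emits them, and routes through stereo-defined alkenes would need that
support before real-world use. Ring-closure digits precede the `!` token;
the grammar is one consistent, reversible choice.

## Reaction centers and templates

For an atom-mapped reaction with a single product, an atom is *reacting*
when its environment differs between its starting-material occurrence and
its product occurrence: any change in the neighbor multiset (element and
bond order), formal charge, or total hydrogen count, plus any product atom
whose label never occurs on the reactant side. This operationalizes
"environmental change" as a reproducible, toolkit-independent diff; an
independently written brute-force version of the same definition backs the
test suite.

A *tagging template* generalizes one reaction's center: the product
substructure induced by the reacting atoms plus all atoms within a
conditional radius (1–3 bonds), with atoms typed by element, aromaticity,
charge, ring membership and degree — the minimal typing that separates the
radius tiers without collapsing chemically distinct environments. Mining
merges identical environments, counts support, and keeps templates with
support at least 2 and 1–10 reactive atoms. Application is subgraph
matching (VF2, with an induced-match post-filter) followed by symmetry
deduplication; templates only *tag* atoms, they never rewrite structures.

## Site enumeration

Three complementary strategies feed the single-step loop:

* **systematic** — every single atom, bonded pair, and connected triplet
  (path or three-membered ring), collapsed by symmetry;
* **template** — mined templates at radius 2 by default;
* **model** — a learned tagger behind the `tagger_model()` contract, beam
  50 by default; suggestions that do not re-canonicalize to the query
  molecule are dropped and counted.

The default combination (systematic + template radius 2 + model beam 50)
follows the configuration that worked best in the study this design
derives from. Sites are deduplicated up to molecular symmetry *before*
prediction — the cheaper place — and validated steps are deduplicated
again afterwards; per-strategy provenance flags survive the merge so
Venn-style diagnostics of strategy overlap remain possible.

## The single-step loop and its contracts

For each tagged variant, the retro contract (T1) proposes up to `beam_t1`
starting-material sets; each is combined with up to `beam_t2` reagent sets
from the reagent contract (T2); the forward contract (T3) then predicts the
product of each (SM, R) combination. A step is kept only when T3's top-1
prediction equals the query product — canonical string equality with
stereochemistry included, the strictest reading of forward validation — and
the step's confidence is T3's score. Among validated reagent alternatives
for one SM set the highest forward confidence wins; steps whose SM set
contains the product itself are rejected as no-ops. Default beams are
B = B' = 3, a balance of recall against the cubic growth of forward calls;
`min_confidence` exists as a filter but defaults to 0 so that route
ranking, not a hard threshold, decides.

All contracts must be pure: identical inputs give identical outputs, with
scores in (0, 1] sorted descending — scores multiply into route products,
so a product-stable range is load-bearing, not cosmetic.

## Route scores

For a route of $N$ steps with forward confidences $CS_i$ and starting
materials $\mathrm{SM}_i$:

$$\mathrm{RPScore} = SP^{\,N}\cdot\prod_i CS_i \cdot
  \prod_{m \in \bigcup_i \mathrm{SM}_i} \mathrm{Simplicity}(m),
  \qquad \mathrm{CScore} = \prod_i CS_i .$$

The step penalty $SP$ defaults to 0.8, so a one-step route with unit
confidence through building blocks scores exactly 0.8 and a two-step one
0.64; shorter, more confident routes through simpler intermediates always
rank higher, and extending a route strictly decreases its score whenever
$SP < 1$. Reagents are excluded from the simplicity product, and each
distinct molecule is counted once even when two branches share it
(`count_duplicates` preserves the per-occurrence alternative; double
counting would over-penalize branch sharing). The final target's own
simplicity does not enter — only starting-material-side molecules do.

Simplicity maps a synthetic-complexity score $c \in [1,5]$ linearly to
$1-(c-1)/4 \in [0,1]$, and a building-block member is 1 by definition. The
complexity scorer is pluggable; the shipped default is a deterministic
heuristic — a clipped linear function of heavy-atom count, ring count
(cyclomatic number) and stereocenter count — chosen so the package runs
with no trained weights while any learned complexity model with the same
signature and range can be swapped in through the configuration.

## Multistep search

The search tree is an AND-OR structure over molecules and validated steps.
Each iteration: enumerate all routes of the current tree (one step selected
per expanded molecule, consistently across branches; acyclicity excludes
any step that re-creates an ancestor), rank them by RPScore, take the top
`expansion_width` (20) unsolved routes, and expand their open non-building-
block leaves with the single-step loop. Results are memoized per canonical
SMILES, so a molecule reached through several routes is predicted once and
the steps appear wherever it occurs. Molecules that produce no validated
step are dead and prune every route through them. The loop stops at
`min_solved` solved routes (10), at `max_iterations` (10), or when nothing
expandable remains — in the last case with an exhaustion flag rather than
an error.

Route enumeration is exhaustive up to a cap (10 000 routes, flagged when
hit), generated depth-first with steps in descending-confidence order;
per-molecule results are capped at the 50 most confident steps. Both caps
are configuration, not hard-coded truth: at the problem sizes this package
targets they never bind, and an exact brute-force enumeration oracle backs
the implementation in the tests. Because expansions only ever add steps,
the best solved RPScore is non-decreasing over iterations (an anytime
property the suite asserts). Ties in ranking break by fewer steps, then by
the route identity key — the sorted list of `product => sorted SM set`
step keys, which also deduplicates routes across iterations.

## The toy world

The synthetic generator builds a closed molecule universe from three
bimolecular condensation-style rules — ester formation (acid + alcohol),
amide formation (acid + primary amine) and ether formation (alcohol +
alkyl bromide) — over a small library of mono- and bifunctional building
blocks (acids, alcohols, symmetric diols and diacids, amines,
amino-alcohols, hydroxy-acids, bromides). Bifunctional blocks are what
gives depth: a monoester of a diol keeps a free hydroxyl for the next
step. Rules carry fixed reagent sets and base confidences (0.95 / 0.90 /
0.85), so forward scores are deterministic.

Design points that matter for interpreting test results:

* **Unique-outcome filter.** A reaction is recorded only when the rule
  applied to that reactant pair has exactly one possible product over all
  site and role assignments, so the forward model's top-1 is well defined
  and every corpus reaction round-trips at noise 0.
* **Ground truth.** Minimum route lengths are computed by an exhaustive
  dynamic program over all rule disconnections — independent of the search
  being tested.
* **Atom maps for free.** Products are built by graph surgery on mapped
  reactant graphs, so corpus reactions are perfectly atom-mapped; the
  template miner sees idealized mapping, not the noisy output of a mapping
  model.
* **Noise mode.** The forward mock can corrupt a deterministic
  pseudo-random fraction of calls (hash of the inputs and the seed), which
  keeps contracts pure while letting filtering statistics be tested
  against exact binomial intervals.

What the toy world does **not** emulate: reactivity conflicts
(chemoselectivity beyond the motif definitions), protecting-group
chemistry, reaction yields, stereoselective transformations, and the
ambiguity of learned predictors whose beams contain near-duplicates.
Passing tests therefore demonstrate the correctness of the orchestration —
tagging, validation, scoring, memoization, search — not the chemical
accuracy any particular model backend would deliver on real molecules.

## Numerical and degenerate-input choices

* Confidence scores live in (0, 1]; a zero score is rejected at the
  contract boundary.
* All ordering is deterministic: descending score/support, then
  lexicographic on canonical strings.
* An untagged string is an error in `parse_tagged()` unless
  `allow_untagged` is set — silently accepting one would hide a tagging
  failure upstream.
* Multi-fragment (dot-separated) products are rejected for tagging and in
  reaction records; the corpus contract is single-product reactions.
* A reaction with an empty reacting set (an identity reaction) is skipped
  and counted, not an error: corpora contain such records.
* A building-block target returns a trivially-solved report with zero
  predictor calls; a zero iteration budget returns the unexpanded root.

## Problem sizes

The test suite and the reproduction script run entirely on generated toy
worlds: 16 building blocks, 10–15 recorded reactions per depth level,
generation depths 1–3, and twenty seeded worlds for the search study —
sizes chosen so the whole suite exercises every property in a few minutes
on one core while still producing branched, multi-route search trees. The
same code paths accept arbitrarily large building-block files and reaction
corpora; only the mock predictors are toy.

## Known limitations

* Aromaticity perception covers benzene/pyridine-type six-rings and
  furan/pyrrole/thiophene-type five-rings (iterated for simple fused
  systems); exotic aromatic systems should be supplied in aromatic SMILES
  form.
* No E/Z double-bond stereochemistry.
* The heuristic complexity scorer is a stand-in ranking device: it orders
  molecules by size and decoration sensibly but carries no learned notion
  of synthetic accessibility.
* Route enumeration is exact rather than lazily best-first; the cap plus
  confidence-ordered generation keeps it tractable at the intended scale,
  but pathological trees with thousands of interchangeable steps would
  need a priority-queue generator.
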