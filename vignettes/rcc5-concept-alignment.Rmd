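---
title: "Aligning conflicting phylogenomic hierarchies with RCC-5"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning conflicting phylogenomic hierarchies with RCC-5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcc5align)
```

## The problem

Independent phylogenomic studies publish conflicting hierarchies over
overlapping sets of organisms, and the names they use are unreliable
carriers of meaning across studies: the same name can label different
clade concepts ("Pelecaniformes" including or excluding the
cormorants), different names can label congruent concepts ("Strisores"
vs "Caprimulgimorphae"), and many well-supported nodes carry no name at
all. `rcc5align` treats every *usage* of a name as a source-qualified
concept (`2015.Neoaves` is never "the same thing" as `2014.Neoaves`)
and asks a reasoner to work out how the concept *regions* of two
sources relate.

The vocabulary is the five base relations of Region Connection Calculus
(RCC-5) between nonempty regions: congruence `==`, proper inclusion
`>`, inverse proper inclusion `<`, overlap `><`, and exclusion `!`.
Uncertainty is expressed by disjunctions over these five; the 32
subsets form a lattice from the empty (contradictory) set to the
uninformative full disjunction.

## Inputs and the coverage constraint

An alignment problem consists of:

* one rooted parent/child concept tree per source, each parent carrying
  a **coverage** flag: under coverage, the parent's region is exactly
  the union of its children's regions;
* **articulations**: expert-asserted RCC-5 relations (possibly
  disjunctive) between concepts of different sources.

Phylogenomic studies sample exemplar species rather than full faunas,
so strict coverage makes differential sampling propagate upward as
spurious exclusion: if no sampled parrot species is shared, the two
order-level parrot concepts come out disjoint. Relaxing coverage
*locally* (the `nocoverage` directive) materializes a nonempty residue
concept `nc_<parent>` — "the parent beyond its sampled children" —
which models an *intensional*, property-based node definition: the
parent can then attain congruence with the other source's parent in
spite of incongruent children. The residue is an ordinary concept: it
is counted in result tables and can be related to other concepts.

```{r parrots}
strict <- fixture_psittaciformes("strict")
glance(align_concepts(strict))["n_exclusive"]
relaxed <- fixture_psittaciformes("relaxed")
tidy(align_concepts(relaxed)) |>
  dplyr::filter(relation == "==")
```

## How the reasoner works

After residues are materialized every parent region is a union of
terminal regions, so a set-interpretation of the whole problem is
determined by which cells of the product grid

(terminals of source 1 + "outside") x (terminals of source 2 + "outside")

are nonempty; each nonempty cell ("atom") contributes one anonymous
point of the universe. Sibling disjointness (on by default; switchable
for non-tree classifications, at considerable cost) is what makes this
grid a faithful basis. Every constraint then reduces to one of two
monotone forms — *these atoms are empty* (inclusions, congruences,
exclusions) or *at least one of these atoms is nonempty* (concept
nonemptiness, proper-inclusion residues, overlap witnesses) — and such
a system is satisfiable exactly when the maximal assignment (all
non-forced atoms nonempty) satisfies every at-least-one set. This gives
sound and complete consistency checking; disjunctive articulations are
handled by branching over their base-relation choices.

Three services are built on this test:

* `check_consistency()` reports a witness model, or (for inconsistent
  input) a minimal conflicting articulation subset found by
  deletion-based minimization (attempted below a configurable
  articulation count — the diagnosis is a convenience, not part of the
  semantics). When the number of disjunction branches exceeds a limit
  the outcome is an explicit "undecided (limit)", never a silent
  answer.
* `enumerate_worlds()` enumerates distinct possible worlds, where two
  worlds are the same iff their *signatures* — the matrices of realized
  base relations over all concept pairs — are equal. A well-specified
  alignment narrows to exactly one world.
* `infer_mir()` computes the **Maximally Informative Relations**: for
  every cross-source pair, the set of base relations realizable in at
  least one world, i.e. relation `r` is in the entry iff the problem
  plus "left `r` right" is consistent. The MIR covers *every* pair
  (residues included), so a two-tree problem always yields
  `|C_A| * |C_B|` entries.

Three backends implement the same contract. The default is a counting
path for two-tree problems with single-base articulations: it
aggregates allowed-atom counts per concept pair once and answers each
of the five entailment queries per pair in time proportional to the
number of concepts, which is what makes 148 x 22- and 97 x 83-concept
alignments run in seconds. The generic per-query path handles
disjunctive inputs, more than two trees, and relaxed sibling
disjointness. The exhaustive backend enumerates every emptiness pattern
of the atom space and evaluates each constraint directly on the witness
sets; it is the reference oracle, and the test suite asserts that all
backends agree on randomized problems.

## Resolving overlap: whole vs split concepts

Exactly-overlapping pairs are the irreducible conflict. Under
*whole-concept resolution* the region graph keeps input labels and
joins overlapping regions by a dashed edge. Under *split-concept
resolution* each overlapping pair (A, B) is replaced by its three
products — `A * B`, `A \ B`, `B \ A` — which partition the union of
the pair. Products that coincide with an input-labeled region are
redundant synonyms; the remainder name regions that *no* input concept
identifies, and `split_label_census()` counts them, by label
multiplicity. Region graphs are computed from a concrete witness
because pairwise MIR alone does not determine triple-wise
intersections; when several worlds exist the witness used is reported
(the shipped use-case alignment has exactly one world).

```{r zoom}
zoom <- fixture_neoaves_zoom()
al <- align_concepts(zoom)
glance(al)
overlap_matrix(al$mir)$grand_total
census <- split_label_census(
  al$mir, build_regions(zoom, al$mir, al$consistency$witness, "split"))
census
```

## The use-case fixtures

The fixtures reconstruct the published avian use case from in-paper
material only:

* `fixture_tables_1_2()` — the supra-ordinal concept hierarchies of the
  two bird phylogenomies (41 and 37 labeled supra-ordinal concepts),
  with order-level children as terminals. One printed row of the 2015
  table assigns the unnamed clade below Otidimorphae the same two
  children already placed under Columbimorphae_Clade1; this cannot form
  a tree (one concept, two parents) and contradicts both the 2014
  analogue and the conflict-region narrative, so the default tree uses
  the corrected children (Cuculiformes, Otidiformes). The printed
  variant is kept and raises the structural error it deserves.
* `fixture_neoaves_zoom()` — the conflict region below the two Neoaves
  concepts, 21 concepts per source, with terminal articulations
  asserting congruence for the eleven pairs named congruent in the
  narrative and exclusion otherwise (species/order-level labels are
  treated as reliable indicators of congruence-or-exclusion). Coverage
  holds globally here, so all 26 overlaps are genuine topological
  conflict. This alignment has exactly one possible world.
* `fixture_psittaciformes()` — the parrot example in both coverage
  variants. The sources' species lists are only partly printed; the
  unprinted exemplars are synthesized placeholders with a fixed naming
  scheme (`Psittacidae_gen1_sp1` ...), documented as such. Counted
  results (108 and 160 MIR) depend only on the concept counts, which
  follow the published figure caption. In this reconstruction both
  order-level concepts sit above single-child family chains, so order
  and family coincide extensionally and the three asserted congruences
  merge into two output regions.

## The synthetic generator

`generate_problem()` emulates a partitioned alignment at a chosen
scale: a hidden universe of points, one random hierarchical interval
partition per source, optional relaxed-coverage residues (one reserved
point each), and input articulations asserting the true base relation
for sampled pairs of visible terminals. The hidden interpretation is
returned as ground truth, so generated problems are consistent by
construction and every MIR entry must contain the ground-truth relation
— the basis of the recovery tests. `overlap_rate` controls how often a
split boundary in the second tree ignores the first tree's boundaries
(0 yields congruence/nesting-dominated alignments, 1 fully independent
partitions). Everything derives from a single integer seed;
serialization is byte-identical across runs.

What the generator does *not* emulate: real nomenclatural signal (names
are arbitrary, so name-reliability analyses on generated data are
uninformative), expert-curated relaxation (residues are placed at
random parents), and multi-source chains beyond two trees. Passing
recovery tests on generated data therefore validates the logic, not the
biological judgment embedded in a curated alignment.

The acceptance checks use generated problems at the published partition
sizes — 148 x 22 concepts with seven relaxed parents, and 97 x 83 with
four residues on the second tree — where only the MIR *count* (the
completeness product) is compared; the published split of the seven
relaxed parents across the two sources is not stated, so the generator
places four on the large and three on the small tree.

## Numerical and design choices

* Concepts, including materialized residues, are nonempty; RCC-5 is
  undefined on empty regions. A relaxed parent whose context forces an
  empty residue is therefore reported inconsistent rather than silently
  collapsed.
* `child <= parent` is non-strict: a covered single-child parent is
  congruent with its child.
* World identity is signature equality, not witness-set equality:
  universes are anonymous.
* The five-per-pair entailment queries of the fast path are required
  (and tested) to agree exactly with the generic path; no approximation
  is involved.
* Enumeration limits: possible-world enumeration stops at a caller
  limit with an explicit truncation flag; the exhaustive backend
  refuses atom spaces above 18 atoms; consistency checking declares
  "undecided (limit)" beyond 4096 disjunction branches. Sizes used in
  the shipped tests: backend-equivalence problems of 3-9 concepts per
  tree, recovery problems up to 15 x 11, and the two partition-scale
  runs above (seconds each).
* Split labels are serialized as `A * B`, `A \ B`, `B \ A` with full
  source-qualified labels on both sides, following the use-case result
  tables rather than the lower-case shorthand of the running text.
* The bipartition comparator treats the concordance containments as
  non-strict: identical restricted bipartitions are concordant (a
  strict reading would leave identical edges neither concordant nor
  conflicting, contradicting the congruent backbone of the published
  comparison). Edges whose restricted ingroup has fewer than two tips
  are uninformative. When an edge is concordant with one alternative
  edge and conflicting with another, both flags are reported and the
  summary status lets conflict take precedence.
* Taxonomy grafting of unsampled tips (off by default) attaches each
  unmatched tip below its nearest named taxonomy ancestor present in
  the alternative tree; it exists to reproduce how taxonomy-based
  placement manufactures conflict, not as a recommended analysis.

## Known limitations

* The name-reliability table of the full root-to-order avian alignment
  (97 x 83 real concepts) cannot be reconstructed from in-paper
  material alone; the analysis is validated on the conflict-region
  alignment instead, and runs on any user-supplied MIR CSV.
* MIR is computed for consecutive source pairs; relations across
  non-consecutive sources are only exposed through
  `compose_relations()`.
* The fast path requires sibling disjointness; classifications with
  overlapping sibling groups fall back to the generic path, which is
  exponential in the number of terminals per tree and practical only
  for small problems.
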