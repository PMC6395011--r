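# rcc5align

Logic-based alignment of conflicting taxonomic and phylogenomic concept
hierarchies with the five base relations of Region Connection Calculus
(RCC-5).

## The problem

When independent phylogenomic studies publish incongruent trees over
overlapping taxa, the names they use cannot carry the comparison:
identical names can mean different things across studies, different
names can mean the same thing, and many conflicting nodes are unnamed.
`rcc5align` individuates every name usage as a source-qualified
*concept* (`2015.Neoaves` vs `2014.Neoaves`) and reasons over the
relations between concept *regions*:

| token | relation |
|-------|----------------------------|
| `==`  | congruence |
| `>`   | proper inclusion |
| `<`   | inverse proper inclusion |
| `><`  | overlap |
| `!`   | exclusion |

with disjunctions over these five (a 32-element lattice) expressing
uncertainty. Inputs are per-source parent/child concept trees — each
parent under a *coverage* constraint (parent = union of children) that
can be relaxed locally via `nocoverage`, materializing a nonempty
residue concept `nc_<parent>` that models intensionally defined nodes —
plus expert articulations between sources. The reasoner decides whether
all constraints admit a possible world, enumerates the distinct worlds,
and infers the **Maximally Informative Relations (MIR)**: for every
cross-source concept pair, the set of base relations realizable in at
least one world. Downstream analyses express overlap as whole-concept
or split-concept (`A*B`, `A\B`, `B\A`) resolution regions, tabulate
overlap matrices and clade-name reliability, and annotate rooted
bipartition concordance/conflict between trees in the style of
supertree synthesis tools.

The package ships deterministic fixtures reconstructing the
neoavian-explosion use case (two conflicting avian phylogenomic
hierarchies) from published concept tables, and a seeded random
generator of alignment problems with known ground truth.

## Worked example

Align the most conflicting region of the two bird phylogenies — the 21
concepts below each source's Neoaves:

```r
library(rcc5align)
zoom <- fixture_neoaves_zoom()
al <- align_concepts(zoom, worlds_limit = 5)
al
#> <rcc5 alignment> 21 x 21 concepts, 441 MIR entries; 26 overlapping, 13 congruent clusters
#>   possible worlds: 1
```

The alignment is fully determined (one possible world). Its 441 MIR
entries contain 13 clusters of congruent concepts (e.g.
`2015.Strisores == 2014.Caprimulgimorphae`) and 26 overlapping pairs —
the irreducible topological conflict, summarized as a matrix:

```r
overlap_matrix(al$mir)
#> <overlap matrix> 26 overlapping pairs (8 x 8 concepts)
#>                               2014.Passerea 2014.Columbea ... Totals
#> 2015.Aequorlitornithes                   ><            ><          6
#> 2015.Aequorlitornithes_Clade1            ><            ><          5
#> 2015.Neoaves_Clade3                      ><            ><          5
#> ...
#> Totals                                    6             5         26
```

The unnamed "waterbird" clade sequence of the 2015 source drives most
of the conflict:

```r
chain_overlap_count(al$mir, paste0("2015.", c(
  "Neoaves_Clade3", "Aequorlitornithes", "Aequorlitornithes_Clade1")))
#> [1] 16
```

Under split-concept resolution the 26 overlaps generate 78 product
labels, of which 21 identify 15 output regions that no input concept
names:

```r
regions <- build_regions(zoom, al$mir, al$consistency$witness, "split")
split_label_census(al$mir, regions)
#> <split-concept label census>
#>   total labels:    78
#>   synonyms:        57
#>   novel regions:   15 (11 uniquely, 4 redundantly labeled; 21 labels)
```

Coverage relaxation in one call: with coverage applied globally the two
differentially sampled parrot hierarchies come out mutually exclusive,
while relaxing four lower-level parents yields the intuitive
higher-level congruences:

```r
rel <- align_concepts(fixture_psittaciformes("relaxed"))
dplyr::filter(tidy(rel), relation == "==")
#> # A tibble: 5 × 6
#>   left                right               relation  mask left_nc right_nc
#> 1 2015.Psittaciformes 2014.Psittaciformes ==           1 FALSE   FALSE
#> 2 2015.Psittacidae    2014.Psittaciformes ==           1 FALSE   FALSE
#> 3 2015.Psittaciformes 2014.Psittacidae    ==           1 FALSE   FALSE
#> 4 2015.Psittacidae    2014.Psittacidae    ==           1 FALSE   FALSE
#> 5 2015.Nestor         2014.Nestor         ==           1 FALSE   FALSE
```

`tidy()`, `glance()` and `autoplot()` give the MIR table, a one-row
summary, and a relation heatmap; `write_mir_csv()` / `write_dot()`
export tables and styled alignment graphs. A thin command-line wrapper
(`inst/cli/rcc5align.R`) exposes `align`, `fixtures`, `otol`, `names`
and `overlaps` subcommands over the same functions.

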