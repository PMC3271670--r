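---
title: "The DCJ-substitution distance: model, algorithm and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DCJ-substitution distance: model, algorithm and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjsub)
```

## The model

`dcjsub` compares two genomes given as signed gene orders over linear
and circular chromosomes, with no duplicated markers.  Markers present
in both genomes are *common*; the rest are *unique* to one genome.  Two
operations are counted, both with unit weight:

* a **DCJ** cuts the current genome at two positions and rejoins the
  four open ends differently (special cases use a telomere, join two
  telomeres, or split one adjacency into two telomeres).  This one
  operation realises inversions, translocations, fusions, fissions, and
  circular excisions/integrations.
* a **substitution** replaces one contiguous block of unique markers in
  a single adjacency by another block.  Either block may be empty, so
  insertions and deletions are special cases; a whole chromosome may be
  substituted at once, but never a linear one by a circular one or back.

A substitution is not meant as a single mutational event; it stands for
a region under continuous local change whose content differs between
the genomes.  Counting it as one step makes the distance a parsimonious
lower bound for any evolutionary history; conversely, because only
unique markers can be substituted, the distance cannot collapse to a
trivial rewrite of one genome into the other.  The price is that the
measure is not a metric: `test-acceptance.R` constructs a triple
`d(A,C) > d(A,B) + d(B,C)` by routing through a genome that shares no
markers with either side.

## The computation

The pipeline mirrors the structure of the closed form:

1. **Partition** the markers (`partition_markers`), build the labeled
   adjacencies of each genome (`build_adjacencies`) and the adjacency
   graph (`build_graph`), and classify components (`components`).
   `d_DCJ = n − (c + b/2)` (`dcj_distance`); the AB-path count is even
   by parity and the code asserts rather than rounds.
2. **Runs and potentials** (`component_runs`, `indel_potential`,
   `substitution_potential`).  Runs are counted from the genome tags of
   non-empty labels along the component walk, merging equal neighbours;
   for cycles the merge is circular, which makes the count independent
   of the starting vertex, so no explicit starting rule is needed.
   AB-paths are walked from their genome-A endpoint.  The closed forms
   are `λ = ⌈(Λ+1)/2⌉` and `σ = ⌈λ/2⌉` for `Λ ≥ 1`, zero otherwise; the
   tests certify `σ = 0/1/1/2` for `Λ = 0/1/2/4` by exhaustive search
   over real operation sequences.
3. **Singletons.**  Whole chromosomes of unique markers are singletons.
   Circular singletons can never take part in a recombination (they are
   not paths), so their pairing is exactly `P_C = min(#A, #B)`.  Linear
   singletons are degenerate AA-/BB-paths with one run; they enter the
   recombination pool, where pairing one from each genome (one
   whole-chromosome substitution, saving one step) competes with their
   use as recombination sources.  The optimiser decides; in every tested
   configuration the two uses tie or pairing wins, consistent with
   computing `P_L` by the minimum rule.
4. **Recombination groups.**  Recombinations between two labeled paths
   are enumerated at the level of run sequences by
   `recombination_rows`: each path's tag sequence is split at a
   between-run boundary (or joined whole at a telomere), the pieces are
   exchanged both ways, and equal tags merge at the junction; cut
   positions and telomeres are constrained to the acting genome, which
   is what makes linear singletons special.  This splicing engine was
   validated exhaustively against operation-level enumeration on
   constructed instances: for every ordered pair of the 23 path classes
   and run-count indices `i ∈ {0, 1}` (966 combinations, plus all
   singleton pairings) the generated rows coincide exactly with the set
   of real DCJ recombinations and their effects.
   `deduction_search` then maximises the total saving over sequences of
   distance-non-increasing rows plus singleton pairings, and
   `group_counts` decomposes one optimal sequence into the classical
   groups: `U` (the unique recombination saving 2 in one step,
   sources AA:E4 + BB:E4), `V` (chains saving 3), `W` (two-step chains
   saving 2), `X` (single recombinations saving 1), `Y` (chains through
   a distance-neutral recombination, saving 2) and `Z` (chains saving
   1), with `deduction = 2U + 3V + 2W + X + 2Y + Z`.

### Why a search instead of a fixed greedy order

The groups are classically counted by a greedy pass in the order
`U, V, W, X, Y, Z`.  With the complete rule set this order is not
always safe: for example, from
`{AB:A4, AB:A4, AA:B1, BB:A1}` the maximal `X` step would pair
AA:B1 with BB:A1 for a saving of 1 and strand the two AB-paths, while
the `Y` chain (recombine the AB-paths into AA:A3 + BB:B3, then resolve
both) saves 2 — and from `{AB:A4, AB:A4, AB:B4, AB:B4, AA:B1, BB:A1}`
the preference reverses.  `dcjsub` therefore computes the deduction as
an exact optimisation and reports the group decomposition of an optimal
solution; the acceptance suite checks it against an independent
exhaustive enumerator over the shipped rule table on random class
multisets.

### State-space reductions in the optimiser

Three reductions keep the exact search near-linear for realistic
inputs; each is validated rather than assumed:

* **Run-count cap.**  A path's available rows depend on its kind, first
  run, and run count only up to `Λ = k + 4` (writing `Λ = 4i + k`):
  rows are uniform in `i` beyond the first index, which was checked by
  the generator-versus-enumeration sweep at `i ∈ {0, 1}`.  Tokens are
  collapsed accordingly.
* **Dead resultants.**  AB-paths whose run count is not a positive
  multiple of four can never act as a source of any useful row (they
  are the `•` resultants of the group tables); they are dropped from
  the pool, as are clean paths and cycles, whose recombinations were
  verified never to create usable sources or negative distance changes.
* **Neutral-row filter.**  Distance-neutral rows are kept only when
  they can feed a later saving: when a source is a 4k-run AB-path, or
  an AA + BB pair creates one.  All chains found by closure scans (no
  irreducible synergy group has more than four sources) are of this
  shape.

The number of labeled *paths* is bounded by twice the chromosome count,
so the pool is small for real genomes regardless of how many markers
they carry; the overall computation is linear in genome size with a
component bounded by the labeled-path pool.

## The rule table

`inst/extdata/recombination_rules.tsv` records the class-level summary:
all 31 recombinations with `Δd ≤ −1` (one saving 2, thirty saving 1),
the 28 distance-neutral recombinations that create sources for them,
and the group chains `U..Z` with their source multisets, total `Δd` and
per-path score.  The table is generated from the operation engine, and
`load_rule_table` re-validates every pairwise row against that engine
at load time, alongside the delta arithmetic
(`Δd = Δσ + Δ_dcj`), the `Δσ ≥ −2` bound, and closure of table 1 under
swapping the roles of the two genomes — so a corrupted table cannot be
loaded silently.

## The brute-force oracle

`oracle_distance` certifies the closed form on small instances by
breadth-first search over genuine genome states: all DCJs (generated
from the adjacency-set form of the genome), plus substitutions whose
removed block is a contiguous block of markers absent from the target
and whose inserted content is *any* signed arrangement of absent
target-unique markers.  The arrangement freedom matters: an optimal
scenario may insert markers in an order that only later DCJs turn into
the target order, so restricting insertions to blocks that appear
contiguously in the target loses optimal scenarios (a circular
intermediate whose wrap-around joins the two ends of a linear target
chromosome is the smallest example).  The search is exact; a state is
pruned only under an admissible bound: DCJs fix at most two projected
common-marker adjacencies and never change content, substitutions fix
content and never the projection, so
`remaining ≥ ⌈missing/2⌉ + [content differs]`.

The acceptance suite certifies the distance formula against this oracle
on 200 seeded instances with up to 4 common and 3 unique markers (the
oracle is given exactly the formula's value as its depth budget, so it
either exhibits a scenario of that length and the absence of shorter
ones, or refutes the formula), and a DCJ-only variant confirms the
common-content reduction.

## The simulator

`random_genome_pair` draws an ancestor over the common and A-unique
markers (signed, shuffled, split over the requested chromosomes, with
the A-unique markers laid out as the removal blocks), then derives the
second genome by the prescribed number of substitutions — which jointly
remove every A-unique marker and introduce every B-unique one — and
random DCJs.  `n_dcj + n_subst` bounds the true distance, giving every
simulated instance a built-in sanity check.  With `circular = TRUE` all
chromosomes stay circular, which makes the pair co-tailed and the
separate-sorting bound exact — the regime used to exercise the
co-tailed equality.

What the generator does *not* emulate: duplicated markers (outside the
model), realistic chromosome numbers or marker counts of specific
taxa, and length- or position-biased rearrangements.  Passing tests
demonstrate correctness of the distance computation under the model,
not the biological fidelity of the model itself.

## Problem sizes used by the tests

The certified comparisons run at the scale where exhaustive search is
exact and fast: oracle instances use at most 7 distinct markers;
property sweeps use 100–500 seeded simulator draws with up to 7 common
and 3 + 3 unique markers; group-counting comparisons use random
multisets of up to 6 labeled paths, with genome-level exhaustive checks
on two-path instances.  The closed form itself has no such limits.

## Known limitations

* Distances only: no optimal scenario is reported, and the operation
  sequence reconstructed internally for group counting is not exposed.
* Genomes with duplicated markers are rejected, not approximated.
* The exact group optimisation is worst-case exponential in the number
  of labeled paths of recombination-relevant classes; this number is
  bounded by twice the chromosome count and is tiny in practice, but
  adversarial inputs with very many labeled paths would be slow.
* The triangle inequality does not hold for this distance; downstream
  uses that need a metric must post-process.
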