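---
title: "Delineating maximal homologous groups without annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating maximal homologous groups without annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homolograph)
```

## The problem

Phylogenomic studies of bacteria conventionally treat annotated marker
genes as the unit of evolution, assuming each gene is homologous — and
recombination-free — across its whole length.  Horizontal transfer,
duplication/loss and gene fission or fusion break that assumption at
every scale from a single base to whole operons.  `homolograph`
partitions a set of genome assemblies, with no annotations at all, into
**maximal homologous groups (MHGs)**: maximal sets of maximum-length
genome subsequences whose evolutionary history is a single tree with no
internal rearrangement.  Member sequences may be orthologous or
paralogous; duplications contribute several members from one genome, and
losses simply leave a genome out of a group.

## The algorithm

The input is a set of pairwise local alignments: either BLASTN tabular
output (`-outfmt "6 qseqid sseqid qstart qend sstart send bitscore qseq
sseq"`), or, for small inputs, the built-in exact aligner.  The stages
are:

1. **Relative bit-score filtering.**  For each genome the maximum
   self-alignment bit score is taken as a reference; alignments scoring
   below a configurable fraction of the reference of their query's
   genome are excluded, as are trivial full-length self hits.  The
   fraction defaults to 0.05 and is deliberately permissive so that
   divergent homologs survive; it is exposed as `bitscore_fraction`.
2. **Pile-up.**  Per genome, strictly overlapping alignment intervals
   are unioned into non-overlapping node ranges; abutting intervals are
   *not* merged, since an abutment is a boundary, not shared coverage.
   Each range seeds one initial single-sequence group.
3. **Alignment graph.**  Nodes are the ranges; one edge per alignment
   joins the two ranges containing its query and subject segments
   (parallel edges and self loops allowed).  Connected components bound
   all merging, so components can be traversed independently.
4. **Edge traversal with breakpoint propagation.**  Alignments are
   stored with two bit arrays, one per side, where 1 marks a residue
   and 0 a gap column.  A breakpoint at a genome position is carried
   across an alignment by counting residues: find the leftmost column
   at which the source array has accumulated `pos - start` ones and
   place the destination breakpoint after the ones the destination
   array has accumulated before that column (reflected from the
   destination end for inverted alignments).  For every edge, the
   current group boundaries inside the two aligned spans are mapped
   across until both sides carry the same refinement — each mapped
   boundary splits the group containing it, with the cut propagated
   breadth-first through the group's internal alignment edges so every
   member is cut at the homologous position.  The aligned post-split
   pairs are then merged, flipping member strands when the alignment is
   inverted.  After all edges are visited the groups are the MHG
   partition.

### Numerical and tie-break choices

* Coordinates are 0-based half-open everywhere inside the package;
  1-based formats are converted at I/O boundaries only.
* When a breakpoint lands in a run of destination gap columns it is
  placed before the run (leftmost) — the unique position consistent
  with counting residues strictly before the column.  With this
  convention mapping a breakpoint across an alignment and back is the
  identity whenever the adjacent residue occupies a match column; the
  property suite asserts this.
* Edges are processed in `(component, min node id, max node id, edge
  id)` order.  The fixpoint formulation makes the result independent of
  edge order; the fixed order makes runs bit-for-bit reproducible, and
  there is no explicit recursion stack to bound.
* When two internal paths disagree about where a breakpoint lands on a
  member (possible when overlapping gapped alignments place their gaps
  differently), the minimum position wins and a reconciliation note is
  recorded in `attr(partition, "warnings")`.  Gapless inputs never
  trigger this.
* A breakpoint at an existing boundary is a no-op; zero-length residual
  members are dropped from their side of a split.
* **Maximality repair.**  Overlapping alignments whose extents differ
  by a few bases leave alignment endpoints strictly inside homologous
  runs, which would make groups shorter than maximal (the known
  boundary artifact of seeded local search).  Finalization therefore
  coalesces adjacent groups whose members abut bijectively and
  strand-consistently; such neighbours are one maximal group by
  definition, and this is exactly the grouping the per-base
  transitive-closure oracle produces.
* Finalized groups are reported in a canonical frame (first member on
  the `+` strand) with ids assigned by the first member's
  `(genome, start)`, so identical inputs give identical files.

The engine is single-threaded; components are independent by
construction, so the result does not depend on any threading setting a
front end might accept.

## The built-in aligner

`align_local()` is a seed-and-extend, **ungapped** local aligner meant
for fixtures and examples (a few tens of kb): shared 9-mers seed
diagonals and each seeded diagonal is scanned for all maximal-scoring
segments (Ruzzo–Tompa), on both strands, with deterministic output.
Match/mismatch scores default to +2/-3 and the raw segment score stands
in for the bit score (relative-score filtering is scale-free).  A `gap`
argument is accepted for interface compatibility but unused: real
gapped alignments should come from BLAST tabular input, and the
mutation-free or low-divergence fixtures the aligner exists for need no
gaps.  Homologies shorter than the seed length are invisible; with the
default scoring, a run of random sequence can occasionally extend an
alignment a few bases past a true homology boundary (the maximality
repair and the oracle both absorb this).  Passing a very large negative
`mismatch` restricts output to maximal exact runs, which is what the
boundary-exactness tests use.

## The synthetic-data generator

`simulate_genomes()` plants ancestral block families into genomes with
per-copy loss, duplication, inversion, translocation (random placement
order), point substitution, and fission: a cut point is chosen per
fissioned family and physically applied in a proper subset of the
genomes, so delineation must recover the boundary in *every* genome
from alignment evidence.  Blocks are separated by random spacers whose
bases flanking each copy are guard characters chosen per (family,
boundary, copy) — including complement-awareness for inverted copies
and continuation-awareness at fission cuts — so that exact alignments
stop exactly at planted boundaries for up to four copies per family
(three split copies per cut).  `truth_partition()` converts the event
log into the expected partition; single-member groups are dropped since
they carry no alignment evidence.

What the generator does *not* emulate: realistic base composition (GC
skew, codon structure), indels within homologous blocks, segment-length
heterogeneity within a family, or divergence deep enough to defeat the
exact aligner.  Passing tests on these fixtures therefore demonstrates
the correctness of the graph machinery — pile-up, propagation,
partition, merge, strand handling — not the sensitivity of any
particular external search tool on real, divergent genomes.

An independent check accompanies the generator:
`transitive_homology_partition()` expands every alignment into per-base
correspondences, takes an orientation-aware transitive closure, and
groups maximal parallel runs.  On seeded fixtures the pipeline's
partition equals this brute-force oracle exactly, including fission
boundaries and duplicated members; the acceptance suite runs twenty
such comparisons with 3–6 genomes and 2–10 families.

## Coverage and conflict analytics

`mhg_occurrence()` counts groups per taxon pair; `mhg_base_coverage()`
reports the fraction of a genome (optionally masked to genic or
intergenic space) covered by groups spanning at least `min_taxa`
genomes, which is non-increasing in `min_taxa`;
`classify_mhg_location()` splits groups into gene-only, intergenic-only
and mixed, where "inside genes" means inside the *union* of genic
features so operons and overlapping genes behave sensibly.

For phylogenetic conflict, every tree's internal edges are converted to
bipartition bitmasks over an ordered taxon universe, normalized so each
split has exactly one representation (the side holding the tree's
lowest-index taxon); Robinson–Foulds distances are symmetric
differences of those sets, normalized by `2(n-3)`.
`filter_informative()` implements the three usability rules for
split-support comparison: at least four members, at most one member per
genome, and no internal branch shorter than 0.0005
substitutions/site — strictly less than, so a branch exactly at the
floor is retained.  The floor sits below the reciprocal of a typical
~1.5 kb marker, so shorter branches imply zero mutations and an
unresolvable local topology.  `split_support()` restricts a marker's
and a group's bootstrap trees to their shared taxa (pairs sharing fewer
than four taxa contribute nothing — four is the minimum for a
nontrivial shared split) and tabulates each observed split's bootstrap
frequency in both sources.

## The recombinant-marker simulation study

A marker gene with internal recombination is modelled as a
concatenation of non-recombining components whose true trees form a
chain: each component tree is one random nearest-neighbor interchange
from its predecessor (consecutive trees are always at raw RF 2), a
conservative facsimile of recombination between close relatives.
Sequences evolve under the equal-rates, equal-frequencies model
(Jukes–Cantor); defaults are 15 components of 100 bp (a 1500 bp
marker, matching typical marker length), 10 replicate markers, and 100
bootstrap replicates.

Tree estimation uses neighbor joining on Jukes–Cantor distances with
column-resampling bootstrap — a fast, deterministic desk-scale
estimator rather than full maximum likelihood.  The default base tree
is a random 19-tip pure-birth topology with every branch at 0.05
substitutions/site; both are exposed so a real species tree can be
supplied.

Two properties of this configuration matter for interpreting results.
First, the qualitative pattern of the study reproduces at this scale:
concatenated markers receive much higher bootstrap support than their
100 bp components, and among component-tree branches the true ones are
clearly better supported than the incorrect ones, which the acceptance
suite asserts on medians.  Second, the *magnitude* of marker-tree
error depends strongly on branch lengths.  With uniform 0.05 branches a
100 bp segment carries about five expected substitutions per branch, so
the estimator recovers nearly every component tree exactly and the
marker tree sits at the chain's topological centre; the mean normalized
RF between the marker tree and the true component trees then reflects
chain spread alone (about 0.19 under the defaults).  Substantially
larger mean conflict requires the inference noise that heterogeneous,
partly very short branches of an empirical species tree induce at
100 bp.  Users studying that regime should pass their own base tree via
the `base` argument.

## Problem sizes used by the test and acceptance suites

Fixtures use 2–6 genomes of roughly 1–4 kb with 1–10 planted families
of 100–300 bp; the simulation study runs 10 replicates of 15 × 100 bp
components over 19 taxa with 100 bootstrap replicates.  These sizes
exercise every code path (fission, inversion, duplication, loss,
tandem and interspersed repeats) while keeping a full run in minutes on
one core.

## Known limitations

* The engine holds all components in memory; the per-component
  independence that would allow flushing or parallelism is designed in
  but not exploited.
* The built-in aligner is ungapped and exact-match-seeded; it is not a
  substitute for a heuristic search tool on real divergent genomes.
* Gap-placement disagreements between overlapping gapped alignments are
  reconciled by the leftmost/minimum rule rather than re-alignment.
* Circular chromosomes are treated as linear strings; origin-spanning
  homology is split.
* Quantifying per-branch concordance of species trees (internode
  certainty style measures) and any functional categorization of
  covered genes are out of scope.
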