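# homolograph

Annotation-free delineation of **maximal homologous groups (MHGs)** in
sets of bacterial genome assemblies, with the phylogenetic-conflict
analytics that motivate them.

## Why

Phylogenomic pipelines for prokaryotes usually take annotated marker
genes as the unit of evolution and assume each gene is homologous, and
recombination-free, across its whole length.  Horizontal transfer,
duplication/loss and gene fission/fusion violate that assumption, and —
as the bundled simulation study shows — concatenating segments with
different histories produces confidently supported *wrong* trees.  An
MHG is the alternative unit: a maximal set of maximum-length genome
subsequences whose evolutionary history is a single tree with no
internal rearrangement, computed directly from whole-genome local
alignments with no annotations.

## The algorithm in brief

Given all-vs-all pairwise local alignments (BLASTN tabular with aligned
sequences, or the built-in exact aligner for small inputs):

1. **Filter** alignments whose bit score falls below a fraction
   (default 0.05) of their query genome's maximum self-alignment score;
   trivial self hits are dropped.
2. **Pile up** overlapping alignment intervals per genome into
   non-overlapping node ranges — the initial single-sequence groups.
3. **Build the alignment graph**: nodes are ranges, one edge per
   alignment (parallel edges and self loops allowed); connected
   components bound all merging.
4. **Traverse every edge**, mapping group boundaries across each
   alignment through per-alignment bit arrays (1 = residue, 0 = gap):
   a boundary splits every member of a group at the homologous
   position, propagated breadth-first through the group's internal
   alignment edges, and the aligned post-split pairs are merged, with
   strand flips for inverted alignments.  The surviving groups are the
   MHG partition: per genome the members never overlap, and each group
   is homologous across its entire length, indels excepted.

A brute-force per-base transitive-closure oracle
(`transitive_homology_partition()`) and a synthetic genome generator
with planted ground truth (`simulate_genomes()`) validate the machinery
end to end: on mutation-free fixtures the pipeline recovers the planted
partition boundary-for-boundary, including fission cuts, inverted and
duplicated copies.

## Worked example

Plant three block families (some fissioned) into three synthetic
genomes, align, filter, delineate:

```r
library(homolograph)

fx  <- simulate_genomes(n_genomes = 3, n_families = 3, block_len = 200,
                        p_fission = 0.5, seed = 7)
al  <- align_local(fx$genomes)
self <- al[al$query_genome == al$subject_genome, ]
flt <- filter_alignments(al, max_self_bitscore(self), fraction = 0.01)
part <- mhg_delineate(flt, verbose = TRUE)
#> alignments: 15 in, 15 after filtering
#> graph: 15 nodes, 15 edges, 5 components
#> traversal: 0 splits, 10 merges, 5 final groups
part
#> <mhg_partition> 5 group(s), 15 member sequence(s), 3 genome(s)
#> # A tibble: 15 x 5
#>    mhg_id genome start   end strand
#>     <int> <chr>  <int> <int> <chr>
#>  1      1 g1       131   202 +
#>  2      1 g2       774   845 +
#>  3      1 g3      1076  1147 +
#>  4      2 g1       348   548 +
#>  ...
```

Five groups from three families: the two fissioned families each
contribute two groups, split at the planted cut in *every* genome.  The
partition matches the generator's ground truth exactly:

```r
identical(canonical_partition(part),
          canonical_partition(truth_partition(fx$truth)))
#> [1] TRUE

glance(part)
#> # A tibble: 1 x 5
#>   n_mhgs n_members n_genomes mean_members total_bp
#> 1      5        15         3            3     1800

mhg_base_coverage(part, fx$genomes, min_taxa = 2)
#> # A tibble: 3 x 5
#>   genome min_taxa covered_bp total_bp coverage
#> 1 g1            2        600     1248    0.481
#> 2 g2            2        600     1312    0.457
#> 3 g3            2        600     1663    0.361
```

`mhg_occurrence()`, `classify_mhg_location()` and `coverage_table()`
give the per-taxon-pair and genic/intergenic analytics;
`filter_informative()`, `tree_bipartitions()`, `rf_distance()` and
`split_support()` drive the marker-vs-MHG split-conflict comparison;
`marker_conflict_experiment()` runs the recombinant-marker simulation
study (chained-NNI component trees, Jukes-Cantor sequences, NJ +
bootstrap).  `autoplot()` methods and `plot_*()` helpers render the
partition, occurrence heatmap, coverage curves and support
distributions.  A thin command-line front end lives at
`inst/cli/homolograph` (`delineate`, `coverage`, `simulate-markers`,
`make-fixture`).

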