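# ighclonal

Identification of clonally-related sequence sets in human immunoglobulin
heavy-chain (IGH) repertoires.

## The problem

During B-cell development each cell assembles a heavy-chain variable
region by recombining one IGHV, one IGHD and one IGHJ germline gene, with
non-templated N nucleotides added at the two joints. During an immune
response a cell's descendants accumulate point mutations (somatic
hypermutation), producing a *clonally-related set*: sequences descended
from one V-D-J rearrangement. Finding these sets in repertoire sequencing
data is the entry point for studying clonal expansion, but doing it by
visual inspection of aligner output does not scale.

`ighclonal` automates the task for sequences that have already been
partitioned into V / N1 / D / N2 / J segments with germline gene
assignments (any partitioner whose output can be mapped onto a
semicolon-separated record works; the field order is configurable). It is
aimed at immunogenetics researchers processing repertoire data in R or
from the shell.

## The method

1. **CDR3 extraction.** The third complementarity-determining region
   (IMGT codons 105–117) spans the V-D-J join and is the most variable
   part of the gene, so it carries most of the clonal signal. Per-gene
   length libraries anchor it: for each IGHV gene, the number of
   nucleotides from the first nucleotide of codon 105 (IMGT-gapped
   position 313) to the gene's 3' end; for each IGHJ gene, the offset of
   the J-TRP codon (the first `TGG`). The CDR3 is the V tail + N1 + D +
   N2 + J head.
2. **Pairwise distance (NED_VJ).** For CDR3s *x*, *y* the normalized
   edit distance is the minimum over all edit paths *P* of

   ```
   NED_VJ(x, y) = min over P of  ( W(P) + S_V + S_J ) / L(P)
   ```

   where `W(P)` is the path weight (match 0, substitution 1, gap opening
   3, gap extension 1), `L(P)` the path length (every aligned pair and
   every gapped position counts 1), and `S_V`, `S_J` are germline
   mismatch penalties: 5 / 3 / 1 for an IGHV subgroup / gene / allele
   mismatch and 3 / 1 for an IGHJ gene / allele mismatch. Unlike the
   post-normalized distance (`ld / max(m, n)`), the minimizing path is
   not necessarily a Levenshtein-optimal path; the ratio is minimized
   directly (solved exactly by fractional programming, with a
   path-length-indexed dynamic program and an exhaustive-path enumerator
   as cross-checks).
3. **Clustering.** Average-linkage (UPGMA) agglomeration over the
   pairwise matrix builds a dendrogram; the maximal subtrees whose merge
   heights stay below the empirical threshold **τ = 0.32** are reported
   as clonal sets, everything else as singletons.

A simulation module (`simulate_repertoire()`) generates labelled
synthetic repertoires — V-D-J rearrangement, N addition, i.i.d. somatic
hypermutation, optional chimeric artifacts — so the whole pipeline is
testable against a known clonal partition without any external data.

## Worked example

Bundled under `inst/extdata/` is a small synthetic repertoire (10 clones,
30 sequences, 2% per-site mutation) with its CDR3 length libraries:

```r
library(ighclonal)

p  <- system.file("extdata", "example_partitioned.txt", package = "ighclonal")
vl <- read_library_tsv(system.file("extdata", "example_v_start.tsv", package = "ighclonal"))
jl <- read_library_tsv(system.file("extdata", "example_j_end.tsv", package = "ighclonal"))

parsed <- parse_partitioned_file(p)
res <- clonal_sets(parsed$records, vl, jl, metric = "ned_vj", tau = 0.32)
head(res$assignments, 5)
#>     seq_id set_id set_size
#> 1 c002_s01      1        4
#> 2 c002_s02      1        4
#> 3 c002_s03      1        4
#> 4 c002_s04      1        4
#> 5 c004_s01      2        4
```

Ten clonal sets are found and no singletons; each row assigns a sequence
to a numbered set (singletons would carry the `"singleton"` token in the
CSV output). Against the generator's truth labels:

```r
truth <- read.csv(system.file("extdata", "example_truth.csv", package = "ighclonal"))
truth$set_id <- as.character(truth$clone_id)
evaluate(res$sets, truth[, c("seq_id", "set_id")])
#> Clonal set evaluation
#>   clusters below threshold: 10
#>   sequences in clusters:    30
#>   clusters differing:       0
#>   incorrectly assigned:     0
#>   correctly clustered (%):  100.0
```

The merge trajectory (`res$trajectory`) gives the evaluation graph used
to justify the threshold: early merges happen at distance ~0 (clonal
pairs), the final merges here at 0.84–0.87 (unrelated clones), with a
wide gap around 0.32. `write_assignments_csv()`, `write_dendrogram_xml()`
persist the outputs; the same pipeline is scriptable via the bundled
`exec/ighclonal` command-line tool (`simulate`, `build-libs`, `cluster`,
`evaluate` subcommands).

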