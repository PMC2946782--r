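---
title: "Clustering immunoglobulin heavy-chain sequences into clonal sets"
author: "ighclonal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering immunoglobulin heavy-chain sequences into clonal sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighclonal)
```

## The model

A rearranged IGH variable region is a mosaic: a germline IGHV gene, a
non-templated N1 region, a germline IGHD gene, an N2 region and a
germline IGHJ gene. All descendants of one rearrangement (a clone) share
that mosaic and diverge only by somatic point mutation. Two consequences
drive the method:

* the CDR3 (IMGT codons 105–117), which spans the V-D-J join and both N
  regions, is essentially unique per rearrangement and nearly identical
  within a clone; and
* clone members carry the same germline IGHV and IGHJ assignments.

`ighclonal` therefore scores every pair of sequences with a germline-aware
normalized edit distance over their CDR3s, builds an average-linkage
dendrogram, and declares the subtrees below a fixed threshold to be
clonal sets.

### CDR3 anchoring

The CDR3 start is anchored in the IMGT unique numbering: codon $c$
occupies gapped nucleotide positions $3(c-1)+1 \ldots 3(c-1)+3$, so the
first nucleotide of codon 105 is gapped position 313. For each IGHV
germline gene, `build_v_start_library()` counts the non-gap nucleotides
at or after position 313 of its IMGT-gapped sequence — the number of
germline V nucleotides inside the CDR3. The end is anchored on the
conserved J-TRP (codon 118): `build_j_end_library()` records the offset
of the first `TGG` in each IGHJ gene, optionally restricted to a known
reading frame. The CDR3 spans codons 105–117 inclusive, so the `TGG`
itself is excluded. Whether the original convention searched the `TGG`
in frame or as a plain substring is ambiguous; both are supported via
`frame_hint`, with the plain first occurrence as the default.

`extract_cdr3()` then concatenates the last `v_tail_len` nucleotides of
the reported V segment, N1, D, N2 in full, and the first `j_head_len`
nucleotides of the J segment. Segments shorter than the library length
(truncated reads) are clamped with a flag rather than discarded; records
whose V or J call is missing from the libraries are excluded with a
recorded reason and the rest of the pipeline proceeds.

## The distance

For CDR3s $x$ ($m$ nt) and $y$ ($n$ nt) an *edit path* is a sequence of
matches, substitutions, insertions and deletions transforming $x$ into
$y$. Three distances are provided:

* `ld(x, y)` — minimum path weight (block-gap Levenshtein distance);
* `pned(x, y)` — `ld(x, y) / max(m, n)` (post-normalized);
* `ned(x, y, offset)` — $\min_P \,(W(P) + \text{offset})/L(P)$, the
  normalized edit distance, where $L(P)$ counts every aligned pair and
  every gapped position.

`ned_vj()` is `ned()` with `offset` $= S_V + S_J$, the germline mismatch
penalties: $S_V \in \{0, 1, 3, 5\}$ for identical gene-and-allele /
allele / gene / subgroup mismatches, $S_J \in \{0, 1, 3\}$ (IGHJ has no
subgroup tier). Because the offset is constant for a pair, the penalties
simply shift the numerator; the minimizing path is re-optimized under
the shifted objective rather than inherited from the Levenshtein
optimum (for an unambiguous definition of $L$, since the
Levenshtein-optimal path is not unique). Dividing by the path length,
rather than a string length, makes one mismatch between short junctions
count for more than one mismatch between long ones, and spreads the
germline penalties over the junction length.

### Cost parameters

All costs are unitless weights per edit operation. Defaults: match 0,
substitution 1, gap opening 3, gap extension 1. The opening surcharge
makes one length-changing event three times as expensive as a point
mutation — appropriate because somatic hypermutation is overwhelmingly
substitutional, so length differences are strong evidence against clonal
relatedness. The extension cost must be strictly positive for the
normalized distances to be informative: with free extensions, deleting
all of $x$ and inserting all of $y$ costs at most twice the opening
charge regardless of length, so the distance between *arbitrary*
unrelated junctions collapses toward $2 \cdot \text{gap\_open}/(m+n)$ —
far below any useful clonal threshold — and no fixed cutoff can separate
clones. With `gap_open = gap_extend = substitution = 1` every distance
reduces exactly to the textbook unit-cost Levenshtein model, which the
test suite exploits as an independent oracle (`utils::adist`). An `N`
base compares as a mismatch against everything, including `N`, so
low-quality positions cannot manufacture clonal links.

### Solvers and numerical choices

Three independent routes compute `ned`:

1. **Parametric (default).** Dinkelbach fractional programming: iterate
   $\lambda \leftarrow (W^* + \text{offset})/L^*$ where $(W^*, L^*)$
   belong to the path minimizing $W - \lambda L$ (a standard affine-gap
   DP with every operation discounted by $\lambda$). The iteration
   terminates when no path improves on $\lambda$ (tolerance
   $10^{-12}$, scale-adjusted); the returned value is the exact ratio of
   a concrete optimal path, not an approximation. $O(mn)$ per iteration
   and a handful of iterations in practice.
2. **Path-length-indexed DP** (`method = "dp"`). States $(i, j, k, s)$
   with $k \le m + n$ the number of operations so far and $s$ the gap
   state, kept as two $k$-slices. Cubic in the string length — the
   classical complexity for this distance — and used as a cross-check.
3. **Exhaustive enumeration** (`brute_force_ned()`), guarded to
   $m + n \le 12$, the test oracle both others must match exactly.

Ties between equal-ratio paths are irrelevant (only the ratio is
returned). Degenerate inputs: two empty strings have distance 0 (an
error with a positive offset, since no path exists to carry it); one
empty string forces the single whole-string gap.

## Clustering

`upgma()` implements unweighted average linkage over the *original*
pairwise distances (UPGMA proper, not the weighted variant): at each
step the pair of clusters with the smallest unweighted mean of
cross-pair distances merges at that mean, maintained by the
Lance–Williams size-weighted update, which is algebraically identical to
re-averaging. Equal-distance ties are broken deterministically by the
lexicographically smallest pair of smallest-member ids, so the result is
invariant to input order. Average linkage cannot produce inversions;
monotone non-decreasing merge heights are asserted on every run.

`cut_tree(tree, tau = 0.32)` extracts the maximal subtrees whose merge
heights are strictly below the threshold (at-or-below is available via
`strict = FALSE`); subtrees with at least two leaves are clonal sets,
numbered by decreasing size then lexicographic smallest member, and the
rest are singletons. τ = 0.32 is the empirical clonal threshold for
NED_VJ on human IGH data: on the merge-trajectory diagnostic
(`merge_trajectory()`, merge height versus merge index) clonally-related
sequences merge early at low heights, the curve flattens, then rises
sharply once unrelated sequences start joining; 0.32 sits in the flat
region. Degenerate thresholds are legal and logged: τ ≤ 0 yields all
singletons, τ above the root height one all-inclusive set.

`evaluate()` compares predicted sets with a benchmark labelling using an
exact-set-match rule: a sequence is correct if and only if its predicted
set contains exactly its benchmark partners, and
`pct_correct = 100 (n_{seqs} - n_{incorrect}) / n_{seqs}` over the
sequences placed in predicted sets. Benchmark conventions for such
tables vary; the raw counts are always reported so any alternative
normalization can be recomputed.

## The synthetic generator

`simulate_repertoire()` emulates exactly the data model the method
assumes: per clone one draw of V, D, J and uniform-base N1/N2 regions
(lengths uniform on 2–8 nt), then per member i.i.d. substitutions at
`shm_rate` applied to every segment. The default germline pools
(`synthetic_germlines()`) hold 25 V genes (three subgroups, multiple
genes and alleles, so every penalty tier can fire), 25 D genes of
10–20 nt and 6 J genes — proportions chosen to echo the functional human
IGH repertoire at reduced scale. Every V gene carries a planted CDR3
starting length (9 nt by default, the typical germline contribution
beyond the conserved 2nd-CYS codon) and every J gene a planted J-TRP
offset, so the library builders can be validated against known answers.

Clone junctions are redrawn until all pairwise naive-CDR3 NEDs are at
least 0.32 — i.e. until the planted partition is actually identifiable
at the clonal threshold. Mere non-identity is not enough: two clones
that draw the same V, D and J and differ only in a few N nucleotides are
indistinguishable from genuine clonal relatives *by any junction-based
method*, which is the known failure mode of junction clustering with
short D genes. Requiring separation makes recovery tests well-posed;
`min_junction_dist = 0` restores the weaker non-identity rule.

`inject_chimeras()` models the PCR artifact in which a sequence keeps
its junction but acquires another template's V region: the V call and V
body are swapped for a different V gene while the CDR3-proximal tail and
everything downstream are preserved. Such artifacts are invisible to
plain CDR3 distances (identical junctions, distance 0) and are exactly
what the $S_V$ penalty guards against — with it the chimera sits at
$S_V / |CDR3| > 0$ from its former clone-mates.

What the generator does **not** model: hotspot-targeted or indel somatic
hypermutation, exonuclease trimming of gene ends, realistic N-length or
gene-usage distributions, platform-specific sequencing error, or
aligner mispartitioning. Passing recovery tests therefore demonstrates
the correctness of the distance-and-clustering machinery under the
method's own assumptions, not its accuracy on real reads — on real data
the dominant error sources are partitioning quality and the biological
caveats above.

## Problem sizes and reproducibility

The recovery experiments simulate 30 clones of 2–8 members
(≈ 150 sequences, ≈ 11,000 pairwise distances per run); noiseless runs
must recover the planted partition exactly (adjusted Rand index 1.0) and
mean recovery over 20 independent repertoires must not improve when the
mutation rate rises from 2% to 8% per site. Distance solvers are checked
against exhaustive enumeration on hundreds of random pairs (lengths ≤ 6,
offsets up to 8) at $10^{-12}$; `upgma()` against an $O(n^3)$
re-averaging reference and `stats::hclust(method = "average")` on random
matrices up to $n = 15$. All stochastic tests fix their seeds.
`scripts/acceptance.R --seed S --out f.json` re-runs the recovery and
oracle computations end to end from a single seed.

## Known limitations

* The distance ignores shared-mutation patterns in the V region, which
  could split clones that diverged early or join coincidentally similar
  junctions; the threshold is fixed rather than data-adaptive.
* IGHD identity is deliberately not used (unreliable to call, and
  already inside the CDR3).
* Very short junctions make the germline penalties dominate
  ($S/L$ grows as $L$ shrinks), which is conservative but can
  over-separate clones with short CDR3s.
* The average-linkage step is $O(n^2)$ memory in the number of unique
  sequences; repertoires beyond a few tens of thousands of sequences
  need pre-deduplication.
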