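---
title: "Multilevel overlap-graph coarsening of sequencing reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel overlap-graph coarsening of sequencing reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovlcoarse)
```

## Overview

`ovlcoarse` models a sequencing read set as an overlap graph and reduces
that graph iteratively by Heavy Edge Matching (HEM), producing a hierarchy
`G_0, G_1, ..., G_N` that represents the reads across a spectrum of
granularities. Read clusters can be extracted at any level; on metagenomic
data the coarse levels recover the partition of reads by source genome.
This vignette documents the model, the parameters that matter, the
numerical conventions, and the design choices made where the design was
genuinely open.

## Overlap detection

Reads are concatenated into one string with a `$` sentinel after each read
and indexed by a suffix array (prefix-doubling construction, `O(n log n)`,
byte-order comparisons). For a query read of length `l`, all `l - k + 1`
overlapping k-mers are used as exact-match seeds; a `stride > 1` option
seeds more sparsely at a sensitivity cost. Each suffix-array hit landing in
a different read yields a candidate (reference, diagonal) pair; candidates
are deduplicated, and only pairs with reference id greater than the query
id are pursued, so each unordered read pair is evaluated exactly once.
K-mers containing `N` never seed (and `N` never counts as a match in
alignment or q-gram hashing).

Candidate pairs pass through a q-gram filter on the overlap windows implied
by the seed diagonal: two strings within `e` edit operations share at least
`w + 1 - q(e + 1)` q-grams (`w` the shorter window length), so counting the
multiset intersection of q-grams and requiring that bound cannot reject a
true candidate within the error budget. The budget itself is derived from
the identity threshold as `e = ceil((1 - min_identity/100) * w)`. A
non-positive bound passes automatically.

Surviving candidates are aligned with a banded overlap
(Needleman–Wunsch-style) dynamic program restricted to diagonals within
`±band` of the seed diagonal, with free end gaps — the unaligned prefix of
one read and suffix of the other are unpenalized, so suffix–prefix
dovetails and containments are both scored naturally. Scoring is unit
match `+1` / mismatch `-1` / gap `-1`; the algorithm is named for its
band, and with `band >= max(|a|, |b|)` it reproduces the unrestricted
overlap alignment exactly (this is tested against an independent quadratic
DP). An overlap is accepted iff alignment length `>= min_overlap_length`
and identity `= 100 * matches / columns >= min_identity`. When several
diagonal clusters hit the same pair, the best alignment is kept (longest,
then highest identity, then smallest diagonal).

Default parameters: `k = 16` bp, `q = 8` bp, `band = 8` diagonals,
`min_overlap_length = 50` bp, `min_identity = 90` percent. The k and q
values are standard engineering choices for ~100 bp reads with sub-percent
error rates: 16-mers are long enough that cross-genome chance hits are
rare, and `q = 8` keeps the filter bound informative on 50–100 bp windows.
The length/identity thresholds are exposed as flags; nothing in the method
depends on their specific values.

## The graph and its invariants

The overlap graph has one node per read and one undirected edge per
accepted overlap, weighted by the alignment overlap length in bp (longer
overlap, stronger evidence of adjacency in the underlying sequence).
Storage is flat compressed-sparse-row arrays: a per-node offset array plus
destination/weight arrays in which each undirected edge appears once per
endpoint; within a node's edge set, edges are sorted by descending weight
with ties broken by ascending destination id (a deterministic, documented
key). Level-0 edges also carry percent identity; identity is not
propagated to coarse levels, where summed lengths are the only meaningful
weight. Self-loops and parallel edges are structurally excluded.

## Heavy Edge Matching coarsening

Each iteration computes a matching and contracts it:

* **Visit order.** Nodes are keyed by their heaviest incident edge weight
  (0 if isolated) and visited in strictly descending key tiers; within a
  tier the order is a seeded-RNG shuffle. (The alternative reading — one
  global weight-biased shuffle — is not used; tiers make the
  heaviest-first intent exact while the shuffle removes id bias.)
* **Neighbor scan.** An unmatched node scans its edge set in stored
  (descending-weight) order. The scan *stops* when the weight drops below
  `min_edge_weight` — sound because the set is sorted. A neighbor that is
  already matched is skipped. A neighbor whose merge would not satisfy the
  density constraint is skipped *and the scan continues*, because density
  is not monotone in edge weight; only the weight floor justifies
  stopping.
* **Density constraint.** A pair `(u, v)` may merge only if

  `edge_density(u, v) = 2 (ew[u] + ew[v] + w(u,v)) / (s (s - 1)) > min_density`,

  with `s = nw[u] + nw[v]`, `nw` the count of level-0 descendants and `ew`
  the level-0 edge weight already internal to the node. This is the
  average internal overlap length per node pair of the prospective
  supernode; for two singletons it reduces to `w(u, v)`, which is why a
  density minimum of 50 is commensurate with a 50 bp minimum overlap
  length. The inequality is strict. The defaults `min_density = 50` and
  `min_match_ratio = 0.01` are the operating point used throughout this
  package's own studies; `min_edge_weight` defaults to 0 so that density
  is the binding constraint.
* **Passes.** `passes` (default 1) sweeps per iteration; later passes
  revisit only still-unmatched nodes, with keys retained and a fresh
  within-tier shuffle.
* **Contraction.** Supernode ids are allocated scanning old ids in
  ascending order (first-seen member of each pair, and each unmatched
  node) — an arbitrary but fixed convention for reproducibility. For a
  merged pair, `nw` adds and `ew` adds plus the matched edge weight.
  `node_map` records each old node's supernode; `node_map_inverse` (length
  `2|V|`, `-1` sentinel for a missing second child) records each
  supernode's children. Edges are relabeled through `node_map`; collapsed
  (self-mapped) edges are dropped, parallel edges merged with summed
  weights, and edge sets re-sorted. Two conservation laws hold at every
  level and are enforced by tests: `sum(nw) = |V_0|` and
  `sum_{E_0} w = sum_V ew + sum_{E_i} w`.
* **Termination.** Coarsening stops when the matched-node ratio
  `2|M| / |V|` falls strictly below `min_match_ratio`, or at
  `max_iterations` (default 50, a generous safety cap).

All randomness flows through R's RNG from a single seed; a rerun with the
same inputs and seed serializes bit-identically.

## Cluster extraction and evaluation

`expand_to_reads()` descends the `node_map_inverse` arrays from any level
to level 0; `clusters_at()` computes the full partition by composing the
`node_map` arrays, which is mathematically the same recursion evaluated in
the other direction and costs `O(|V_0|)` per level (a property test
asserts the two routes agree). Cluster sizes equal the level's node
weights by construction.

With ground-truth labels, each cluster is labeled by majority read vote,
ties broken deterministically by the lexicographically smallest label, and
the error rate is the percentage of reads whose label differs from their
cluster's majority. At level 0 every read is a singleton, so the error
rate is 0 by definition and only becomes informative as clusters grow.

`traversal_order()` walks the reduced graph (BFS by default, DFS behind a
flag; components seeded at the unvisited node of largest node weight, ties
to the smallest id; neighbors in stored order) and expands each supernode
to reads, yielding a permutation of the read ids. `relabel_edges()` applies
that permutation to the level-0 graph; the contract is bijectivity plus a
non-increasing mean edge-endpoint distance (`locality_score()`), which the
tests check on simulated two-genome data.

## The synthetic-data generator

The generator emulates the kind of simulated-metagenome experiment the
method is meant for: `n_genomes` i.i.d.-random A/C/G/T genomes; optional
homology pairs sharing an ancestral segment (`shared_fraction` of the
genome, each copy independently mutated at `divergence/2` so the expected
pairwise divergence of the copies is about `divergence`); reads drawn per
genome as `floor(coverage * L / mean_read_length)` with uniform start
positions; fixed 100 bp lengths (Illumina-like) or truncated-Gaussian
lengths (454-like, mean ~440 bp per the emulated design); i.i.d.
substitution errors; per-read ground-truth labels. Defaults are the study
conditions used by the acceptance checks: 4 genomes of 50 kb, 15x
coverage, 100 bp reads, 0.5% substitutions. Homology defaults
(`shared_fraction = 0.1`, `divergence = 0.05`) are deliberate placeholders
for robustness experiments — real related genomes' homology levels are not
reducible to two numbers.

What it does *not* emulate: position- and quality-dependent error
profiles, indels and homopolymer errors (454's characteristic failure
mode), chimeric reads, GC and coverage bias, and repeat structure within a
genome (i.i.d. genomes are nearly repeat-free). Reads are drawn from the
forward strand only by default (a reverse-complement flag exists, but the
overlapper's default is forward–forward seeding). Passing tests on this
generator therefore demonstrates the pipeline's correctness and its
behavior under substitution noise and varying coverage — not performance
on repeat-rich or indel-heavy real data.

Read-count convention: `floor(coverage * L / mean_read_length)` is exact
and testable; external read simulators round differently by a handful of
reads, so only proportionality across a coverage sweep (e.g. 15x yields
exactly 3 times the 5x count for the same genome) is asserted, never
third-party counts.

## Numerical choices and degenerate inputs

* Identity is serialized at 2 decimal places; alignment lengths and all
  graph weights are integer-valued and serialized exactly. Level files
  round-trip bit-identically.
* Alignment tie-breaks are fixed: diagonal > up > left during traceback;
  terminal cell chosen as the first strict maximum scanning the last
  column (ascending row) then the last row (ascending column).
* Strict inequalities follow the stated rules: density must be *greater
  than* the minimum, termination when the match ratio *falls below* the
  minimum. A singleton pair with `w` exactly at the density minimum does
  not merge.
* Degenerate cases: an empty FASTA file is a valid empty read set; an
  edgeless graph coarsens to a single-level hierarchy (match ratio 0); an
  empty matching contracts to an isomorphic graph with fresh ids; an empty
  overlap window rejects the candidate before alignment; `match_ratio` and
  `error_rate` are errors on empty graphs/read sets rather than NaN.
* FASTQ qualities are Phred+33; quality trimming removes the longest
  prefix and suffix such that both terminal bases meet the threshold
  (interior bases are never touched — trimming never splits a read).

## Open design points, resolved

* **Density formula grouping.** The density expression is implemented as
  `2(ew_u + ew_v + w) / (s(s-1))` — the weighted density of the merged
  supernode (internal weight over node pairs), the only grouping under
  which a density threshold of 50 is commensurate with overlap lengths
  and equals `w` for singleton pairs.
* **Seed count.** All `l - k + 1` component k-mers are enumerated; the
  stride option exists for sparser seeding but defaults to full coverage
  of the read.
* **Pair semantics.** The graph stores one logical undirected edge per
  pair (symmetric adjacency); HEM and the density computation require
  symmetric neighbor access, and nothing downstream needs directed
  duplicates.
* **Traversal.** BFS from heaviest supernodes; the relabeling contract is
  only bijectivity plus non-increasing locality, so the traversal flavor
  is a flag, not a commitment.
* **Distribution.** The pipeline is single-process; the block-parallel
  overlap decomposition and parallel merge sort that a cluster deployment
  would use are out of scope, with the sort contract (stable, documented
  key) guaranteed by a serial sort.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
generated at test time: oracle comparisons on strings up to 2,000
characters and graphs up to 200 nodes; pipeline checks on four-genome
50 kb metagenomes at 5x/15x/25x coverage (10,000–50,000 reads), chosen so
the whole distribution builds and verifies on a single CPU in minutes
while still exercising every stage at realistic densities.

## Known limitations

Indel-rich technologies are underserved by the substitution-only error
model and the banded alignment's modest default band. Identity is not
propagated through coarsening, so coarse-level cluster quality is driven
by overlap length alone. The density constraint assumes overlap length is
the meaningful edge currency; with very short reads or very low coverage
the default operating point (50 / 0.01) may terminate after one or two
iterations. Finally, majority-vote evaluation requires ground truth and is
a clustering metric, not an assembly metric — no consensus sequence is
produced.
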