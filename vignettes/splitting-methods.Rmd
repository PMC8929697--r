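---
title: "Splitting sequence families into dissimilar training and test sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting sequence families into dissimilar training and test sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msasplit)
```

## The problem

Benchmarks of homology-search and sequence-classification methods need test
sequences that the method has not effectively seen. Because members of a
sequence family are related by evolution, a uniform random split of an MSA
leaves test sequences that are nearly or exactly identical to training
sequences, so measured accuracy reflects memorization rather than remote
recognition. `msasplit` instead enforces a distance rule: no test sequence
may exceed `p`% identity to any training sequence, and no two test
sequences may exceed `q`% identity to each other. Sequences that fit
neither set are excluded; a split "succeeds" when the train and test sets
reach user-chosen size minima.

## Model and graph formulation

Let the rows of an alignment be vertices. For threshold `p`, graph `G1`
has an edge between two rows when their percent identity is *strictly*
greater than `p`/100; the strict inequality means a returned split
satisfies "at most `p`% identical" exactly. Percent identity here is

> (columns where both rows carry the same residue, case-insensitively,
> with columns gapped in either row never counting) / (the shorter of the
> two ungapped lengths)

computed on the rows as aligned — no realignment. Dividing by the shorter
ungapped length is the convention of the profile-HMM benchmarking
toolchain this package interoperates with; the choice matters for
fragmentary rows, which is also why the 70%-of-mean-length fragment filter
(`fragment_filter`) is applied once, before splitting. Ambiguity codes are
compared by plain character equality. A pair of fully gapped rows has no
defined identity and raises an error rather than guessing.

Splitting is a two-step graph problem: step 1 finds a *bipartite
independent pair* — disjoint sets `S`, `T` with no `G1` edge between them
(edges inside a set are fine: training alignments legitimately contain
redundancy, and test candidates are de-redundified separately) — and
declares the larger side the training set. Step 2 takes the q-threshold
graph `G2` on the smaller side and returns an independent set as the test
set.

## The four algorithms

**Cobalt** uses greedy sequential scans. Step 2 is the classic greedy
maximal independent set: scan a uniform random permutation, admit a vertex
iff none of its neighbors was admitted earlier. Step 1 is the bipartite
variant: each vertex flips a fair coin for a preferred side and joins it
iff it has no neighbor on the *opposite* side, else tries the other side,
else is excluded. The opposite-side test is what preserves the
no-crossing-edge invariant that the whole method rests on; a vertex
adjacent to both sides is exactly the "bridge" case and is dropped.

**Blue** replaces the single scan with random-priority rounds. Every
still-eligible vertex draws a fresh uniform label; a vertex whose label
beats all its still-eligible competitors wins its side, and winners knock
their neighbors out of the opposite side's eligibility. Step 1 tracks
S- and T-eligibility separately, with doubly eligible vertices choosing a
candidate side by fair coin each round; step 2 is the same election on one
set. Blue spreads selection chances more evenly (in each round a vertex's
chance is inversely related to its number of surviving competitors), which
is why it splits more families, at the cost of more rounds of labels.

**Cluster** is single-linkage clustering at `p`: connected components of
`G1`. The largest component is the training set (ties broken toward the
component containing the smallest row index, for determinism); the test
set takes one uniformly chosen vertex per q-component of the remainder.
Its test set is an independent set of `G2` but not a maximal one, and one
bridging sequence collapses the family into a single component, where the
randomized algorithms can simply exclude the bridge.

**Independent Selection** admits each vertex to the training set
independently with probability `p_select` (default 0.70); vertices outside
with no edge into the training set are test candidates, reduced by the
greedy step 2. No larger-side swap is applied — the drawn set is the
training set even if smaller.

An isolated vertex (no `G1` neighbor, i.e. a maximally remote sequence)
illustrates the character of each method: Cluster always sends it to the
test set; Independent Selection does so with probability exactly
1 − 0.70 = 0.30; Blue and Cobalt do so roughly half the time (the
larger-side swap interacts with the rest of the graph, so 50% is an
idealization, not a constant — the package tests assert the exact 30% and
100% laws and only the validity properties for Blue/Cobalt).

## Repetition drivers, seeds, determinism

Blue and Cobalt return different splits on different runs. `run_until_n`
reruns until the size minima are met (at most `n_reps` times, default 40);
`best_of_n` always runs `n_reps` times and keeps the successful split
maximizing `|train| × |test|`, ties to the earliest run. Run `i` uses the
sub-seed `sub_seed(seed, i)`, a fixed integer function of the master seed,
so any repetition can be replayed in isolation. Every algorithm is fully
deterministic given its seed; label ties in the random-priority elections
(probability zero with ideal uniforms, possible in floating point) are
broken by vertex index. Failed splits return a structured result with
`success = FALSE` rather than raising, so batch drivers can count pass
rates; per-family wall-clock caps are available at the command-line layer
(`--timeout`) and are not part of algorithm semantics.

## Lazy similarity evaluation

Identity is expensive (O(L) per pair), and most algorithms touch few
pairs, so `similarity_graph` computes an edge only when first queried and
caches the answer keyed on the unordered pair. Queries of the form "does
`v` have a neighbor in set X" stop at the first edge found. The
accounting invariant — never more than C(N,2) evaluations per graph, with
component discovery on well-separated families strictly below it — is
asserted in the test suite. The worst case (an edgeless family) evaluates
all pairs: O(L·N²) overall.

## The synthetic generator

`generate_family` produces the structured inputs the tests and examples
run on: `k` clusters grown from independent random consensus sequences
over the 20-letter amino-acid alphabet, members mutated by independent
substitutions calibrated (by solving the two-copy match probability for
the substitution rate) so same-cluster identities concentrate near
`within_identity`; optional half/half chimeras of two cluster consensuses
as bridges; optional unrelated random rows as outliers. Defaults: two
clusters of 15, `within_identity = 0.35`, 400 columns. The 0.35 default
places cluster pairs above a 25% train threshold but below a 50% test
threshold, so a cluster is one single-linkage unit at `p` while its
members remain mutually admissible as test sequences at `q`; 400 columns
keep the identity standard deviation near 0.024, so realized pairwise
identities stay on the intended side of both thresholds. Cross-cluster and
outlier identities sit near the 5% random background. Mutations are
substitution-only, so generated alignments are ungapped and identity
targets stay analytic; real families add gaps, fragments, length variation
and phylogenetic correlation, none of which the generator emulates — the
generator validates algorithmic behavior, not biological realism, and
passing tests say nothing about, e.g., pid conventions on heavily gapped
rows beyond the unit tests that exercise gaps directly. Abstract graphs
(`generate_graph`: edgeless, complete, path, cycle, star, Erdős–Rényi,
two cliques plus a planted bridge) drive the distribution-level tests.

Test problem sizes were chosen to keep the full suite comfortably
desk-scale while leaving sampling error well inside the asserted
tolerances: 200,000 runs for the exact small-graph outcome distributions
(total-variation tolerance 0.01), 10,000 runs for the 30% isolated-outlier
law (tolerance three standard errors, ±0.014), 1,000 random graphs for the
maximality/validity sweep.

## Benchmark construction

`build_benchmark` converts test sequences into a search benchmark in the
profile-benchmark style: per family, the test set is down-sampled to at
most 10 sequences; each test domain is embedded in a synthetic sequence
whose total length is drawn from the background database's empirical
length distribution conditioned on being at least the domain length
(implemented by restricting the empirical sample to feasible lengths,
which is equivalent to rejection), at a uniform start position, flanked by
independently chosen, uniformly shuffled background windows (one fresh
window per segment); decoys copy the segment-length triple of a uniformly
chosen positive and shuffle all three segments, 200,000 of them at full
scale. Embedding coordinates are recorded 1-based inclusive so
`substr(full_seq, domain_start, domain_end)` recovers the domain — the
natural R convention. Each positive embeds exactly one domain. Shuffled
windows carry their source window as an attribute so composition
provenance is checkable.

## Design choices made where the design was open

* **Test output format**: test sequences are written as unaligned FASTA
  (gaps stripped) because downstream benchmark embedding consumes them
  individually; the training set keeps its original alignment columns with
  row order randomly permuted.
* **Greedy BIP adjacency test**: as discussed above, membership tests run
  against the opposite side. Testing against a vertex's own side would let
  a vertex with a same-side neighbor drift to the other side and create a
  train/test pair above threshold, violating the method's defining
  guarantee; the implementation therefore closes that path, and the
  validity of every returned split is asserted property-style in the
  tests.
* **Blue step 2** uses the random-priority election, matching the
  algorithm pairing of step 1; `blue_greedy_step2 = TRUE` switches to the
  greedy scan for users who want Cobalt-style step 2 under a Blue step 1.
* **Tie at |S| = |T|** in step 1: no swap; the first set is the training
  set.
* **Cluster's step-2 set** is the test set (the candidate-side reduction),
  mirroring the two-step framework of the other algorithms.
* **All-gap columns** that arise after filtering or subsetting are
  retained, keeping column indices stable for provenance.
* **Duplicate row identifiers** within a Stockholm block are an error, not
  a silent dedup.

## Known limitations

* Percent-identity conventions differ across toolchains (alignment-implied
  vs realigned pairs, shorter-length vs alignment-length denominators).
  Splits computed here satisfy their thresholds under the convention
  stated above; rates on external databases shift slightly under other
  conventions.
* Blue's multi-round elections are substantially slower than Cobalt on
  families with tens of thousands of rows; Cobalt is the practical choice
  at that scale.
* Repeated Blue/Cobalt splits of one family are not independent draws, so
  they are unsuited to k-fold cross-validation designs.
* The q-threshold redundancy rule applies only within the test set;
  training-set redundancy is deliberately preserved.
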