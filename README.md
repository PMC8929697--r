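# msasplit

Splitting a biological sequence family into training and test sets is not a
random-partition problem: family members are related by evolution, so a
random split leaves test sequences nearly identical to training sequences
and inflates benchmark scores. `msasplit` splits a multiple sequence
alignment (MSA) into a training set and a test set such that

* no test sequence has more than **p**% pairwise identity to *any* training
  sequence (default p = 25 for proteins), and
* no pair of test sequences is more than **q**% identical (default q = 50).

It is aimed at people building remote-homology benchmarks (profile HMM
searches, sequence classifiers) who need dissimilar, redundancy-controlled
train/test splits of Pfam-style alignment families.

## The algorithms

Cast each sequence as a vertex and connect two vertices when their pairwise
identity exceeds the threshold. Percent identity is the number of alignment
columns where both rows carry the same residue, divided by the shorter
ungapped length. A valid split is then a *bipartite independent pair*
(BIP): disjoint vertex sets S (train) and T (candidate test) with no edge
between them in the p-threshold graph G1, followed by an independent set U
of the q-threshold graph G2 on T (the test set). Four algorithms are
provided:

* **Cobalt** — greedy sequential: scan vertices in random order; each joins
  a coin-preferred side when it has no neighbor on the opposite side
  (step 1), then a greedy sequential maximal independent set on T (step 2).
* **Blue** — random priority: round-based elections where each eligible
  vertex draws a uniform label and wins against its still-eligible
  neighbors' labels (steps 1 and 2). Splits the most families but costs
  more rounds.
* **Cluster** — single-linkage clustering: the largest connected component
  of G1 is the training set, one random vertex per q-component of the rest
  is the test set. Deterministic sets, but a single "bridge" sequence that
  is similar to two otherwise-dissimilar groups collapses the family into
  one cluster and the split fails.
* **Independent Selection** — each vertex joins the training set
  independently with probability 0.70; unconflicted leftovers seed the test
  set.

Blue and Cobalt can *exclude* bridging sequences rather than give up, which
is why they split many families that Cluster cannot. Because they are
randomized, `run_until_n` / `best_of_n` drivers rerun them with a
replayable sub-seed schedule. Pairwise identities are computed lazily and
cached, so at most C(N,2) distance computations are ever done per
threshold graph (worst-case O(L·N²) for N sequences of length L).

## Worked example

A synthetic family of two 12-sequence clusters (within-cluster identity
about 35%) joined by one chimeric bridge sequence:

```r
library(msasplit)
aln <- generate_family(family_spec(k_clusters = 2, cluster_sizes = c(12, 12),
                                   n_bridges = 1, seed = 42))
#> <msa> synthetic_family: 25 sequences x 400 columns

split_msa(aln, "cluster", split_config(seed = 7))
#> <split_result> cluster: train 25, test 0, excluded 0 (failed size minima)

res <- split_msa(aln, "cobalt", split_config(seed = 7, mode = "until", n_reps = 40))
#> <split_result> cobalt: train 12, test 12, excluded 1 (success)
res$runs_used
#> [1] 6
aln$ids[res$excluded]
#> [1] "BRIDGE1"

validate_split(aln, res, p = 25, q = 50)[c("valid", "max_train_test")]
#> $valid      [1] TRUE
#> $max_train_test [1] 0.08
```

The bridge makes the whole family one single-linkage cluster, so Cluster
cannot split it (train 25, test 0). Cobalt succeeds on its 6th repetition
by placing one cluster in the training set, the other in the test set, and
excluding the bridge; the maximum train/test identity in the returned split
is 8%, comfortably under the 25% requirement.

From the shell, the same machinery is available as
`exec/msasplit split --algorithm cobalt --mode until --reps 40 --seed 7
family.sto` (writes `train.sto` and `test.fa`) and `msasplit batch` for
multi-MSA files with a TSV report.

## Benchmark-set construction

`build_benchmark()` turns test sequences into a homology-search benchmark:
test sets are down-sampled to at most 10 sequences per family; each test
domain is embedded at a random position in a synthetic sequence whose
length is drawn from a background database's length distribution and whose
flanks are shuffled background subsequences; a shared decoy set (200,000
sequences at full scale) copies the positives' segment-length structure
with all three segments shuffled.

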