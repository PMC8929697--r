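Package: msasplit
Title: Dissimilar Training/Test Splits of Sequence Families by Independent Set Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Splits a multiple sequence alignment into a training set and a
    test set such that no test sequence exceeds a pairwise identity threshold
    p to any training sequence and no two test sequences exceed a threshold q.
    Implements four randomized graph algorithms over a lazily evaluated
    sequence-similarity graph: greedy sequential independent set selection
    (Cobalt), random-priority independent set selection (Blue), single-linkage
    clustering (Cluster), and Independent Selection, together with
    run-until-n and best-of-n repetition drivers. Also provides Stockholm and
    FASTA input/output, a fragment filter, synthetic family and graph
    generators for testing, and construction of homology-search benchmark
    sets with embedded test domains and shuffled decoy sequences.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
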