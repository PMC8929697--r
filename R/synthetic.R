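#' Amino-acid alphabet used by the synthetic generator
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specification of a synthetic sequence family
#'
#' Describes a family with controlled similarity structure: `k_clusters`
#' groups of mutually similar sequences (pairwise identity concentrating
#' near `within_identity`), optional chimeric bridge sequences joining two
#' clusters, and optional outlier sequences unrelated to everything else.
#' Cross-cluster and outlier identities concentrate near the random
#' background for the alphabet (about 1/20 = 5% for proteins), safely below
#' the usual 25% train/test threshold.
#'
#' The default `within_identity` of 0.35 places same-cluster pairs above a
#' 25% train/test threshold but below a 50% test/test threshold, so whole
#' clusters are single-linkage clusters at p = 25 while their members remain
#' mutually usable as test sequences at q = 50.
#'
#' @param k_clusters Number of clusters.
#' @param cluster_sizes Integer vector of length `k_clusters`.
#' @param within_identity Target pairwise identity within a cluster, a
#'   fraction; must exceed the alphabet background `1/|alphabet|`.
#' @param n_bridges Number of chimeric bridge sequences; bridge `j` is a
#'   half/half chimera of the consensus sequences of two clusters, giving it
#'   roughly half the within-cluster identity to members of each parent.
#' @param n_outliers Number of independent random sequences.
#' @param alphabet Residue alphabet (default the 20 amino acids).
#' @param seq_len Number of columns (default 400).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param name Family name.
#' @return A `family_spec` list.
#' @export
family_spec <- function(k_clusters = 2, cluster_sizes = c(15, 15),
                        within_identity = 0.35, n_bridges = 0,
                        n_outliers = 0, alphabet = AA_ALPHABET,
                        seq_len = 400, seed = NULL,
                        name = "synthetic_family") {
  stopifnot(length(cluster_sizes) == k_clusters,
            all(cluster_sizes >= 1), seq_len >= 1,
            within_identity > 0, within_identity <= 1,
            n_bridges >= 0, n_outliers >= 0, length(alphabet) >= 2)
  if (n_bridges > 0 && k_clusters < 2)
    stop("bridges require at least two clusters")
  if (within_identity <= 1 / length(alphabet))
    stop("within_identity must exceed the random background 1/|alphabet| = ",
         signif(1 / length(alphabet), 3))
  structure(list(k_clusters = k_clusters, cluster_sizes = cluster_sizes,
                 within_identity = within_identity, n_bridges = n_bridges,
                 n_outliers = n_outliers, alphabet = alphabet,
                 seq_len = seq_len, seed = seed, name = name),
            class = "family_spec")
}

# Substitution probability m giving expected pairwise identity w between two
# sequences independently mutated from a shared consensus, where each
# position mutates with probability m to a uniform draw from the alphabet
# (possibly the same letter). Match probability:
#   (1 - m + m/A)^2 + (A - 1) (m/A)^2
.mutation_rate_for_identity <- function(w, A) {
  f <- function(m) (1 - m + m / A)^2 + (A - 1) * (m / A)^2 - w
  stats::uniroot(f, c(0, 1), tol = 1e-10)$root
}

.random_seq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

.mutate <- function(consensus, m, alphabet) {
  chars <- strsplit(consensus, "")[[1L]]
  hit <- stats::runif(length(chars)) < m
  chars[hit] <- sample(alphabet, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a synthetic sequence family
#'
#' Realizes a [family_spec] as an ungapped [msa] (mutations are
#' substitution-only, so all rows have full length and pairwise identity
#' targets stay analytic). Each cluster is grown from an independent random
#' consensus; members are mutated copies calibrated so that same-cluster
#' identities concentrate near `within_identity`. Bridges are unmutated
#' half/half chimeras of two cluster consensuses; outliers are independent
#' random sequences. Row order: cluster members (cluster 1 first), then
#' bridges, then outliers; identifiers encode the role (`CL1_3`, `BRIDGE1`,
#' `OUT1`).
#'
#' @param spec A [family_spec].
#' @return An [msa].
#' @examples
#' aln <- generate_family(family_spec(k_clusters = 2,
#'                                    cluster_sizes = c(5, 5),
#'                                    n_bridges = 1, seed = 7))
#' aln
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  A <- length(spec$alphabet)
  m <- .mutation_rate_for_identity(spec$within_identity, A)
  consensi <- vapply(seq_len(spec$k_clusters),
                     function(i) .random_seq(spec$seq_len, spec$alphabet),
                     character(1))
  ids <- character(0)
  seqs <- character(0)
  for (k in seq_len(spec$k_clusters)) {
    for (j in seq_len(spec$cluster_sizes[[k]])) {
      ids <- c(ids, sprintf("CL%d_%d", k, j))
      seqs <- c(seqs, .mutate(consensi[[k]], m, spec$alphabet))
    }
  }
  half <- ceiling(spec$seq_len / 2)
  for (b in seq_len(spec$n_bridges)) {
    a <- ((b - 1L) %% spec$k_clusters) + 1L
    z <- (b %% spec$k_clusters) + 1L
    chim <- paste0(substr(consensi[[a]], 1, half),
                   substr(consensi[[z]], half + 1, spec$seq_len))
    ids <- c(ids, sprintf("BRIDGE%d", b))
    seqs <- c(seqs, chim)
  }
  for (o in seq_len(spec$n_outliers)) {
    ids <- c(ids, sprintf("OUT%d", o))
    seqs <- c(seqs, .random_seq(spec$seq_len, spec$alphabet))
  }
  msa(ids, seqs, name = spec$name)
}

#' Generate an abstract test graph
#'
#' Deterministic structured graphs plus seeded Erdős–Rényi graphs, for
#' exercising the splitting algorithms without sequences.
#'
#' @param kind One of `"edgeless"`, `"complete"`, `"path"`, `"cycle"`,
#'   `"star"`, `"erdos_renyi"`, `"planted_two_cluster_bridge"`.
#' @param n Vertex count (`edgeless`, `complete`, `path`, `cycle`,
#'   `erdos_renyi`); for `star`, the total count including the hub
#'   (vertex 1).
#' @param prob Edge probability for `erdos_renyi`.
#' @param sizes Length-2 vector of clique sizes for
#'   `planted_two_cluster_bridge`; the final vertex is a bridge adjacent to
#'   exactly one member of each clique.
#' @param seed Seed for `erdos_renyi` (other kinds are deterministic).
#' @return A `sim_graph` with explicit adjacency.
#' @examples
#' g <- generate_graph("star", n = 5)
#' graph_degree(g, 1)  # hub degree 4
#' @export
generate_graph <- function(kind, n = NULL, prob = NULL, sizes = NULL,
                           seed = NULL) {
  kind <- match.arg(kind, c("edgeless", "complete", "path", "cycle", "star",
                            "erdos_renyi", "planted_two_cluster_bridge"))
  edges <- function(e) graph_from_edges(n, e)
  switch(kind,
    edgeless = edges(cbind(integer(0), integer(0))),
    complete = edges(t(utils::combn(n, 2))),
    path = edges(cbind(seq_len(n - 1), seq_len(n - 1) + 1L)),
    cycle = edges(rbind(cbind(seq_len(n - 1), seq_len(n - 1) + 1L),
                        c(n, 1L))),
    star = edges(cbind(1L, seq(2L, n))),
    erdos_renyi = {
      if (!is.null(seed)) set.seed(seed)
      pairs <- t(utils::combn(n, 2))
      keep <- stats::runif(nrow(pairs)) < prob
      edges(pairs[keep, , drop = FALSE])
    },
    planted_two_cluster_bridge = {
      stopifnot(length(sizes) == 2, all(sizes >= 1))
      n1 <- sizes[[1]]; n2 <- sizes[[2]]
      n <- n1 + n2 + 1L
      e1 <- if (n1 > 1) t(utils::combn(seq_len(n1), 2)) else NULL
      e2 <- if (n2 > 1) t(utils::combn(n1 + seq_len(n2), 2)) else NULL
      bridge <- rbind(c(n, 1L), c(n, n1 + 1L))
      edges(rbind(e1, e2, bridge))
    })
}
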