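# Independent brute-force oracles for the graph algorithms. Everything here
# works directly on a plain logical adjacency matrix and never calls into the
# package's graph machinery, so it can serve as ground truth.

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  smaller <- all_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, smaller + (smaller >= i))
    out <- rbind(out, block)
  }
  out
}

set_key <- function(x) paste(sort(x), collapse = ",")
pair_key <- function(S, T) paste0("S=", set_key(S), "|T=", set_key(T))

is_independent_set <- function(adj, set) {
  if (length(set) < 2L) return(TRUE)
  !any(adj[set, set])
}

# maximal within `universe`: no vertex of universe \ set can be added
is_maximal_is <- function(adj, set, universe) {
  if (!is_independent_set(adj, set)) return(FALSE)
  for (v in setdiff(universe, set)) {
    if (length(set) == 0L || !any(adj[v, set])) return(FALSE)
  }
  TRUE
}

no_crossing_edges <- function(adj, A, B) {
  if (length(A) == 0L || length(B) == 0L) return(TRUE)
  !any(adj[A, B])
}

# connected components by transitive closure of the adjacency matrix
brute_components <- function(adj, vertices = seq_len(nrow(adj))) {
  reach <- adj[vertices, vertices, drop = FALSE]
  diag(reach) <- TRUE
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach > 0)) break
    reach <- nxt
  }
  comps <- unique(apply(reach, 1, function(r) sort(vertices[r]),
                        simplify = FALSE))
  comps[order(vapply(comps, min, numeric(1)))]
}

# deterministic replay of greedy sequential IS for a given vertex order
oracle_greedy_is <- function(adj, ord) {
  U <- integer(0)
  for (v in ord) {
    if (length(U) == 0L || !any(adj[v, U])) U <- c(U, v)
  }
  sort(U)
}

# deterministic replay of greedy sequential BIP: each vertex prefers the
# side given by its coin (0 = S first) and may join a side only if it has
# no neighbor on the opposite side; final swap when |S| < |T|
oracle_greedy_bip <- function(adj, ord, coins) {
  S <- integer(0); T <- integer(0)
  adjacent_to <- function(v, set) length(set) > 0L && any(adj[v, set])
  for (i in seq_along(ord)) {
    v <- ord[[i]]
    if (coins[[i]] == 0) {
      if (!adjacent_to(v, T)) S <- c(S, v)
      else if (!adjacent_to(v, S)) T <- c(T, v)
    } else {
      if (!adjacent_to(v, S)) T <- c(T, v)
      else if (!adjacent_to(v, T)) S <- c(S, v)
    }
  }
  if (length(S) < length(T)) list(S = sort(T), T = sort(S))
  else list(S = sort(S), T = sort(T))
}

# exact outcome distribution of greedy sequential IS over all permutations
enum_greedy_is_dist <- function(adj) {
  n <- nrow(adj)
  perms <- all_perms(n)
  keys <- apply(perms, 1, function(ord) set_key(oracle_greedy_is(adj, ord)))
  table(keys) / nrow(perms)
}

# exact outcome distribution of greedy sequential BIP over all
# (permutation, coin vector) pairs
enum_greedy_bip_dist <- function(adj) {
  n <- nrow(adj)
  perms <- all_perms(n)
  coin_space <- as.matrix(expand.grid(rep(list(0:1), n)))
  keys <- character(nrow(perms) * nrow(coin_space))
  k <- 0L
  for (pi in seq_len(nrow(perms))) {
    for (ci in seq_len(nrow(coin_space))) {
      k <- k + 1L
      res <- oracle_greedy_bip(adj, perms[pi, ], coin_space[ci, ])
      keys[[k]] <- pair_key(res$S, res$T)
    }
  }
  table(keys) / length(keys)
}

total_variation <- function(emp, exact) {
  keys <- union(names(emp), names(exact))
  e <- stats::setNames(rep(0, length(keys)), keys)
  x <- e
  e[names(emp)] <- as.numeric(emp)
  x[names(exact)] <- as.numeric(exact)
  sum(abs(e - x)) / 2
}

# adjacency matrices for the small-graph catalogue
catalogue_graphs <- function() {
  adj_of <- function(n, edges) {
    m <- matrix(FALSE, n, n)
    for (e in edges) { m[e[1], e[2]] <- TRUE; m[e[2], e[1]] <- TRUE }
    m
  }
  list(
    edgeless5 = adj_of(5, list()),
    K2 = adj_of(2, list(c(1, 2))),
    P3 = adj_of(3, list(c(1, 2), c(2, 3))),
    K3 = adj_of(3, list(c(1, 2), c(2, 3), c(1, 3))),
    star4 = adj_of(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5))),
    C4 = adj_of(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))),
    C5 = adj_of(5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1))))
}

# eager all-pairs pid matrix straight from the definition, as an oracle for
# alignment-backed graphs
brute_pid_matrix <- function(aln) {
  n <- length(aln)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) m[i, j] <- percent_identity(aln$seqs[[i]], aln$seqs[[j]])
  }
  m
}

random_msa <- function(n, L, gap_frac = 0.2) {
  letters20 <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(letters20, L, replace = TRUE)
    gaps <- runif(L) < gap_frac
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  msa(sprintf("s%02d", seq_len(n)), seqs, name = "random")
}
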