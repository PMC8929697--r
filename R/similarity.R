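#' Pairwise percent identity between two aligned rows
#'
#' Identity is the number of alignment columns in which both rows carry the
#' same residue (case-insensitive; columns where either row is gapped never
#' count), divided by the shorter of the two ungapped lengths. This is the
#' convention used throughout the package to decide whether two sequences
#' are "more than p% identical". No realignment is performed; the rows are
#' compared column-by-column as given.
#'
#' @param a,b Gapped sequence strings of equal length.
#' @return A fraction in `[0, 1]`.
#' @examples
#' percent_identity("ACDE", "ACDG")    # 0.75
#' percent_identity("AC-DE", "ACWDE")  # 4 identities / min(4, 5) = 1
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("percent_identity requires equal-length gapped strings")
  ca <- utf8ToInt(toupper(a))
  cb <- utf8ToInt(toupper(b))
  gap <- utf8ToInt("-.")
  ra <- !(ca %in% gap)
  rb <- !(cb %in% gap)
  la <- sum(ra)
  lb <- sum(rb)
  if (la == 0L && lb == 0L)
    stop("percent identity is undefined for two fully gapped rows")
  # one fully gapped row contributes no identities; use the other's length
  denom <- if (la == 0L || lb == 0L) max(la, lb) else min(la, lb)
  sum(ca == cb & ra & rb) / denom
}

# Internal: precompute per-row integer codes and residue masks for fast
# repeated pid evaluation inside a graph.
.encode_rows <- function(seqs) {
  gap <- utf8ToInt("-.")
  codes <- lapply(seqs, function(s) utf8ToInt(toupper(s)))
  resid <- lapply(codes, function(x) !(x %in% gap))
  list(codes = codes, resid = resid,
       ungapped = vapply(resid, sum, integer(1)))
}

#' Lazily evaluated similarity graph over alignment rows
#'
#' Vertices are the rows of the alignment; an edge joins `u` and `v` when
#' their [percent_identity] is strictly greater than `threshold_percent`/100.
#' Edges are computed only when an algorithm first asks whether a given pair
#' is connected, and the answer is cached, so at most `choose(n, 2)` pairwise
#' identity computations are ever performed per graph regardless of how many
#' algorithms are run on it. [graph_n_evals] reports the running count.
#'
#' @param aln An [msa] object.
#' @param threshold_percent Identity threshold in percent, in `[0, 100]`.
#' @return A `sim_graph` object (an environment) with fields `n` (vertex
#'   count) and `threshold`.
#' @seealso [graph_from_adjacency] for running the splitting algorithms on
#'   abstract graphs, [graph_edge], [connected_components].
#' @export
similarity_graph <- function(aln, threshold_percent) {
  stopifnot(inherits(aln, "msa"),
            threshold_percent >= 0, threshold_percent <= 100)
  n <- length(aln)
  g <- new.env(parent = emptyenv())
  g$n <- n
  g$threshold <- threshold_percent / 100
  g$mode <- "lazy"
  g$enc <- .encode_rows(aln$seqs)
  g$known <- matrix(FALSE, n, n)
  g$val <- matrix(FALSE, n, n)
  g$n_evals <- 0L
  class(g) <- "sim_graph"
  g
}

#' Build a graph from an explicit adjacency structure
#'
#' Escape hatch for running the splitting algorithms on abstract graphs
#' (used heavily by the test fixtures): vertices are `1..n` and edges come
#' from a symmetric logical adjacency matrix or an edge list.
#'
#' @param adj Symmetric logical/numeric adjacency matrix (diagonal ignored).
#' @return A `sim_graph` object.
#' @export
graph_from_adjacency <- function(adj) {
  adj <- adj != 0
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (!isTRUE(all(adj == t(adj))))
    stop("adjacency matrix must be symmetric")
  diag(adj) <- FALSE
  g <- new.env(parent = emptyenv())
  g$n <- nrow(adj)
  g$threshold <- NA_real_
  g$mode <- "adjacency"
  g$adj <- adj
  g$n_evals <- 0L
  class(g) <- "sim_graph"
  g
}

#' @rdname graph_from_adjacency
#' @param n Number of vertices.
#' @param edges Two-column matrix of vertex index pairs (may be empty).
#' @export
graph_from_edges <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  if (length(edges)) {
    edges <- matrix(as.integer(edges), ncol = 2)
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  graph_from_adjacency(adj)
}

#' @export
print.sim_graph <- function(x, ...) {
  cat(sprintf("<sim_graph> %d vertices, %s, %d pair evaluations\n", x$n,
              if (x$mode == "lazy")
                sprintf("identity threshold %.0f%% (lazy)", 100 * x$threshold)
              else "explicit adjacency",
              x$n_evals))
  invisible(x)
}

# Internal: evaluate (and cache) the edge predicate for one pair.
.eval_pair <- function(g, u, v) {
  enc <- g$enc
  lu <- enc$ungapped[[u]]; lv <- enc$ungapped[[v]]
  if (lu == 0L && lv == 0L)
    stop("percent identity is undefined for two fully gapped rows (vertices ",
         u, ", ", v, ")")
  denom <- if (lu == 0L || lv == 0L) max(lu, lv) else min(lu, lv)
  pid <- sum(enc$codes[[u]] == enc$codes[[v]] &
             enc$resid[[u]] & enc$resid[[v]]) / denom
  e <- pid > g$threshold
  g$val[u, v] <- e; g$val[v, u] <- e
  g$known[u, v] <- TRUE; g$known[v, u] <- TRUE
  g$n_evals <- g$n_evals + 1L
  e
}

#' Query one edge of a similarity graph
#'
#' @param g A `sim_graph`.
#' @param u,v Vertex indices (no self-edges: `graph_edge(g, v, v)` is FALSE).
#' @return Logical: is the pair connected?
#' @export
graph_edge <- function(g, u, v) {
  if (u == v) return(FALSE)
  if (g$mode == "adjacency") return(g$adj[u, v])
  if (g$known[u, v]) return(g$val[u, v])
  .eval_pair(g, u, v)
}

# Internal: TRUE if v has any neighbor in `set`. Stops at the first edge
# found, so fewer pairs may be evaluated than |set|.
.any_edge <- function(g, v, set) {
  if (length(set) == 0L) return(FALSE)
  if (g$mode == "adjacency") return(any(g$adj[v, set]))
  known <- g$known[v, set]
  if (any(g$val[v, set][known])) return(TRUE)
  for (w in set[!known]) {
    if (w != v && .eval_pair(g, v, w)) return(TRUE)
  }
  FALSE
}

# Internal: the neighbors of v within `set` (all pairs evaluated).
.neighbors_within <- function(g, v, set) {
  set <- set[set != v]
  if (length(set) == 0L) return(integer(0))
  if (g$mode == "adjacency") return(set[g$adj[v, set]])
  known <- g$known[v, set]
  for (w in set[!known]) .eval_pair(g, v, w)
  set[g$val[v, set]]
}

#' Number of pairwise identity evaluations performed so far
#'
#' For lazy alignment-backed graphs this counts distinct pairs whose
#' identity has been computed; it can never exceed `choose(n, 2)`.
#'
#' @param g A `sim_graph`.
#' @return Integer count.
#' @export
graph_n_evals <- function(g) g$n_evals

#' Degree of a vertex (evaluates all pairs involving it)
#'
#' @param g A `sim_graph`.
#' @param v Vertex index.
#' @return Integer degree.
#' @export
graph_degree <- function(g, v) length(.neighbors_within(g, v, seq_len(g$n)))

#' Connected components of a similarity graph
#'
#' Components are discovered by breadth-first traversal that queries edges
#' lazily; unreached pairs are never evaluated. The partition is a
#' deterministic property of the graph (no randomness is involved), and
#' components are returned in order of their smallest vertex.
#'
#' @param g A `sim_graph`.
#' @param vertices Vertex subset to partition (default: all vertices).
#' @return List of integer vectors, each sorted ascending.
#' @export
connected_components <- function(g, vertices = seq_len(g$n)) {
  unvisited <- sort(unique(as.integer(vertices)))
  comps <- list()
  while (length(unvisited) > 0L) {
    root <- unvisited[[1L]]
    unvisited <- unvisited[-1L]
    comp <- root
    queue <- root
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- .neighbors_within(g, v, unvisited)
      if (length(nb)) {
        unvisited <- setdiff(unvisited, nb)
        comp <- c(comp, nb)
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
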