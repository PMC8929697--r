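#' Configuration for a train/test split
#'
#' @param p Train/test identity threshold in percent: no returned test
#'   sequence may be more than `p`% identical to any training sequence
#'   (default 25, the usual protein setting; 60 is typical for RNA).
#' @param q Test/test identity threshold in percent (default 50).
#' @param min_train,min_test Minimum acceptable set sizes for a split to
#'   count as successful (defaults 10 and 2).
#' @param mode `"single"` for one run, `"until"` to run up to `n_reps` times
#'   and return the first success, `"best"` to run `n_reps` times and return
#'   the successful split maximizing `|train| * |test|`.
#' @param n_reps Number of repetitions for `"until"`/`"best"` (default 40).
#' @param seed Integer RNG seed; `NULL` uses (and advances) the current RNG
#'   state. Repetition drivers derive a deterministic sub-seed per run.
#' @param p_select Inclusion probability for Independent Selection
#'   (default 0.70).
#' @param blue_greedy_step2 If TRUE, Blue uses the greedy sequential rather
#'   than the random-priority independent set algorithm for its second step.
#' @return A `split_config` list.
#' @export
split_config <- function(p = 25, q = 50, min_train = 10, min_test = 2,
                         mode = c("single", "until", "best"), n_reps = 40,
                         seed = NULL, p_select = 0.70,
                         blue_greedy_step2 = FALSE) {
  mode <- match.arg(mode)
  stopifnot(p >= 0, p <= 100, q >= 0, q <= 100,
            min_train >= 1, min_test >= 1, n_reps >= 1,
            p_select > 0, p_select < 1)
  structure(list(p = p, q = q, min_train = min_train, min_test = min_test,
                 mode = mode, n_reps = as.integer(n_reps), seed = seed,
                 p_select = p_select, blue_greedy_step2 = blue_greedy_step2),
            class = "split_config")
}

new_split_result <- function(train, test, vertices, algorithm, cfg, seed,
                             iteration = 1L, runs_used = 1L) {
  train <- sort(as.integer(train))
  test <- sort(as.integer(test))
  structure(list(
    train = train,
    test = test,
    excluded = setdiff(sort(as.integer(vertices)), c(train, test)),
    algorithm = algorithm,
    seed = seed,
    iteration = iteration,
    runs_used = runs_used,
    success = length(train) >= cfg$min_train && length(test) >= cfg$min_test,
    objective = length(train) * length(test)),
    class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %s: train %d, test %d, excluded %d (%s)\n",
              x$algorithm, length(x$train), length(x$test),
              length(x$excluded),
              if (x$success) "success" else "failed size minima"))
  invisible(x)
}

# ---- step algorithms ------------------------------------------------------

#' Greedy sequential maximal independent set (Cobalt step 2)
#'
#' Scans the vertices in a uniformly random order and adds each vertex to
#' the independent set when none of its neighbors has been added before it.
#' The result is always a maximal independent set. Low-degree vertices
#' (outlier sequences) are favored: a vertex enters whenever all of its
#' neighbors come later in the order.
#'
#' @param g A `sim_graph`.
#' @param vertices Vertex subset to operate on (default: all).
#' @return Sorted integer vector: a maximal independent set within
#'   `vertices`.
#' @export
greedy_sequential_is <- function(g, vertices = seq_len(g$n)) {
  vertices <- as.integer(vertices)
  ord <- vertices[sample.int(length(vertices))]
  U <- integer(0)
  for (v in ord) {
    if (!.any_edge(g, v, U)) U <- c(U, v)
  }
  sort(U)
}

#' Greedy sequential bipartite independent pair (Cobalt step 1)
#'
#' Scans the vertices in a uniformly random order; each vertex flips a fair
#' coin to pick a preferred side and joins it if it has no neighbor already
#' placed on the *opposite* side (edges within a side are allowed — a
#' bipartite independent pair only forbids crossing edges); failing that it
#' tries the other side, and a vertex with neighbors on both sides is
#' excluded. The returned pair has no crossing edges, and the first set is
#' never smaller than the second (sides are swapped at the end if needed;
#' at a tie no swap occurs).
#'
#' @inheritParams greedy_sequential_is
#' @return List with sorted integer vectors `S` (the larger side) and `T`.
#' @export
greedy_sequential_bip <- function(g, vertices = seq_len(g$n)) {
  vertices <- as.integer(vertices)
  n <- length(vertices)
  ord <- vertices[sample.int(n)]
  coins <- stats::runif(n)  # one fair coin per scanned vertex
  S <- integer(0)
  T <- integer(0)
  for (i in seq_len(n)) {
    v <- ord[[i]]
    if (coins[[i]] < 0.5) {
      if (!.any_edge(g, v, T)) S <- c(S, v)
      else if (!.any_edge(g, v, S)) T <- c(T, v)
    } else {
      if (!.any_edge(g, v, S)) T <- c(T, v)
      else if (!.any_edge(g, v, T)) S <- c(S, v)
    }
  }
  if (length(S) < length(T)) { tmp <- S; S <- T; T <- tmp }
  list(S = sort(S), T = sort(T))
}

# label comparison with index tie-break (ties have probability zero with
# real uniforms but are possible in finite precision; determinism matters)
.beats <- function(lab, v, w) {
  lab[[v]] < lab[[w]] || (lab[[v]] == lab[[w]] && v < w)
}

#' Random-priority maximal independent set (Blue step 2)
#'
#' Round-based election: every still-eligible vertex draws a fresh uniform
#' label; vertices whose label is smaller than the labels of all their
#' eligible neighbors join the independent set and knock their neighbors
#' out. Rounds repeat until no eligible vertices remain; the result is a
#' maximal independent set. In each round the chance of selecting a vertex
#' is inversely related to its number of still-eligible neighbors.
#'
#' @inheritParams greedy_sequential_is
#' @return Sorted integer vector: a maximal independent set within
#'   `vertices`.
#' @export
random_priority_is <- function(g, vertices = seq_len(g$n)) {
  live <- sort(as.integer(vertices))
  U <- integer(0)
  lab <- rep(NA_real_, g$n)
  while (length(live) > 0L) {
    lab[live] <- stats::runif(length(live))
    ord <- live[sample.int(length(live))]
    for (v in ord) {
      if (!(v %in% live)) next
      nb <- .neighbors_within(g, v, live)
      if (length(nb) == 0L || all(vapply(nb, function(w) .beats(lab, v, w),
                                         logical(1)))) {
        U <- c(U, v)
        live <- setdiff(live, c(v, nb))
      }
    }
  }
  sort(U)
}

#' Random-priority bipartite independent pair (Blue step 1)
#'
#' Tracks each vertex's eligibility for the two sides separately. Per
#' round: vertices eligible for only one side become candidates for it;
#' doubly eligible vertices pick a side by fair coin; every candidate draws
#' a uniform label. The S-candidates are processed in random order, each
#' joining S when its label is smaller than the labels of all its neighbors
#' that are both T-candidates and still T-eligible (eligibility updates take
#' effect immediately); joining S makes the vertex ineligible for both sides
#' and its neighbors T-ineligible. Surviving T-candidates then join T and
#' make their neighbors S-ineligible. Rounds repeat until no vertex is
#' eligible for either side. No edge crosses the returned pair; the first
#' set is never smaller than the second.
#'
#' @inheritParams greedy_sequential_is
#' @return List with sorted integer vectors `S` (the larger side) and `T`.
#' @export
random_priority_bip <- function(g, vertices = seq_len(g$n)) {
  vertices <- sort(as.integer(vertices))
  LS <- logical(g$n); LS[vertices] <- TRUE
  LT <- logical(g$n); LT[vertices] <- TRUE
  S <- integer(0)
  T <- integer(0)
  lab <- rep(NA_real_, g$n)
  in_CT <- logical(g$n)
  while (any(LS) || any(LT)) {
    only_S <- which(LS & !LT)
    only_T <- which(LT & !LS)
    both <- which(LS & LT)
    coin <- stats::runif(length(both))
    CS <- sort(c(only_S, both[coin < 0.5]))
    CT <- sort(c(only_T, both[coin >= 0.5]))
    cand <- sort(c(CS, CT))
    lab[cand] <- stats::runif(length(cand))
    in_CT[] <- FALSE
    in_CT[CT] <- TRUE
    ordS <- CS[sample.int(length(CS))]
    for (v in ordS) {
      competitors <- .neighbors_within(g, v, which(LT & in_CT))
      if (length(competitors) == 0L ||
          all(vapply(competitors, function(w) .beats(lab, v, w), logical(1)))) {
        S <- c(S, v)
        nbT <- .neighbors_within(g, v, which(LT))
        LT[c(v, nbT)] <- FALSE
        LS[v] <- FALSE
      }
    }
    survivors <- CT[LT[CT]]
    T <- c(T, survivors)
    for (v in survivors) {
      LT[v] <- FALSE
      nbS <- .neighbors_within(g, v, which(LS))
      LS[c(v, nbS)] <- FALSE
    }
  }
  if (length(S) < length(T)) { tmp <- S; S <- T; T <- tmp }
  list(S = sort(S), T = sort(T))
}

# ---- full splitting algorithms -------------------------------------------

#' Split by the Cobalt algorithm
#'
#' Step 1 finds a bipartite independent pair in the p-threshold graph with
#' [greedy_sequential_bip]; the larger side becomes the training set. Step 2
#' extracts a maximal independent set from the q-threshold graph restricted
#' to the smaller side with [greedy_sequential_is]; that becomes the test
#' set. An input that cannot be split at the configured minima returns a
#' result with `success = FALSE` rather than raising an error.
#'
#' @param g_p `sim_graph` at the train/test threshold `p`, over all rows.
#' @param g_q `sim_graph` at the test/test threshold `q`, over the same rows
#'   (only pairs inside the candidate test set are ever evaluated).
#' @param cfg A [split_config].
#' @param vertices Vertex subset to split (default: all).
#' @return A `split_result` with elements `train`, `test`, `excluded`,
#'   `algorithm`, `seed`, `success` and `objective`.
#' @export
split_cobalt <- function(g_p, g_q, cfg = split_config(),
                         vertices = seq_len(g_p$n)) {
  seed <- .use_seed(cfg$seed)
  pair <- greedy_sequential_bip(g_p, vertices)
  test <- greedy_sequential_is(g_q, pair$T)
  new_split_result(pair$S, test, vertices, "cobalt", cfg, seed)
}

#' Split by the Blue algorithm
#'
#' As [split_cobalt], but step 1 uses [random_priority_bip] and step 2 uses
#' [random_priority_is] (or the greedy variant when
#' `cfg$blue_greedy_step2` is TRUE).
#'
#' @inheritParams split_cobalt
#' @return A `split_result`.
#' @export
split_blue <- function(g_p, g_q, cfg = split_config(),
                       vertices = seq_len(g_p$n)) {
  seed <- .use_seed(cfg$seed)
  pair <- random_priority_bip(g_p, vertices)
  test <- if (isTRUE(cfg$blue_greedy_step2)) greedy_sequential_is(g_q, pair$T)
          else random_priority_is(g_q, pair$T)
  new_split_result(pair$S, test, vertices, "blue", cfg, seed)
}

#' Split by the Cluster algorithm (single-linkage clustering)
#'
#' The p-threshold graph is partitioned into connected components
#' (equivalently, single-linkage clusters at identity `p`). The largest
#' component becomes the training set (ties broken toward the component
#' containing the smallest vertex index); the remaining vertices form the
#' candidate test set, from which one vertex is drawn uniformly at random
#' per connected component of the q-threshold graph. The test set is an
#' independent set of the q-graph but, unlike Blue/Cobalt, not necessarily
#' maximal. A family that collapses into one component cannot be split.
#'
#' @inheritParams split_cobalt
#' @return A `split_result`.
#' @export
split_cluster <- function(g_p, g_q, cfg = split_config(),
                          vertices = seq_len(g_p$n)) {
  seed <- .use_seed(cfg$seed)
  comps <- connected_components(g_p, vertices)
  sizes <- lengths(comps)
  big <- which.max(sizes)  # comps ordered by smallest vertex: deterministic tie-break
  train <- comps[[big]]
  rest <- setdiff(as.integer(vertices), train)
  test <- integer(0)
  if (length(rest) > 0L) {
    qcomps <- connected_components(g_q, rest)
    test <- vapply(qcomps, function(cc) cc[[sample.int(length(cc), 1L)]],
                   integer(1))
  }
  new_split_result(train, test, vertices, "cluster", cfg, seed)
}

#' Split by Independent Selection
#'
#' Every vertex joins the training set S independently with probability
#' `cfg$p_select` (0.70 by default). Vertices outside S with no p-edge to
#' any member of S form the candidate test set, reduced to a maximal
#' independent set of the q-graph by [greedy_sequential_is]. The training
#' set is S as drawn; no size-based swap is applied.
#'
#' @inheritParams split_cobalt
#' @return A `split_result`.
#' @export
split_indep_selection <- function(g_p, g_q, cfg = split_config(),
                                  vertices = seq_len(g_p$n)) {
  seed <- .use_seed(cfg$seed)
  vertices <- as.integer(vertices)
  S <- vertices[stats::runif(length(vertices)) < cfg$p_select]
  rest <- setdiff(vertices, S)
  cand <- rest[!vapply(rest, function(v) .any_edge(g_p, v, S), logical(1))]
  test <- greedy_sequential_is(g_q, cand)
  new_split_result(S, test, vertices, "indepsel", cfg, seed)
}

# Set the RNG from cfg$seed if given; return the seed actually associated
# with this run (NA when running off the ambient RNG stream).
.use_seed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) {
    set.seed(seed)
    return(as.integer(seed))
  }
  NA_integer_
}

#' Deterministic sub-seed for repetition i of a master seed
#'
#' @param seed Master integer seed.
#' @param i Run index (1-based).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 16807) %% 2147483647)
}

# ---- repetition drivers ---------------------------------------------------

#' Run a splitter repeatedly, returning the first successful split
#'
#' Runs `split_fn` at most `cfg$n_reps` times with independent sub-seeds
#' derived from `cfg$seed` and returns the first result meeting the size
#' minima, or the last (failed) result if none does. Because the sub-seed
#' schedule is a deterministic function of the master seed, any individual
#' run can be replayed.
#'
#' @param split_fn One of [split_cobalt], [split_blue], [split_cluster],
#'   [split_indep_selection].
#' @inheritParams split_cobalt
#' @return A `split_result`; `runs_used` records how many runs executed.
#' @export
run_until_n <- function(split_fn, g_p, g_q, cfg = split_config(),
                        vertices = seq_len(g_p$n)) {
  master <- if (is.null(cfg$seed)) sample.int(2147483646L, 1L) else cfg$seed
  res <- NULL
  for (i in seq_len(cfg$n_reps)) {
    cfg_i <- cfg
    cfg_i$seed <- sub_seed(master, i)
    res <- split_fn(g_p, g_q, cfg_i, vertices)
    res$iteration <- i
    res$runs_used <- i
    if (res$success) return(res)
  }
  res
}

#' Run a splitter n times, returning the best successful split
#'
#' Runs exactly `cfg$n_reps` times (sub-seeds as in [run_until_n]) and
#' returns the successful split maximizing the product of training and test
#' set sizes (equivalently their geometric mean); ties go to the earliest
#' run. If no run succeeds, the last failed result is returned.
#'
#' @inheritParams run_until_n
#' @return A `split_result`; `iteration` records which run was chosen.
#' @export
best_of_n <- function(split_fn, g_p, g_q, cfg = split_config(),
                      vertices = seq_len(g_p$n)) {
  master <- if (is.null(cfg$seed)) sample.int(2147483646L, 1L) else cfg$seed
  best <- NULL
  last <- NULL
  for (i in seq_len(cfg$n_reps)) {
    cfg_i <- cfg
    cfg_i$seed <- sub_seed(master, i)
    res <- split_fn(g_p, g_q, cfg_i, vertices)
    res$iteration <- i
    last <- res
    if (res$success && (is.null(best) || res$objective > best$objective))
      best <- res
  }
  out <- if (is.null(best)) last else best
  out$runs_used <- cfg$n_reps
  out
}

# ---- high-level interface -------------------------------------------------

.algorithm_fns <- list(cobalt = split_cobalt, blue = split_blue,
                       cluster = split_cluster, indepsel = split_indep_selection)

#' Split an alignment into dissimilar training and test sets
#'
#' High-level driver: builds the p- and q-threshold similarity graphs over
#' the alignment rows and runs the chosen algorithm under the chosen
#' repetition mode. The guarantee of any returned split (successful or not)
#' is that no test row has percent identity above `p`% to any training row
#' and no two test rows are above `q`% identical; rows in neither set are
#' excluded.
#'
#' @param aln An [msa] object (apply [fragment_filter] beforehand if
#'   fragment removal is wanted; the whole-pipeline commands do this).
#' @param algorithm `"cobalt"`, `"blue"`, `"cluster"` or `"indepsel"`.
#' @param cfg A [split_config]; additional arguments in `...` are passed to
#'   [split_config] when `cfg` is missing.
#' @param ... Arguments forwarded to [split_config].
#' @return A `split_result` whose indices refer to rows of `aln`.
#' @examples
#' spec <- family_spec(k_clusters = 2, cluster_sizes = c(12, 12), seed = 1)
#' aln <- generate_family(spec)
#' res <- split_msa(aln, "cobalt", seed = 42)
#' res
#' @export
split_msa <- function(aln, algorithm = c("cobalt", "blue", "cluster",
                                         "indepsel"),
                      cfg = split_config(...), ...) {
  algorithm <- match.arg(algorithm)
  g_p <- similarity_graph(aln, cfg$p)
  g_q <- similarity_graph(aln, cfg$q)
  fn <- .algorithm_fns[[algorithm]]
  switch(cfg$mode,
         single = fn(g_p, g_q, cfg),
         until = run_until_n(fn, g_p, g_q, cfg),
         best = best_of_n(fn, g_p, g_q, cfg))
}

#' Validate a split against the identity criteria
#'
#' Eagerly recomputes every train-by-test and test-by-test percent identity
#' and reports the maxima and any violating pairs. A split passes when all
#' train/test identities are at most `p`/100 and all test/test identities at
#' most `q`/100 (the edge condition is strictly greater-than, so equality is
#' allowed).
#'
#' @param aln The [msa] the split refers to.
#' @param result A `split_result` (or any list with integer `train` and
#'   `test` row indices).
#' @param p,q Thresholds in percent.
#' @return List with `valid` (logical), `max_train_test`, `max_test_test`
#'   (fractions, `NA` when there are no such pairs) and `violations`, a
#'   data frame of offending pairs.
#' @export
validate_split <- function(aln, result, p = 25, q = 50) {
  stopifnot(inherits(aln, "msa"))
  train <- as.integer(result$train)
  test <- as.integer(result$test)
  if (length(c(train, test)) &&
      (max(train, test) > length(aln) || min(train, test, Inf) < 1))
    stop("split indices outside the alignment")
  viol <- list()
  max_tt <- NA_real_
  for (u in train) for (v in test) {
    pid <- percent_identity(aln$seqs[[u]], aln$seqs[[v]])
    if (is.na(max_tt) || pid > max_tt) max_tt <- pid
    if (pid > p / 100)
      viol[[length(viol) + 1L]] <- data.frame(kind = "train-test", u = u,
                                              v = v, pid = pid)
  }
  max_qq <- NA_real_
  if (length(test) > 1L) {
    for (i in seq_len(length(test) - 1L)) for (j in (i + 1L):length(test)) {
      u <- test[[i]]; v <- test[[j]]
      pid <- percent_identity(aln$seqs[[u]], aln$seqs[[v]])
      if (is.na(max_qq) || pid > max_qq) max_qq <- pid
      if (pid > q / 100)
        viol[[length(viol) + 1L]] <- data.frame(kind = "test-test", u = u,
                                                v = v, pid = pid)
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol)
                else data.frame(kind = character(0), u = integer(0),
                                v = integer(0), pid = numeric(0))
  list(valid = nrow(violations) == 0L,
       max_train_test = max_tt,
       max_test_test = max_qq,
       violations = violations)
}
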