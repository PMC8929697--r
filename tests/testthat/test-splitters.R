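test_that("greedy sequential IS: known small-graph behavior", {
  # edgeless graph: everything is selected
  g <- generate_graph("edgeless", n = 5)
  set.seed(1)
  expect_equal(greedy_sequential_is(g), 1:5)
  # path a-b-c: result is {b} iff b drawn first, P = 1/3 by enumeration
  d <- enum_greedy_is_dist(catalogue_graphs()$P3)
  expect_equal(unname(d[["2"]]), 1 / 3)
  expect_equal(unname(d[["1,3"]]), 2 / 3)
  g3 <- generate_graph("path", n = 3)
  set.seed(100)
  hits <- sum(replicate(6000, identical(greedy_sequential_is(g3), 2L)))
  expect_lt(abs(hits / 6000 - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 6000))
  # complete graph: exactly one vertex, uniform over vertices
  d <- enum_greedy_is_dist(catalogue_graphs()$K3)
  expect_equal(as.numeric(d[c("1", "2", "3")]), rep(1 / 3, 3))
  gk <- generate_graph("complete", n = 4)
  set.seed(2)
  out <- replicate(2000, greedy_sequential_is(gk))
  expect_true(all(lengths(out) == 1))
  counts <- table(factor(unlist(out), levels = 1:4))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("greedy sequential BIP: placement rules and swap", {
  # single vertex always lands in S (swap guarantees |S| >= |T|)
  g1 <- generate_graph("edgeless", n = 1)
  for (s in 1:10) {
    set.seed(s)
    b <- greedy_sequential_bip(g1)
    expect_equal(b$S, 1L)
    expect_length(b$T, 0)
  }
  # a connected pair can never be split across sides: no crossing edges
  g2 <- generate_graph("complete", n = 2)
  for (s in 1:25) {
    set.seed(s)
    b <- greedy_sequential_bip(g2)
    expect_true(no_crossing_edges(g2$adj, b$S, b$T))
    expect_gte(length(b$S), length(b$T))
  }
  # triangle: all three vertices end up on one side, none excluded
  gk <- generate_graph("complete", n = 3)
  set.seed(3)
  for (i in 1:25) {
    b <- greedy_sequential_bip(gk)
    expect_equal(b$S, 1:3)
  }
})

test_that("random priority IS selects each endpoint of an edge equally", {
  g <- generate_graph("complete", n = 2)
  set.seed(17)
  picks <- replicate(4000, random_priority_is(g))
  expect_true(all(lengths(picks) == 1))
  frac1 <- mean(unlist(picks) == 1L)
  expect_lt(abs(frac1 - 0.5), 3 * sqrt(0.25 / 4000))
  # edgeless: everything selected in round one
  ge <- generate_graph("edgeless", n = 7)
  expect_equal(random_priority_is(ge), 1:7)
})

test_that("both IS algorithms return maximal independent sets", {
  set.seed(23)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    g <- generate_graph("erdos_renyi", n = n, prob = sample(c(.1, .3, .6), 1),
                        seed = sample.int(1e6, 1))
    u1 <- greedy_sequential_is(g)
    u2 <- random_priority_is(g)
    expect_true(is_maximal_is(g$adj, u1, 1:n))
    expect_true(is_maximal_is(g$adj, u2, 1:n))
    # restricted to a subset: maximal within the subset
    sub <- sort(sample(1:n, max(2, n %/% 2)))
    u3 <- random_priority_is(g, sub)
    expect_true(is_maximal_is(g$adj, u3, sub))
  }
})

test_that("random priority BIP returns crossing-free pairs with |S| >= |T|", {
  # edgeless odd graph: every vertex placed in round one, none excluded
  ge <- generate_graph("edgeless", n = 9)
  set.seed(31)
  b <- random_priority_bip(ge)
  expect_equal(sort(c(b$S, b$T)), 1:9)
  expect_gte(length(b$S), length(b$T))
  # single vertex: S = {v}
  set.seed(31)
  b1 <- random_priority_bip(generate_graph("edgeless", n = 1))
  expect_equal(b1$S, 1L)
  set.seed(32)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    g <- generate_graph("erdos_renyi", n = n, prob = sample(c(.1, .3, .6), 1),
                        seed = sample.int(1e6, 1))
    b <- random_priority_bip(g)
    expect_true(no_crossing_edges(g$adj, b$S, b$T))
    expect_gte(length(b$S), length(b$T))
    expect_lte(length(intersect(b$S, b$T)), 0)
  }
})

test_that("cobalt and blue splits are valid on structured families", {
  aln <- generate_family(family_spec(2, c(12, 12), seed = 8))
  g_p <- similarity_graph(aln, 25)
  g_q <- similarity_graph(aln, 50)
  cfg <- split_config(seed = 1, n_reps = 40)
  for (fn in list(split_cobalt, split_blue)) {
    res <- run_until_n(fn, g_p, g_q, cfg)
    expect_true(res$success)
    expect_true(validate_split(aln, res, 25, 50)$valid)
    # partition property
    expect_setequal(c(res$train, res$test, res$excluded), 1:24)
  }
  # n = 1 family: train gets the vertex, test empty, success FALSE
  one <- msa_subset(aln, 1)
  r1 <- split_cobalt(similarity_graph(one, 25), similarity_graph(one, 50),
                     split_config(seed = 2))
  expect_equal(r1$train, 1L)
  expect_length(r1$test, 0)
  expect_false(r1$success)
})

test_that("cluster splits by single-linkage components; bridges collapse it", {
  # explicit components {1,2,3}, {4}, {5}; no q-edges among {4, 5}
  g_p <- graph_from_edges(5, rbind(c(1, 2), c(2, 3)))
  g_q <- generate_graph("edgeless", n = 5)
  res <- split_cluster(g_p, g_q, split_config(min_train = 1, min_test = 1,
                                              seed = 4))
  expect_equal(res$train, 1:3)
  expect_equal(res$test, 4:5)
  expect_true(res$success)
  # the motivating failure mode: one bridging chimera collapses the family
  aln <- generate_family(family_spec(2, c(12, 12), n_bridges = 1, seed = 8))
  g_p <- similarity_graph(aln, 25)
  g_q <- similarity_graph(aln, 50)
  res <- split_cluster(g_p, g_q, split_config(seed = 5))
  expect_false(res$success)
  expect_length(res$test, 0)
  # removing the bridge row restores two components and a successful split
  nobridge <- msa_subset(aln, 1:24)
  res2 <- split_cluster(similarity_graph(nobridge, 25),
                        similarity_graph(nobridge, 50),
                        split_config(seed = 5))
  expect_true(res2$success)
  expect_length(res2$train, 12)
  expect_true(validate_split(nobridge, res2, 25, 50)$valid)
})

test_that("independent selection draws the training set as binomial trials", {
  g <- generate_graph("edgeless", n = 1000)
  cfg <- split_config(min_train = 1, min_test = 1, seed = 77)
  res <- split_indep_selection(g, g, cfg)
  # |S| ~ Binomial(1000, 0.7)
  expect_lt(abs(length(res$train) - 700), 5 * sqrt(1000 * .7 * .3))
  expect_setequal(c(res$train, res$test), 1:1000)  # isolated: rest all in test
  # complete graph: test empty whenever S is nonempty
  gk <- generate_graph("complete", n = 30)
  res <- split_indep_selection(gk, gk, split_config(seed = 78))
  expect_gt(length(res$train), 0)
  expect_length(res$test, 0)
  expect_false(res$success)
})

test_that("every algorithm is deterministic under a fixed seed", {
  aln <- generate_family(family_spec(2, c(8, 8), n_bridges = 1,
                                     n_outliers = 1, seed = 55))
  g_p <- similarity_graph(aln, 25)
  g_q <- similarity_graph(aln, 50)
  for (fn in list(split_cobalt, split_blue, split_cluster,
                  split_indep_selection)) {
    a <- fn(g_p, g_q, split_config(seed = 123, min_train = 2, min_test = 1))
    b <- fn(g_p, g_q, split_config(seed = 123, min_train = 2, min_test = 1))
    expect_identical(a[c("train", "test", "excluded", "success")],
                     b[c("train", "test", "excluded", "success")])
  }
})

test_that("run-until-n stops at the first success and replays by sub-seed", {
  aln <- generate_family(family_spec(2, c(12, 12), seed = 8))
  g_p <- similarity_graph(aln, 25)
  g_q <- similarity_graph(aln, 50)
  cfg <- split_config(seed = 9, n_reps = 40)
  res <- run_until_n(split_cobalt, g_p, g_q, cfg)
  # replaying the chosen sub-seed reproduces the returned split
  cfg1 <- cfg; cfg1$seed <- sub_seed(9, res$runs_used)
  replay <- split_cobalt(g_p, g_q, cfg1)
  expect_identical(replay$train, res$train)
  expect_identical(replay$test, res$test)
  # impossible minima: all reps consumed, success FALSE
  cfg_imp <- split_config(min_train = 1000, min_test = 2, seed = 9, n_reps = 5)
  res <- run_until_n(split_cobalt, g_p, g_q, cfg_imp)
  expect_false(res$success)
  expect_equal(res$runs_used, 5)
})

test_that("run-until-n run count is geometric on a coin-flip fixture", {
  # two isolated vertices, indep selection at p_select 1/2:
  # success iff exactly one lands in S, probability 1/2
  g <- generate_graph("edgeless", n = 2)
  cfg <- split_config(min_train = 1, min_test = 1, p_select = 0.5,
                      n_reps = 60)
  set.seed(300)
  runs <- vapply(1:400, function(i) {
    cfg$seed <- i
    run_until_n(split_indep_selection, g, g, cfg)$runs_used
  }, numeric(1))
  expect_lt(abs(mean(runs) - 2), 3 * sqrt(2 / 400))  # geometric mean 2, var 2
})

test_that("best-of-n maximizes |train| * |test| with earliest-run ties", {
  aln <- generate_family(family_spec(3, c(8, 8, 8), seed = 14))
  g_p <- similarity_graph(aln, 25)
  g_q <- similarity_graph(aln, 50)
  cfg <- split_config(min_train = 4, min_test = 1, seed = 21, n_reps = 12)
  best <- best_of_n(split_cobalt, g_p, g_q, cfg)
  expect_equal(best$runs_used, 12)
  # replay the full schedule: best objective among successes, earliest tie
  objectives <- vapply(1:12, function(i) {
    cfg_i <- cfg; cfg_i$seed <- sub_seed(21, i)
    r <- split_cobalt(g_p, g_q, cfg_i)
    if (r$success) r$objective else -1
  }, numeric(1))
  expect_equal(best$objective, max(objectives))
  expect_equal(best$iteration, which.max(objectives))
  # n_reps = 1 is identical to a single run under the sub-seed
  cfg1 <- split_config(seed = 21, n_reps = 1)
  b1 <- best_of_n(split_cobalt, g_p, g_q, cfg1)
  cfg_s <- split_config(seed = sub_seed(21, 1))
  s1 <- split_cobalt(g_p, g_q, cfg_s)
  expect_identical(b1$train, s1$train)
  expect_identical(b1$test, s1$test)
})

test_that("blue on an edgeless family succeeds per the binomial side split", {
  # 12 isolated vertices: random-priority BIP sides are a fair binomial
  # split; success at 10/2 requires sides of exactly 10 and 2
  g <- generate_graph("edgeless", n = 12)
  p_success <- 2 * choose(12, 10) / 2^12
  set.seed(61)
  succ <- mean(vapply(1:3000, function(i) {
    split_blue(g, g, split_config(seed = i))$success
  }, logical(1)))
  expect_lt(abs(succ - p_success), 3 * sqrt(p_success * (1 - p_success) / 3000))
})

test_that("validate_split reports violations and passes vacuously", {
  aln <- generate_family(family_spec(1, 6, within_identity = 0.40, seed = 2))
  # hand-built violating pair: two same-cluster rows (pid ~ 0.40 > 0.25)
  bad <- list(train = 1:3, test = 4:6)
  rep <- validate_split(aln, bad, p = 25, q = 50)
  expect_false(rep$valid)
  expect_true(all(rep$violations$kind == "train-test"))
  expect_gt(rep$max_train_test, 0.25)
  # empty test passes vacuously
  rep2 <- validate_split(aln, list(train = 1:6, test = integer(0)), 25, 50)
  expect_true(rep2$valid)
  expect_true(is.na(rep2$max_train_test))
  expect_error(validate_split(aln, list(train = 1, test = 99), 25, 50),
               "outside")
})

test_that("split_msa drives all algorithms and modes from an alignment", {
  aln <- generate_family(family_spec(2, c(12, 12), seed = 8))
  for (alg in c("cobalt", "blue", "cluster", "indepsel")) {
    res <- split_msa(aln, alg, split_config(seed = 5, n_reps = 20,
                                            mode = "until"))
    expect_s3_class(res, "split_result")
    expect_true(validate_split(aln, res, 25, 50)$valid)
  }
})
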