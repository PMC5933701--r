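# A small map for query tests: chain A -> B -> C plus a weak edge and a
# hypothetical edge.
query_fixture <- function() {
  m <- research_map("q")
  for (x in worked_example()) {
    m <- add_experiment(m, experiment(ph("A"), ph("B"), x$exp_class, x$outcome))
  }                                         # A -> B scores 0.1625
  m <- add_experiment(m, experiment(ph("B"), ph("C"), "PI", "NO_CHANGE"))  # 0.0625
  m <- add_hypothesis(m, hypothesis(ph("C"), ph("D"), "EXCITATORY"))
  as_global_map(m)
}

test_that("term search is case-insensitive substring match over What/Where/When", {
  m <- research_map("m")
  m <- add_experiment(m, experiment(ph("CREB", "lateral amygdala", "training"),
                                    ph("Arc"), "PI", "INCREASE"))
  g <- as_global_map(m)
  expect_identical(find_nodes(g, "creb"), node_key(ph("CREB", "lateral amygdala", "training")))
  expect_identical(find_nodes(g, "AMYGDALA"), node_key(ph("CREB", "lateral amygdala", "training")))
  expect_identical(find_nodes(g, "training"), node_key(ph("CREB", "lateral amygdala", "training")))
  expect_length(find_nodes(g, "hippocampus"), 0)
  expect_error(find_nodes(g, "  "), "non-empty")
})

test_that("neighborhood respects the hop bound", {
  g <- query_fixture()
  sub1 <- neighborhood(g, query_spec(term = "A", max_hops = 1))
  expect_setequal(sub1$nodes$key, c(key_of("A"), key_of("B")))
  expect_identical(length(sub1$edges), 1L)
  sub2 <- neighborhood(g, query_spec(term = "A", max_hops = 2))
  expect_setequal(sub2$nodes$key, c(key_of("A"), key_of("B"), key_of("C")))
  # no seed match: empty subgraph, not an error
  empty <- neighborhood(g, query_spec(term = "zebrafish"))
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("score bounds filter empirical edges before traversal", {
  g <- query_fixture()
  sub <- neighborhood(g, query_spec(term = "B", max_hops = 1, score_min = 0.15))
  edf <- global_edges(sub)
  expect_identical(nrow(edf[edf$empirical, ]), 1L)
  expect_equal(edf$score[edf$empirical], 0.1625)
  # the weak 0.0625 edge no longer connects B to C
  expect_false(key_of("C") %in% sub$nodes$key)
  # score_max alone keeps only the weak edge
  sub_lo <- neighborhood(g, query_spec(term = "B", max_hops = 1, score_max = 0.1))
  edf_lo <- global_edges(sub_lo)
  expect_equal(edf_lo$score[edf_lo$empirical], 0.0625)
})

test_that("hypothetical edges are included or dropped by flag", {
  g <- query_fixture()
  with_h <- neighborhood(g, query_spec(term = "C", max_hops = 1))
  expect_true(key_of("D") %in% with_h$nodes$key)
  without_h <- neighborhood(g, query_spec(term = "C", max_hops = 1,
                                          include_hypothetical = FALSE))
  expect_false(key_of("D") %in% without_h$nodes$key)
})

test_that("direction constrains traversal; default ignores direction", {
  g <- query_fixture()
  out_only <- neighborhood(g, query_spec(term = "B", max_hops = 1, direction = "out",
                                         include_hypothetical = FALSE))
  expect_setequal(out_only$nodes$key, c(key_of("B"), key_of("C")))
  in_only <- neighborhood(g, query_spec(term = "B", max_hops = 1, direction = "in",
                                        include_hypothetical = FALSE))
  expect_setequal(in_only$nodes$key, c(key_of("A"), key_of("B")))
})

test_that("neighborhoods are nested in max_hops and monotone in the score band", {
  set.seed(404)
  g <- as_global_map(generate_fixture(8, 16, 3, seed = 99))
  term <- "phen01"
  for (k in 1:3) {
    a <- neighborhood(g, query_spec(term = term, max_hops = k))
    b <- neighborhood(g, query_spec(term = term, max_hops = k + 1))
    expect_true(all(a$nodes$key %in% b$nodes$key))
    expect_true(all(names(a$edges) %in% names(b$edges)))
  }
  narrow <- neighborhood(g, query_spec(term = term, max_hops = 2,
                                       score_min = 0.1, score_max = 0.3))
  wide <- neighborhood(g, query_spec(term = term, max_hops = 2,
                                     score_min = 0, score_max = 1))
  expect_true(all(names(narrow$edges) %in% names(wide$edges)))
})

test_that("pair search matches Agent and Target terms directionally", {
  m <- research_map("pmid1")
  for (x in worked_example()) m <- add_experiment(m, x)
  g <- as_global_map(m)
  hit <- pair_search(g, "CREB", "Arc")
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$relation, "NO_CONNECTION")
  expect_identical(nrow(pair_search(g, "Arc", "CREB")), 0L)

  # terms matching several nodes return the union of qualifying edges
  g2 <- query_fixture()
  m3 <- research_map("two")
  m3 <- add_experiment(m3, experiment(ph("kinase alpha"), ph("target"), "PI", "INCREASE"))
  m3 <- add_experiment(m3, experiment(ph("kinase beta"), ph("target"), "PI", "DECREASE"))
  hits <- pair_search(as_global_map(m3), "kinase", "target")
  expect_identical(nrow(hits), 2L)
})

test_that("connectivity profile counts first-reachable nodes per hop, undirected", {
  m <- research_map("path")
  m <- pin_relation(m, "A", "B", "EXCITATORY")
  m <- pin_relation(m, "B", "C", "EXCITATORY")
  m <- pin_relation(m, "C", "D", "EXCITATORY")
  m <- add_experiment(m, experiment(ph("X"), ph("Y"), "PI", "INCREASE"))  # disconnected
  g <- as_global_map(m)
  prof <- connectivity_profile(g, key_of("A"), 3)
  expect_identical(prof$nodes, c(1L, 2L, 3L))
  # direction ignored: D reaches everything upstream too
  expect_identical(connectivity_profile(g, key_of("D"), 3)$nodes, c(1L, 2L, 3L))
  # cumulative counts are monotone and bounded by |nodes| - |seeds|
  prof6 <- connectivity_profile(g, key_of("A"), 6)
  expect_true(all(diff(prof6$nodes) >= 0))
  expect_lte(max(prof6$nodes), nrow(g$nodes) - 1L)
  # the disconnected component is never counted from A
  expect_false(any(prof6$nodes > 3))
  expect_error(connectivity_profile(g, "nope", 2), "node keys")
})
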