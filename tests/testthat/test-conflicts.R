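test_that("path sign composes edge signs multiplicatively", {
  expect_identical(path_sign(c("EXCITATORY", "EXCITATORY", "EXCITATORY")), 1)
  expect_identical(path_sign(c("EXCITATORY", "INHIBITORY")), -1)
  expect_identical(path_sign(c("INHIBITORY", "INHIBITORY")), 1)
  expect_error(path_sign(character(0)), "at least one")
  expect_error(path_sign(c("EXCITATORY", "NO_CONNECTION")), "Excitatory or Inhibitory")
})

test_that("the six-node benchmark yields exactly its two known conflicts", {
  m <- conflict_benchmark_map()
  cf <- detect_conflicts(m)
  expect_length(cf, 2)
  paths <- lapply(cf, function(x) x$path_nodes)
  expect_true(any(vapply(paths, identical, TRUE, key_of(c("A", "E", "D", "B")))))
  expect_true(any(vapply(paths, identical, TRUE, key_of(c("D", "E", "A", "C")))))
  for (x in cf) {
    expect_identical(x$sign, 1)
    expect_true(all(x$path_relations == "EXCITATORY"))
    # endpoints of the path match the independence edge, either orientation
    ends <- c(x$path_nodes[1], x$path_nodes[length(x$path_nodes)])
    expect_setequal(ends, x$independence)
  }
})

test_that("graphs without independence findings or without signed paths are conflict-free", {
  m <- research_map("signed-only")
  m <- pin_relation(m, "A", "B", "EXCITATORY")
  m <- pin_relation(m, "B", "C", "INHIBITORY")
  expect_length(detect_conflicts(m), 0)

  m2 <- research_map("n-only")
  m2 <- pin_relation(m2, "A", "B", "NO_CONNECTION")
  expect_length(detect_conflicts(m2), 0)
})

test_that("a direct signed edge conflicts with an independence finding on the same pair", {
  m <- research_map("minimal")
  m <- pin_relation(m, "A", "B", "NO_CONNECTION")
  m <- add_experiment(m, experiment(ph("A"), ph("B"), "NI", "DECREASE",
                                    experiment_id = "x"))
  # both results sit on the same directed edge -> pooled evidence, no conflict
  expect_length(detect_conflicts(m), 0)

  # but a signed edge in the opposite orientation does conflict
  m2 <- research_map("minimal2")
  m2 <- pin_relation(m2, "A", "B", "NO_CONNECTION")
  m2 <- pin_relation(m2, "B", "A", "EXCITATORY")
  cf <- detect_conflicts(m2)
  expect_length(cf, 1)
  expect_length(cf[[1]]$path_relations, 1)
})

test_that("inhibitory pathways also conflict with independence", {
  m <- research_map("inhib")
  m <- pin_relation(m, "A", "B", "NO_CONNECTION")
  m <- pin_relation(m, "A", "C", "INHIBITORY")
  m <- pin_relation(m, "C", "B", "EXCITATORY")
  cf <- detect_conflicts(m)
  expect_length(cf, 1)
  expect_identical(cf[[1]]$sign, -1)
})

test_that("forbidden causation derives the benchmark's mutual exclusion", {
  fc <- forbidden_causation(conflict_benchmark_map())
  pairs <- paste(fc$cause, fc$effect, sep = " => ")
  expect_true(paste(key_of("A"), key_of("D"), sep = " => ") %in% pairs)
  expect_true(paste(key_of("D"), key_of("A"), sep = " => ") %in% pairs)
  expect_false(any(fc$cause == fc$effect))

  expect_identical(nrow(forbidden_causation(research_map("empty-ish"))), 0L)
  m <- pin_relation(research_map("e-only"), "A", "B", "EXCITATORY")
  expect_identical(nrow(forbidden_causation(m)), 0L)
})

test_that("conflict detection agrees with exhaustive enumeration on random graphs", {
  set.seed(505)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    nodes <- sprintf("N%d", 1:n)
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs <- pairs[sample(nrow(pairs), sample(3:10, 1)), ]
    pairs$relation <- sample(RELATIONS, nrow(pairs), replace = TRUE)
    m <- research_map(sprintf("rand%d", rep))
    for (i in seq_len(nrow(pairs))) {
      m <- pin_relation(m, pairs$from[i], pairs$to[i], pairs$relation[i])
    }
    maxlen <- sample(2:4, 1)
    got <- detect_conflicts(m, max_path_len = maxlen)

    signed <- pairs[pairs$relation != "NO_CONNECTION", ]
    signed <- data.frame(from = vapply(signed$from, key_of, ""),
                         to = vapply(signed$to, key_of, ""))
    npairs <- pairs[pairs$relation == "NO_CONNECTION", ]
    npairs <- data.frame(from = vapply(npairs$from, key_of, ""),
                         to = vapply(npairs$to, key_of, ""))
    want <- oracle_conflicts(signed, npairs, maxlen)
    expect_identical(length(got), length(want), info = sprintf("rep %d", rep))
    got_paths <- sort(vapply(got, function(x) paste(x$path_nodes, collapse = ">"), ""))
    want_paths <- sort(vapply(want, function(x) paste(x$path, collapse = ">"), ""))
    expect_identical(got_paths, want_paths)
  }
})

test_that("conflicts shrink monotonically with min_score and max_path_len", {
  g <- as_global_map(generate_fixture(7, 14, 0, seed = 11, agreement_prob = 1))
  base <- detect_conflicts(g, max_path_len = 4, min_score = 0)
  fewer_len <- detect_conflicts(g, max_path_len = 2, min_score = 0)
  fewer_score <- detect_conflicts(g, max_path_len = 4, min_score = 0.08)
  expect_lte(length(fewer_len), length(base))
  expect_lte(length(fewer_score), length(base))
})

test_that("conflict structure is invariant under node relabeling", {
  build <- function(names) {
    m <- research_map("relabel")
    m <- pin_relation(m, names[1], names[2], "NO_CONNECTION")
    m <- pin_relation(m, names[1], names[3], "EXCITATORY")
    m <- pin_relation(m, names[3], names[2], "EXCITATORY")
    m
  }
  a <- detect_conflicts(build(c("A", "B", "C")))
  b <- detect_conflicts(build(c("GluA1", "memory", "PKA")))
  expect_identical(length(a), length(b))
  expect_identical(vapply(a, function(x) length(x$path_nodes), 0L),
                   vapply(b, function(x) length(x$path_nodes), 0L))
})

test_that("hypothetical edges join conflict analysis only on request", {
  m <- research_map("hyp")
  m <- pin_relation(m, "A", "B", "NO_CONNECTION")
  m <- add_hypothesis(m, hypothesis(ph("A"), ph("C"), "EXCITATORY"))
  m <- add_hypothesis(m, hypothesis(ph("C"), ph("B"), "EXCITATORY"))
  expect_length(detect_conflicts(m), 0)
  expect_length(detect_conflicts(m, include_hypothetical = TRUE), 1)
})

test_that("template matching finds all and only the label-respecting bindings", {
  g <- as_global_map(conflict_benchmark_map())
  motif <- data.frame(from = c("n1", "n2", "n3", "n1"),
                      to = c("n2", "n3", "n4", "n4"),
                      relation = c("E", "E", "E", "N"))
  hits <- match_template(g, motif)
  expect_length(hits, 2)
  expect_setequal(
    vapply(hits, function(h) paste(h[c("n1", "n4")], collapse = "~"), ""),
    c(paste(key_of(c("A", "B")), collapse = "~"),
      paste(key_of(c("D", "C")), collapse = "~")))

  absent <- data.frame(from = "u", to = "v", relation = "I")
  expect_length(match_template(g, absent), 0)

  m <- research_map("three-e")
  m <- pin_relation(m, "A", "B", "EXCITATORY")
  m <- pin_relation(m, "B", "C", "EXCITATORY")
  m <- pin_relation(m, "A", "C", "EXCITATORY")
  single <- data.frame(from = "u", to = "v", relation = "E")
  expect_length(match_template(m, single), 3)
})

test_that("template matching agrees with exhaustive assignment enumeration", {
  set.seed(606)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    nodes <- sprintf("N%d", 1:n)
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs <- pairs[sample(nrow(pairs), sample(4:8, 1)), ]
    pairs$relation <- sample(RELATIONS, nrow(pairs), replace = TRUE)
    m <- research_map(sprintf("tm%d", rep))
    for (i in seq_len(nrow(pairs))) {
      m <- pin_relation(m, pairs$from[i], pairs$to[i], pairs$relation[i])
    }
    template <- data.frame(from = c("x", "y"), to = c("y", "z"),
                           relation = sample(RELATIONS, 2, replace = TRUE))
    got <- match_template(m, template)
    facts <- data.frame(from = vapply(pairs$from, key_of, ""),
                        to = vapply(pairs$to, key_of, ""),
                        relation = pairs$relation)
    want <- oracle_match(facts, template)
    canon <- function(lst) sort(vapply(lst, function(h)
      paste(h[c("x", "y", "z")], collapse = "|"), ""))
    expect_identical(canon(got), canon(want), info = sprintf("rep %d", rep))
  }
})
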