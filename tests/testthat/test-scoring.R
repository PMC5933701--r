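test_that("posterior means implement Laplace-smoothed class rows", {
  zero <- matrix(0L, 4, 3, dimnames = list(EXPERIMENT_CLASSES, RELATIONS))
  expect_equal(unname(posterior_means(zero)), matrix(1/3, 4, 3))

  x <- zero; x["POS_INTERVENTION", "NO_CONNECTION"] <- 1L
  expect_equal(unname(posterior_means(x)["POS_INTERVENTION", ]),
               c(0.25, 0.50, 0.25))

  x["POS_INTERVENTION", "NO_CONNECTION"] <- 2L
  expect_equal(unname(posterior_means(x)["POS_INTERVENTION", ]),
               c(0.2, 0.6, 0.2))

  expect_equal(rowSums(posterior_means(x)), setNames(rep(1, 4), EXPERIMENT_CLASSES))
  expect_error(posterior_means(zero, matrix(0, 4, 3)), "positive")
})

test_that("convergence mean averages the class rows", {
  u <- rep(1/3, 3)
  theta <- rbind(u, u, u, u)
  expect_equal(unname(convergence_mean(theta)), u)

  theta <- rbind(c(.25, .5, .25), u, u, u)
  expect_equal(unname(convergence_mean(theta)[2]), 0.375)

  theta <- rbind(c(.2, .6, .2), c(.25, .5, .25), u, u)
  expect_equal(unname(convergence_mean(theta)[2]), (0.6 + 0.5 + 2/3) / 4)
  expect_equal(round(unname(convergence_mean(theta)[2]), 4), 0.4417)
})

test_that("relation assignment takes a strict argmax and ties are indeterminate", {
  expect_identical(assign_relation(c(1/3, 1/3, 1/3)), INDETERMINATE)
  expect_identical(assign_relation(c(0.3208, 0.4208, 0.2584) /
                                     sum(c(0.3208, 0.4208, 0.2584))), "NO_CONNECTION")
  expect_identical(assign_relation(c(0.45, 0.45, 0.10)), INDETERMINATE)
  expect_identical(assign_relation(c(0.5, 0.3, 0.2)), "EXCITATORY")
})

test_that("the edge score rescales the dominant component and vanishes on ties", {
  expect_equal(edge_score(c(0.3125, 0.375, 0.3125)), 0.0625)
  expect_equal(edge_score(c(0.3, 0.4, 0.3)), 0.1, tolerance = 1e-12)
  expect_true(is.na(edge_score(rep(1/3, 3))))
})

test_that("the worked no-change sequence scores 0.0625 -> 0.1000 -> 0.1625", {
  traj <- score_trajectory(worked_example())
  expect_equal(traj$score, c(0.0625, 0.1000, 0.1625))
  expect_identical(unique(traj$relation), "NO_CONNECTION")
  # increments: each consistent same-class repeat adds less than the last
  expect_equal(diff(c(0, traj$score))[1:2], c(0.0625, 0.0375))
})

test_that("conflicting fourth experiments lower the score as printed", {
  base <- worked_example()
  s_pno <- score_edge(c(base, list(exp_ab("PNO", "INCREASE"))))
  expect_identical(s_pno$relation, "NO_CONNECTION")
  expect_equal(display_score(s_pno$score), 0.1313)
  expect_equal(s_pno$score, 0.13125, tolerance = 1e-12)
  expect_equal(round(unname(s_pno$theta_bar), 4), c(0.3208, 0.4208, 0.2583))

  s_pi <- score_edge(c(base, list(exp_ab("PI", "INCREASE"))))
  expect_identical(s_pi$relation, "NO_CONNECTION")
  expect_equal(s_pi$score, 0.1250, tolerance = 1e-12)
  # a conflict inside an already-represented class costs more
  expect_lt(s_pi$score, s_pno$score)
})

test_that("the shorthand-table configuration counts 5 Excitatory vs 1 Inhibitory", {
  exps <- c(replicate(4, exp_ab("PI", "INCREASE"), simplify = FALSE),
            list(exp_ab("PNO", "DECREASE"), exp_ab("NNO", "DECREASE")))
  counts <- evidence_counts(exps)
  expect_identical(sum(counts[, "EXCITATORY"]), 5L)
  expect_identical(sum(counts[, "INHIBITORY"]), 1L)
  expect_identical(sum(counts[, "NO_CONNECTION"]), 0L)
  es <- score_counts(counts)
  expect_identical(es$relation, "EXCITATORY")
  # class E-components: PI (1+4)/(3+4), PNO (1+0)/(3+1), NNO (1+1)/(3+1),
  # NI untouched at 1/3
  expect_equal(es$score, 1.5 * ((5/7 + 1/4 + 1/2 + 1/3) / 4 - 1/3),
               tolerance = 1e-12)
})

test_that("four consistent experiments, one per class, score exactly 0.25", {
  exps <- lapply(EXPERIMENT_CLASSES, function(cls) {
    exp_ab(cls, switch(cls,
                       POS_INTERVENTION = "INCREASE",
                       POS_NONINTERVENTION = "INCREASE",
                       NEG_NONINTERVENTION = "DECREASE",
                       NEG_INTERVENTION = "DECREASE"))
  })
  es <- score_edge(exps)
  expect_identical(es$relation, "EXCITATORY")
  expect_equal(es$score, 0.25, tolerance = 1e-12)
})

test_that("scoring depends only on the counts, not the experiment order", {
  set.seed(101)
  for (i in 1:50) {
    exps <- random_experiments(sample(1:12, 1))
    s1 <- score_edge(exps)
    s2 <- score_edge(exps[sample(length(exps))])
    expect_identical(s1$relation, s2$relation)
    expect_equal(s1$score, s2$score, tolerance = 1e-15)
  }
})

test_that("scores stay in (0,1) and decompose into bounded class contributions", {
  set.seed(202)
  for (i in 1:50) {
    exps <- random_experiments(sample(1:15, 1))
    es <- score_edge(exps)
    if (es$relation == INDETERMINATE) next
    expect_gt(es$score, 0)
    expect_lt(es$score, 1)
    # score decomposes as sum over classes of (3/8) (theta[c, r*] - 1/3)
    r_star <- es$relation
    contrib <- (3 / 8) * (es$theta[, r_star] - 1 / 3)
    expect_equal(sum(contrib), es$score, tolerance = 1e-12)
    expect_true(all(contrib > -1 / 8 & contrib < 0.25))
    # a class whose evidence all supports r* contributes positively
    supporting <- es$counts[, r_star] > 0 &
      rowSums(es$counts) == es$counts[, r_star]
    expect_true(all(contrib[supporting] > 0))
  }
})

test_that("consistency grows the score with strictly diminishing increments", {
  exps <- replicate(8, exp_ab("PI", "INCREASE"), simplify = FALSE)
  traj <- score_trajectory(exps)
  incr <- diff(c(0, traj$score))
  expect_true(all(incr > 0))
  expect_true(all(diff(incr) < 0))
})

test_that("convergence across classes outweighs consistency within one class", {
  consistent_outcome <- function(cls) {
    if (cls %in% c("POS_INTERVENTION", "POS_NONINTERVENTION")) "INCREASE" else "DECREASE"
  }
  one_class <- score_trajectory(
    replicate(4, exp_ab("PI", "INCREASE"), simplify = FALSE))
  spread <- score_trajectory(
    lapply(EXPERIMENT_CLASSES, function(cls) exp_ab(cls, consistent_outcome(cls))))
  for (k in 2:4) expect_gt(spread$score[k], one_class$score[k])
  expect_equal(spread$score[2], 0.125, tolerance = 1e-12)
})

test_that("for consistent results the final score ignores class interleaving", {
  consistent_outcome <- function(cls) {
    if (cls %in% c("POS_INTERVENTION", "POS_NONINTERVENTION")) "INCREASE" else "DECREASE"
  }
  classes <- c("PI", "PI", "NI", "PNO", "NNO", "NI")
  exps <- lapply(classes, function(cl) {
    cl_full <- evimap:::match_class(cl)
    exp_ab(cl_full, consistent_outcome(cl_full))
  })
  set.seed(303)
  ref <- score_edge(exps)$score
  for (i in 1:10) {
    expect_equal(score_edge(exps[sample(length(exps))])$score, ref,
                 tolerance = 1e-15)
  }
})

test_that("non-uniform priors keep the zero-evidence score at zero", {
  alpha <- default_priors()
  alpha["POS_INTERVENTION", ] <- c(2, 1, 1)  # favour interventional evidence of E
  zero <- matrix(0L, 4, 3, dimnames = dimnames(alpha))
  es <- score_counts(zero, priors = alpha)
  expect_equal(es$score, 0, tolerance = 1e-12)
  expect_gt(baseline_theta(alpha), 1/3)
})

test_that("experiments on different pairs cannot be pooled on one edge", {
  mixed <- list(exp_ab("PI", "NO_CHANGE"),
                experiment(ph("PKA"), ph("CREB"), "PI", "INCREASE"))
  expect_error(score_edge(mixed), "same directed")
  expect_error(score_trajectory(mixed), "same directed")
})
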