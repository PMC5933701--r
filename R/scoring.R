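# The evidence calculus.
#
# Evidence on one directed edge is summarized by a 4x3 counts table x[c, r]:
# the number of experiments of class c (rows: the four connection-experiment
# classes) evidencing relation r (columns: Excitatory, No-connection,
# Inhibitory). Each class row receives an independent Dirichlet prior
# alpha[c, ] (all ones by default, i.e. Laplace add-one smoothing); the
# posterior mean of the class-specific relation probabilities is
#
#   E[theta[c, r]] = (alpha[c, r] + x[c, r]) / (sum_r alpha[c, r] + n_c),
#
# with n_c the class total. Averaging the posterior means across the four
# classes gives the convergence vector theta_bar; the edge's relation is the
# strict argmax of theta_bar and its score rescales the winning component to
# (0, 1):
#
#   score = (max(theta_bar) - theta_o) / (1 - theta_o),
#
# where theta_o is the no-evidence baseline (1/3 under uniform priors). Ties
# in theta_bar yield an indeterminate edge with no score. Repeats within a
# class contribute diminishing amounts (consistency); spreading consistent
# results across classes raises the score faster (convergence).

#' Default prior weights (Laplace add-one smoothing)
#'
#' A 4x3 table of ones: every experiment class gives every relation one
#' pseudocount, so each class row starts at the uniform distribution and the
#' no-evidence baseline is 1/3. Non-uniform tables can up- or down-weight
#' evidence from particular experiment classes.
#'
#' @return A 4x3 numeric matrix with classes as rows and relations as
#'   columns.
#' @export
default_priors <- function() {
  matrix(1, nrow = 4, ncol = 3,
         dimnames = list(EXPERIMENT_CLASSES, RELATIONS))
}

as_priors <- function(alpha) {
  if (is.null(alpha)) return(default_priors())
  alpha <- as.matrix(alpha)
  if (!all(dim(alpha) == c(4, 3))) {
    stop("priors must be a 4x3 table (classes x relations)", call. = FALSE)
  }
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("all prior weights must be strictly positive", call. = FALSE)
  }
  dimnames(alpha) <- list(EXPERIMENT_CLASSES, RELATIONS)
  alpha
}

#' Tally experiments into an evidence-counts table
#'
#' Builds the 4x3 table `x[c, r]` counting, for each experiment class, how
#' many experiments evidenced each relation (via [outcome_to_relation()]).
#' The table is the sufficient statistic of the calculus: any permutation of
#' the same experiment multiset yields the same counts, hence the same
#' score.
#'
#' @param experiments A list of [experiment()] objects.
#' @return An integer matrix with classes as rows and relations as columns,
#'   with class totals in `attr(, "n_c")`.
#' @export
evidence_counts <- function(experiments) {
  x <- matrix(0L, nrow = 4, ncol = 3,
              dimnames = list(EXPERIMENT_CLASSES, RELATIONS))
  for (e in experiments) {
    if (!inherits(e, "experiment")) stop("all elements must be experiments", call. = FALSE)
    x[e$exp_class, e$relation_evidenced] <- x[e$exp_class, e$relation_evidenced] + 1L
  }
  structure(x, n_c = rowSums(x))
}

#' Per-class posterior mean relation probabilities
#'
#' For each experiment class, the posterior mean probability that the next
#' experiment of that class will evidence each relation, under a
#' Dirichlet-multinomial model: `(alpha + x) / (sum(alpha) + n)` per row.
#' With all-ones priors this is Laplace add-one smoothing,
#' `(1 + x) / (3 + n)`. Rows sum to one.
#'
#' @param counts A 4x3 counts table from [evidence_counts()].
#' @param priors A strictly positive 4x3 prior table; [default_priors()] by
#'   default.
#' @return A 4x3 numeric matrix of posterior means.
#' @examples
#' x <- matrix(0, 4, 3, dimnames = list(EXPERIMENT_CLASSES, RELATIONS))
#' x["POS_INTERVENTION", "NO_CONNECTION"] <- 1
#' posterior_means(x)["POS_INTERVENTION", ]  # 0.25 0.50 0.25
#' @export
posterior_means <- function(counts, priors = default_priors()) {
  priors <- as_priors(priors)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4, 3))) {
    stop("counts must be a 4x3 table (classes x relations)", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  post <- priors + counts
  sweep(post, 1, rowSums(post), "/")
}

#' Cross-class convergence mean
#'
#' The mean of each relation's posterior-mean component across the four
#' experiment classes. This vector expresses convergence: it is high for a
#' relation exactly when the separate experiment classes agree on it.
#'
#' @param theta A 4x3 matrix of per-class posterior means (rows sum to 1).
#' @return A named 3-vector summing to 1.
#' @export
convergence_mean <- function(theta) {
  theta <- as.matrix(theta)
  if (!all(dim(theta) == c(4, 3))) {
    stop("theta must be a 4x3 table (classes x relations)", call. = FALSE)
  }
  if (any(abs(rowSums(theta) - 1) > 1e-8)) {
    stop("each row of theta must sum to 1", call. = FALSE)
  }
  tb <- colMeans(theta)
  names(tb) <- RELATIONS
  tb
}

#' Assign the edge relation from the convergence mean
#'
#' The edge takes the relation with the strictly largest component of the
#' convergence mean. When two or more components tie for the maximum the
#' edge is `INDETERMINATE` and carries no score. Because counts are integers
#' true ties are exact in rational arithmetic; an absolute tolerance of
#' `1e-9` only guards floating-point noise.
#'
#' @param theta_bar A 3-vector from [convergence_mean()].
#' @param tol Absolute tie tolerance.
#' @return One of [RELATIONS], or `INDETERMINATE`.
#' @export
assign_relation <- function(theta_bar, tol = 1e-9) {
  theta_bar <- check_theta_bar(theta_bar)
  m <- max(theta_bar)
  at_max <- which(theta_bar >= m - tol)
  if (length(at_max) > 1) INDETERMINATE else RELATIONS[at_max]
}

check_theta_bar <- function(theta_bar) {
  theta_bar <- as.numeric(theta_bar)
  if (length(theta_bar) != 3 || abs(sum(theta_bar) - 1) > 1e-8) {
    stop("theta_bar must be a 3-vector summing to 1", call. = FALSE)
  }
  names(theta_bar) <- RELATIONS
  theta_bar
}

#' No-evidence baseline of the convergence mean
#'
#' The largest component of the convergence mean implied by the priors at
#' zero evidence, so that the edge score is exactly zero before any
#' experiment is recorded. Under uniform priors this is 1/3.
#'
#' @param priors A 4x3 prior table.
#' @return A scalar in (0, 1).
#' @export
baseline_theta <- function(priors = default_priors()) {
  priors <- as_priors(priors)
  zero <- matrix(0L, 4, 3, dimnames = dimnames(priors))
  max(convergence_mean(posterior_means(zero, priors)))
}

#' Edge score from the convergence mean
#'
#' Rescales the winning component of the convergence mean to `(0, 1)`:
#' `(max(theta_bar) - theta_o) / (1 - theta_o)`. Returns `NA` when the
#' maximum is tied (indeterminate edge). The score quantifies convergent and
#' consistent evidential support for the dominant relation; it is not a
#' causal effect size, and its semantics are relative, not absolute.
#'
#' @param theta_bar A 3-vector from [convergence_mean()].
#' @param theta_o The no-evidence baseline; 1/3 under uniform priors (see
#'   [baseline_theta()] for other priors).
#' @param tol Tie tolerance passed to [assign_relation()].
#' @return A scalar in `[0, 1)`, or `NA_real_` for an indeterminate edge.
#' @export
edge_score <- function(theta_bar, theta_o = 1/3, tol = 1e-9) {
  theta_bar <- check_theta_bar(theta_bar)
  if (assign_relation(theta_bar, tol) == INDETERMINATE) return(NA_real_)
  (max(theta_bar) - theta_o) / (1 - theta_o)
}

#' Score the pooled evidence of a counts table
#'
#' Core of the calculus: from a 4x3 counts table, compute the per-class
#' posterior means, the convergence mean, the assigned relation, and the
#' edge score.
#'
#' @param counts A 4x3 counts table ([evidence_counts()]).
#' @param priors A 4x3 prior table; [default_priors()] by default.
#' @param tol Tie tolerance.
#' @return An object of class `evidence_score`: a list with elements
#'   `counts`, `theta` (4x3 posterior means), `theta_bar` (convergence
#'   mean), `theta_o` (baseline), `relation`, and `score` (`NA` when the
#'   relation is indeterminate).
#' @export
score_counts <- function(counts, priors = default_priors(), tol = 1e-9) {
  priors <- as_priors(priors)
  theta <- posterior_means(counts, priors)
  theta_bar <- convergence_mean(theta)
  theta_o <- baseline_theta(priors)
  relation <- assign_relation(theta_bar, tol)
  score <- if (relation == INDETERMINATE) NA_real_ else
    (max(theta_bar) - theta_o) / (1 - theta_o)
  structure(list(counts = counts, theta = theta, theta_bar = theta_bar,
                 theta_o = theta_o, relation = relation, score = score),
            class = "evidence_score")
}

#' Score one edge from its experiments
#'
#' Tallies the experiments (which must all share the same directed Agent ->
#' Target pair) into a counts table and scores it. Equivalent to the
#' shorthand table method: start every cell of the class-by-relation table
#' at one pseudocount, add one per experiment, row-normalize, average rows,
#' and rescale the maximum.
#'
#' @param experiments A list of [experiment()] objects on one directed pair.
#' @param priors A 4x3 prior table.
#' @param tol Tie tolerance.
#' @return An `evidence_score` object (see [score_counts()]).
#' @examples
#' creb <- phenomenon("CREB"); arc <- phenomenon("Arc neurons")
#' es <- score_edge(list(
#'   experiment(creb, arc, "PI", "NO_CHANGE"),
#'   experiment(creb, arc, "PI", "NO_CHANGE"),
#'   experiment(creb, arc, "NI", "NO_CHANGE")))
#' es$relation  # NO_CONNECTION
#' es$score     # 0.1625
#' @export
score_edge <- function(experiments, priors = default_priors(), tol = 1e-9) {
  check_same_pair(experiments)
  score_counts(evidence_counts(experiments), priors, tol)
}

check_same_pair <- function(experiments) {
  if (length(experiments) == 0) return(invisible(TRUE))
  keys <- vapply(experiments, function(e) {
    if (!inherits(e, "experiment")) stop("all elements must be experiments", call. = FALSE)
    paste(node_key(e$agent), node_key(e$target), sep = KEY_SEP)
  }, "")
  if (length(unique(keys)) > 1) {
    stop("all experiments must share the same directed (agent, target) pair", call. = FALSE)
  }
  invisible(TRUE)
}

#' Score trajectory over an ordered experiment sequence
#'
#' Scores every prefix of the sequence, tracing how the edge score grows
#' with each subsequent experiment: repeats within a class add strictly
#' positive but strictly decreasing amounts (consistency), while consistent
#' results spread across classes grow the score faster (convergence), and
#' conflicting results lower it.
#'
#' @param experiments An ordered list of [experiment()] objects on one
#'   directed pair.
#' @param priors A 4x3 prior table.
#' @param tol Tie tolerance.
#' @return A data frame with one row per prefix: `k`, `exp_class`,
#'   `outcome`, `relation`, `score`.
#' @export
score_trajectory <- function(experiments, priors = default_priors(), tol = 1e-9) {
  check_same_pair(experiments)
  n <- length(experiments)
  out <- data.frame(k = seq_len(n),
                    exp_class = vapply(experiments, function(e) e$exp_class, ""),
                    outcome = vapply(experiments, function(e) e$outcome, ""),
                    relation = character(n), score = numeric(n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    es <- score_counts(evidence_counts(experiments[seq_len(k)]), priors, tol)
    out$relation[k] <- es$relation
    out$score[k] <- es$score
  }
  rownames(out) <- NULL
  out
}

#' Round a score for display
#'
#' Scores are computed and stored in double precision; displays round half
#' away from zero to 4 decimal places (so 0.13125 displays as 0.1313).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
display_score <- function(x, digits = 4) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' @export
format.evidence_score <- function(x, ...) {
  if (x$relation == INDETERMINATE) {
    "indeterminate (tied evidence); no score assigned"
  } else {
    sprintf("%s, score %.4f (%.12g)", x$relation, display_score(x$score), x$score)
  }
}

#' @export
print.evidence_score <- function(x, ...) {
  cat("<evidence_score> ", format(x), "\n", sep = "")
  cat("counts (classes x relations):\n")
  tab <- matrix(as.integer(x$counts), 4, 3,
                dimnames = list(unname(CLASS_SYMBOLS[rownames(x$counts)]),
                                unname(RELATION_ABBREV[colnames(x$counts)])))
  print(tab)
  cat("theta_bar: ", paste(sprintf("%s=%.4f", RELATION_ABBREV[names(x$theta_bar)],
                                   x$theta_bar), collapse = " "), "\n", sep = "")
  invisible(x)
}
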