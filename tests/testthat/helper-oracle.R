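# Independent brute-force oracles. These deliberately avoid the package's
# own computational paths: the scorer literally instantiates the shorthand
# pseudocount table from an explicit class/outcome lookup, and the graph
# oracles enumerate paths and injective node assignments exhaustively.

# Explicit class/outcome -> relation-column lookup (columns: E, N, I).
ORACLE_CELL <- local({
  tab <- expand.grid(cls = c("POS_INTERVENTION", "POS_NONINTERVENTION",
                             "NEG_NONINTERVENTION", "NEG_INTERVENTION"),
                     out = c("INCREASE", "NO_CHANGE", "DECREASE"),
                     stringsAsFactors = FALSE)
  tab$col <- c(
    # INCREASE:  PI -> E, PNO -> E, NNO -> I, NI -> I
    1, 1, 3, 3,
    # NO_CHANGE: all -> N
    2, 2, 2, 2,
    # DECREASE:  PI -> I, PNO -> I, NNO -> E, NI -> E
    3, 3, 1, 1)
  tab
})

# Literal table evaluation: start every cell at one pseudocount, add one
# per experiment, row-normalize, average rows, rescale the max.
oracle_score <- function(experiments) {
  classes <- c("POS_INTERVENTION", "POS_NONINTERVENTION",
               "NEG_NONINTERVENTION", "NEG_INTERVENTION")
  tab <- matrix(1, nrow = 4, ncol = 3)
  for (e in experiments) {
    r <- match(e$exp_class, classes)
    k <- ORACLE_CELL$col[ORACLE_CELL$cls == e$exp_class & ORACLE_CELL$out == e$outcome]
    tab[r, k] <- tab[r, k] + 1
  }
  rows <- tab / rowSums(tab)
  tbar <- (rows[1, ] + rows[2, ] + rows[3, ] + rows[4, ]) / 4
  m <- max(tbar)
  winners <- which(abs(tbar - m) < 1e-9)
  if (length(winners) > 1) {
    list(relation = "INDETERMINATE", score = NA_real_)
  } else {
    list(relation = c("EXCITATORY", "NO_CONNECTION", "INHIBITORY")[winners],
         score = (m - 1 / 3) / (1 - 1 / 3))
  }
}

# Exhaustive simple-path enumeration over a signed edge data frame
# (columns from, to); returns a list of node vectors from `from` to `to`
# of length (in edges) at most maxlen.
oracle_simple_paths <- function(edges, from, to, maxlen) {
  out <- list()
  walk <- function(path) {
    head <- path[length(path)]
    if (head == to && length(path) > 1) {
      out[[length(out) + 1L]] <<- path
      return(invisible(NULL))
    }
    if (length(path) - 1 >= maxlen) return(invisible(NULL))
    nxt <- edges$to[edges$from == head]
    for (v in nxt) {
      if (v %in% path) next
      walk(c(path, v))
    }
    invisible(NULL)
  }
  walk(from)
  out
}

# Exhaustive conflict enumeration: for each unordered N pair, all simple
# signed paths in either orientation.
oracle_conflicts <- function(signed_edges, n_pairs, maxlen) {
  out <- list()
  seen <- character()
  for (i in seq_len(nrow(n_pairs))) {
    a <- n_pairs$from[i]; b <- n_pairs$to[i]
    id <- paste(sort(c(a, b)), collapse = "~")
    if (id %in% seen) next
    seen <- c(seen, id)
    for (ends in list(c(a, b), c(b, a))) {
      for (p in oracle_simple_paths(signed_edges, ends[1], ends[2], maxlen)) {
        out[[length(out) + 1L]] <- list(independence = c(a, b), path = p)
      }
    }
  }
  out
}

# Exhaustive injective-assignment template matching: try every assignment
# of template nodes to distinct graph nodes and keep those where all
# template edges are present with matching labels (N in either direction).
oracle_match <- function(facts, template) {
  tnodes <- unique(c(template$from, template$to))
  gnodes <- unique(c(facts$from, facts$to))
  if (length(gnodes) < length(tnodes)) return(list())
  has_edge <- function(u, v, rel) {
    if (rel == "NO_CONNECTION") {
      any(facts$from == u & facts$to == v & facts$relation == rel) ||
        any(facts$from == v & facts$to == u & facts$relation == rel)
    } else {
      any(facts$from == u & facts$to == v & facts$relation == rel)
    }
  }
  combos <- utils::combn(gnodes, length(tnodes), simplify = FALSE)
  out <- list()
  for (chosen in combos) {
    perms <- all_permutations(chosen)
    for (asg in perms) {
      names(asg) <- tnodes
      ok <- all(vapply(seq_len(nrow(template)), function(i) {
        has_edge(asg[[template$from[i]]], asg[[template$to[i]]], template$relation[i])
      }, TRUE))
      if (ok) out[[length(out) + 1L]] <- asg
    }
  }
  out
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}
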