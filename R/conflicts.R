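# Structural conflict detection. A No-connection (independence) finding
# between two phenomena cannot hold together with a determinate-sign
# directed pathway between the same endpoints: both an excitatory and an
# inhibitory chain imply dependence. Independence is treated symmetrically
# (an N edge constrains both orientations), and these inferences are purely
# structural, so they can be recycled: any other instantiation of the same
# node/edge template supports the same inference regardless of node
# identity.

#' Sign of a signed causal path
#'
#' The composite sign of a chain of Excitatory/Inhibitory relations:
#' Excitatory edges carry +1, Inhibitory edges -1, and the path sign is
#' their product (two inhibitions compose to an excitatory pathway).
#'
#' @param relations Character vector of `"EXCITATORY"` / `"INHIBITORY"`.
#' @return `+1` or `-1`.
#' @export
path_sign <- function(relations) {
  if (length(relations) == 0) stop("a signed path has at least one edge", call. = FALSE)
  relations <- vapply(relations, match_relation, "")
  if (any(relations == "NO_CONNECTION")) {
    stop("signed paths contain only Excitatory or Inhibitory relations", call. = FALSE)
  }
  prod(ifelse(relations == "EXCITATORY", 1, -1))
}

# Determinate-sign (E/I) edge table and symmetric independence pairs,
# honoring the score threshold and the hypothetical-edge flag.
signed_edge_table <- function(g, min_score, include_hypothetical) {
  df <- global_edges(g)
  emp <- df[df$empirical & !is.na(df$score) &
              df$relation %in% c("EXCITATORY", "INHIBITORY") &
              df$score >= min_score, c("agent_key", "target_key", "relation", "score")]
  if (include_hypothetical) {
    for (ed in g$edges) {
      for (r in ed$hypotheses) {
        rel <- r$hypothesis$relation
        if (rel %in% c("EXCITATORY", "INHIBITORY")) {
          emp <- rbind(emp, data.frame(agent_key = ed$agent_key,
                                       target_key = ed$target_key,
                                       relation = rel, score = NA_real_,
                                       stringsAsFactors = FALSE))
        }
      }
    }
    # one signed fact per directed pair; empirical rows come first and win
    emp <- emp[!duplicated(paste(emp$agent_key, emp$target_key, sep = KEY_SEP)), ,
               drop = FALSE]
  }
  emp
}

independence_pairs <- function(g, include_hypothetical) {
  df <- global_edges(g)
  pairs <- df[df$empirical & df$relation %in% "NO_CONNECTION",
              c("agent_key", "target_key", "score")]
  if (include_hypothetical) {
    for (ed in g$edges) {
      for (r in ed$hypotheses) {
        if (r$hypothesis$relation == "NO_CONNECTION") {
          pairs <- rbind(pairs, data.frame(agent_key = ed$agent_key,
                                           target_key = ed$target_key,
                                           score = NA_real_,
                                           stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (nrow(pairs) == 0) return(pairs)
  # independence is orientation-free: dedupe unordered endpoint pairs
  lo <- pmin(pairs$agent_key, pairs$target_key)
  hi <- pmax(pairs$agent_key, pairs$target_key)
  keep <- !duplicated(paste(lo, hi, sep = KEY_SEP))
  pairs[keep, , drop = FALSE]
}

signed_igraph <- function(edf, nodes) {
  igraph::graph_from_data_frame(
    edf[, c("agent_key", "target_key")], directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
}

#' Detect pathway-versus-independence conflicts
#'
#' For every independence (No-connection) edge between nodes A and B, finds
#' every simple directed signed pathway A to B or B to A of length at most
#' `max_path_len` over qualifying Excitatory/Inhibitory edges. Each such
#' pathway and the independence finding cannot all be true simultaneously,
#' so each is reported as one conflict.
#'
#' @param g A `global_map` or [research_map()].
#' @param max_path_len Maximum pathway length in edges (default 4).
#' @param min_score Minimum score a signed edge must have to enter a
#'   pathway (default 0: any scored edge).
#' @param include_hypothetical Also let hypothetical Excitatory/Inhibitory
#'   edges form pathways and hypothetical No-connection assertions act as
#'   independence constraints (default `FALSE`).
#' @return A list of `conflict` objects: each has `independence`
#'   (endpoint keys), `independence_score`, `path_nodes`, `path_relations`,
#'   `sign`, `min_edge_score`, and a text `explanation`.
#' @export
detect_conflicts <- function(g, max_path_len = 4, min_score = 0,
                             include_hypothetical = FALSE) {
  g <- as_global_map(g)
  max_path_len <- as.integer(max_path_len)
  if (is.na(max_path_len) || max_path_len < 1) {
    stop("max_path_len must be >= 1", call. = FALSE)
  }
  edf <- signed_edge_table(g, min_score, include_hypothetical)
  npairs <- independence_pairs(g, include_hypothetical)
  out <- list()
  if (nrow(edf) == 0 || nrow(npairs) == 0) return(out)
  ig <- signed_igraph(edf, g$nodes$key)
  rel_of <- stats::setNames(edf$relation, paste(edf$agent_key, edf$target_key, sep = KEY_SEP))
  score_of <- stats::setNames(edf$score, paste(edf$agent_key, edf$target_key, sep = KEY_SEP))
  for (i in seq_len(nrow(npairs))) {
    a <- npairs$agent_key[i]; b <- npairs$target_key[i]
    for (ends in list(c(a, b), c(b, a))) {
      paths <- igraph::all_simple_paths(ig, from = ends[1], to = ends[2],
                                        mode = "out", cutoff = max_path_len)
      for (p in paths) {
        nodes <- names(p)
        steps <- paste(nodes[-length(nodes)], nodes[-1], sep = KEY_SEP)
        rels <- unname(rel_of[steps])
        out[[length(out) + 1L]] <- structure(list(
          independence = c(a, b),
          independence_score = npairs$score[i],
          path_nodes = nodes,
          path_relations = rels,
          sign = path_sign(rels),
          min_edge_score = suppressWarnings(min(score_of[steps], na.rm = TRUE)),
          explanation = sprintf(
            "%s pathway %s conflicts with the independence finding between %s and %s",
            if (path_sign(rels) > 0) "excitatory" else "inhibitory",
            paste(nodes, collapse = " -> "), a, b)
        ), class = "conflict")
      }
    }
  }
  out
}

#' @export
format.conflict <- function(x, ...) x$explanation

#' @export
print.conflict <- function(x, ...) {
  cat("<conflict> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Forbidden-causation pairs
#'
#' Derives ordered pairs `(X, Y)` such that X cannot be a cause of Y, direct
#' or indirect: there is some node B with a determinate-sign directed
#' pathway from Y to B (length at most `max_path_len`) and an independence
#' finding between X and B, so any hypothetical cause X to Y would complete
#' a pathway conflicting with that independence.
#'
#' @inheritParams detect_conflicts
#' @return A data frame with columns `cause` and `effect` (node keys),
#'   sorted; zero rows when nothing is forbidden.
#' @export
forbidden_causation <- function(g, max_path_len = 4, min_score = 0,
                                include_hypothetical = FALSE) {
  g <- as_global_map(g)
  edf <- signed_edge_table(g, min_score, include_hypothetical)
  npairs <- independence_pairs(g, include_hypothetical)
  empty <- data.frame(cause = character(), effect = character(),
                      stringsAsFactors = FALSE)
  if (nrow(edf) == 0 || nrow(npairs) == 0) return(empty)
  ig <- signed_igraph(edf, g$nodes$key)
  # nodes Y with a directed signed path Y ~> B within max_path_len
  d <- igraph::distances(ig, mode = "out")
  out <- empty
  for (i in seq_len(nrow(npairs))) {
    for (ends in list(c(npairs$agent_key[i], npairs$target_key[i]),
                      c(npairs$target_key[i], npairs$agent_key[i]))) {
      x <- ends[1]; b <- ends[2]
      ys <- rownames(d)[d[, b] >= 1 & d[, b] <= max_path_len]
      ys <- setdiff(ys, x)
      if (length(ys)) {
        out <- rbind(out, data.frame(cause = x, effect = ys,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- unique(out)
  out[order(out$cause, out$effect), , drop = FALSE]
}

#' Match a structural template against a map
#'
#' Finds every binding of a small relation-labeled edge pattern to the
#' map's determinate edges (subgraph monomorphism: every template edge must
#' map to a map edge with the same relation label; template nodes map
#' injectively to map nodes; extra map edges among the matched nodes are
#' allowed). No-connection edges match in either orientation, mirroring the
#' symmetric treatment of independence. Because the match is purely
#' structural, an inference made once on a template holds for every binding
#' regardless of node identity.
#'
#' @param g A `global_map` or [research_map()].
#' @param template A data frame with columns `from`, `to`, `relation`
#'   (template node labels and `"EXCITATORY"`/`"INHIBITORY"`/
#'   `"NO_CONNECTION"`), at most 6 distinct nodes.
#' @param min_score Minimum score for map edges entering the match
#'   (hypothesis-only and indeterminate edges never match).
#' @return A list of named character vectors, each mapping template node
#'   labels to map node keys; empty when the template is absent.
#' @export
match_template <- function(g, template, min_score = 0) {
  g <- as_global_map(g)
  template <- as.data.frame(template, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "relation") %in% names(template)) || nrow(template) == 0) {
    stop("template must have rows with columns from, to, relation", call. = FALSE)
  }
  template$relation <- vapply(template$relation, match_relation, "")
  tnodes <- unique(c(template$from, template$to))
  if (length(tnodes) > 6) stop("template may have at most 6 nodes", call. = FALSE)

  df <- global_edges(g)
  df <- df[df$empirical & !is.na(df$score) & df$score >= min_score &
             df$relation %in% RELATIONS, , drop = FALSE]
  # directed E/I facts; N facts in both orientations (symmetric)
  facts <- df[df$relation != "NO_CONNECTION", c("agent_key", "target_key", "relation")]
  ndf <- df[df$relation == "NO_CONNECTION", , drop = FALSE]
  if (nrow(ndf)) {
    facts <- rbind(facts,
                   data.frame(agent_key = ndf$agent_key, target_key = ndf$target_key,
                              relation = "NO_CONNECTION", stringsAsFactors = FALSE),
                   data.frame(agent_key = ndf$target_key, target_key = ndf$agent_key,
                              relation = "NO_CONNECTION", stringsAsFactors = FALSE))
  }
  facts <- unique(facts)

  results <- list()
  extend <- function(binding, edge_idx) {
    if (edge_idx > nrow(template)) {
      results[[length(results) + 1L]] <<- unlist(binding)[tnodes]
      return(invisible(NULL))
    }
    tu <- template$from[edge_idx]; tv <- template$to[edge_idx]
    rel <- template$relation[edge_idx]
    cand <- facts[facts$relation == rel, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      gu <- cand$agent_key[j]; gv <- cand$target_key[j]
      bu <- binding[[tu]]; bv <- binding[[tv]]
      if (!is.null(bu) && bu != gu) next
      if (!is.null(bv) && bv != gv) next
      if (gu == gv) next
      nb <- binding
      if (is.null(bu)) {
        if (gu %in% unlist(nb)) next  # injectivity
        nb[[tu]] <- gu
      }
      if (is.null(nb[[tv]])) {
        if (gv %in% unlist(nb)) next
        nb[[tv]] <- gv
      }
      extend(nb, edge_idx + 1L)
    }
    invisible(NULL)
  }
  extend(stats::setNames(vector("list", length(tnodes)), tnodes), 1L)
  unique(results)
}
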