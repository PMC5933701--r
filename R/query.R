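# Term and pair search, hop-limited neighborhoods, score filtering, and
# connectivity profiling over a global map. Traversal is breadth-first via
# igraph; edges are filtered before the hop bound is applied.

#' Build a query specification
#'
#' @param term Free-text search term, matched case-insensitively as a
#'   substring of any node's What/Where/When fields.
#' @param pair Optional character vector `c(agent_term, target_term)`.
#' @param max_hops Positive integer: maximum number of edge traversals from
#'   the seed nodes.
#' @param score_min,score_max Inclusive score bounds in `[0, 1]` applied to
#'   scored empirical edges.
#' @param include_hypothetical Keep hypothesis-only edges? Such edges carry
#'   no score and are not subject to the score bounds.
#' @param include_unscored Keep empirical edges with tied (indeterminate)
#'   evidence, which carry no score?
#' @param direction Traversal direction for [neighborhood()]: `"both"`
#'   (default, ignore edge direction), `"out"`, or `"in"`.
#' @return An object of class `query_spec`.
#' @export
query_spec <- function(term = NULL, pair = NULL, max_hops = 1L,
                       score_min = 0, score_max = 1,
                       include_hypothetical = TRUE,
                       include_unscored = FALSE,
                       direction = c("both", "out", "in")) {
  direction <- match.arg(direction)
  max_hops <- as.integer(max_hops)
  if (is.na(max_hops) || max_hops < 1) stop("max_hops must be >= 1", call. = FALSE)
  if (score_min > score_max) stop("score_min must be <= score_max", call. = FALSE)
  if (score_min < 0 || score_max > 1) stop("score bounds must lie in [0, 1]", call. = FALSE)
  structure(list(term = term, pair = pair, max_hops = max_hops,
                 score_min = score_min, score_max = score_max,
                 include_hypothetical = isTRUE(include_hypothetical),
                 include_unscored = isTRUE(include_unscored),
                 direction = direction),
            class = "query_spec")
}

#' Find nodes matching a term
#'
#' Case-insensitive substring match of the normalized term against the
#' normalized What, Where, and When fields of every node.
#'
#' @param g A `global_map` (or research map).
#' @param term Non-empty search term.
#' @return A character vector of matching node keys (sorted).
#' @export
find_nodes <- function(g, term) {
  g <- as_global_map(g)
  term <- normalize_field(term)
  if (!nzchar(term)) stop("search term must be non-empty", call. = FALSE)
  nd <- g$nodes
  hit <- grepl(term, normalize_field(nd$what), fixed = TRUE) |
    grepl(term, normalize_field(nd$where), fixed = TRUE) |
    grepl(term, normalize_field(nd$when), fixed = TRUE)
  sort(nd$key[hit])
}

# Edges passing a spec's score and inclusion filters.
qualifying_edges <- function(g, spec) {
  df <- global_edges(g)
  if (nrow(df) == 0) return(df)
  scored <- df$empirical & !is.na(df$score)
  keep_scored <- scored & df$score >= spec$score_min & df$score <= spec$score_max
  keep_unscored_emp <- df$empirical & is.na(df$score) & spec$include_unscored
  keep_hyp_only <- !df$empirical & df$hypothetical & spec$include_hypothetical
  df[keep_scored | keep_unscored_emp | keep_hyp_only, , drop = FALSE]
}

subgraph_of <- function(g, keys, edge_df) {
  keys <- sort(unique(keys))
  pair_ids <- paste(edge_df$agent_key, edge_df$target_key, sep = KEY_SEP)
  keep <- edge_df$agent_key %in% keys & edge_df$target_key %in% keys
  structure(list(mode = g$mode,
                 nodes = g$nodes[g$nodes$key %in% keys, , drop = FALSE],
                 edges = g$edges[names(g$edges) %in% pair_ids[keep]],
                 sources = g$sources,
                 priors = g$priors),
            class = "global_map")
}

#' Hop-limited neighborhood query
#'
#' Seeds are the nodes matching `spec$term` (or the union of matches to
#' `spec$pair` terms). Edges failing the score/inclusion filters are removed
#' first; traversal then expands breadth-first from the seeds up to
#' `spec$max_hops` hops, respecting `spec$direction`. The result contains
#' exactly the traversed nodes and the qualifying edges between them. A term
#' with no match yields an empty subgraph, not an error.
#'
#' @param g A `global_map` (or research map).
#' @param spec A [query_spec()].
#' @return A `global_map` subgraph.
#' @export
neighborhood <- function(g, spec) {
  g <- as_global_map(g)
  stopifnot(inherits(spec, "query_spec"))
  terms <- if (!is.null(spec$pair)) spec$pair else spec$term
  if (is.null(terms)) stop("spec must carry a term or a pair", call. = FALSE)
  seeds <- sort(unique(unlist(lapply(terms, function(tm) find_nodes(g, tm)))))
  if (length(seeds) == 0) {
    return(subgraph_of(g, character(), global_edges(g)[0, , drop = FALSE]))
  }
  edf <- qualifying_edges(g, spec)
  if (nrow(edf) == 0) return(subgraph_of(g, seeds, edf))
  ig <- igraph::graph_from_data_frame(
    edf[, c("agent_key", "target_key")], directed = TRUE,
    vertices = data.frame(name = g$nodes$key, stringsAsFactors = FALSE))
  mode <- switch(spec$direction, both = "all", out = "out", `in` = "in")
  d <- igraph::distances(ig, v = seeds, mode = mode)
  reach <- colnames(d)[apply(d, 2, min) <= spec$max_hops]
  subgraph_of(g, union(seeds, reach), edf)
}

#' Search for edges between an Agent term and a Target term
#'
#' Returns every directed edge whose Agent matches `agent_term` and whose
#' Target matches `target_term` (substring, case-insensitive). Direction
#' matters; empirical and hypothetical edges are both returned, flagged in
#' the edge table.
#'
#' @param g A `global_map` (or research map).
#' @param agent_term,target_term Non-empty search terms.
#' @return A data frame in the format of [global_edges()] (zero rows when
#'   nothing matches).
#' @export
pair_search <- function(g, agent_term, target_term) {
  g <- as_global_map(g)
  ak <- find_nodes(g, agent_term)
  tk <- find_nodes(g, target_term)
  df <- global_edges(g)
  df[df$agent_key %in% ak & df$target_key %in% tk, , drop = FALSE]
}

#' Connectivity profile around seed nodes
#'
#' For each hop count `k = 1..max_k`, the number of non-seed nodes first
#' reachable within `k` edge traversals, ignoring edge direction (both
#' empirical and hypothetical edges connect). Counts are cumulative and
#' monotone non-decreasing in `k`, bounded by the number of non-seed nodes.
#'
#' @param g A `global_map` (or research map).
#' @param seeds Character vector of node keys (must exist in `g`).
#' @param max_k Positive integer: largest hop count profiled.
#' @return A data frame with columns `k` and `nodes`.
#' @export
connectivity_profile <- function(g, seeds, max_k) {
  g <- as_global_map(g)
  max_k <- as.integer(max_k)
  if (is.na(max_k) || max_k < 1) stop("max_k must be >= 1", call. = FALSE)
  seeds <- unique(as.character(seeds))
  if (!all(seeds %in% g$nodes$key)) {
    stop("all seeds must be node keys of the map", call. = FALSE)
  }
  out <- data.frame(k = seq_len(max_k), nodes = 0L)
  if (length(seeds) == 0 || nrow(g$nodes) == 0) return(out)
  edf <- global_edges(g)
  ig <- igraph::graph_from_data_frame(
    edf[, c("agent_key", "target_key")], directed = TRUE,
    vertices = data.frame(name = g$nodes$key, stringsAsFactors = FALSE))
  d <- igraph::distances(ig, v = seeds, mode = "all")
  mind <- apply(d, 2, min)
  mind <- mind[!(names(mind) %in% seeds)]
  out$nodes <- vapply(seq_len(max_k), function(k) sum(mind <= k), 0L)
  out
}
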