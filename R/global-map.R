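# The global map: many research maps merged into one provenance-preserving
# graph. Experiments from all sources pool per directed node-key pair, and
# every pooled edge is re-scored from its pooled counts table (never by
# averaging per-map scores). Hypothetical assertions attach to edges without
# affecting counts. Merging is deterministic: the same multiset of maps
# yields an identical global map regardless of input order.

#' Merge research maps into a global map
#'
#' Pools the experiments of several research maps onto a single directed
#' graph. Node identity follows `mode`: `"full"` keys nodes by the
#' normalized (What, Where, When) triple; `"what_only"` collapses all nodes
#' sharing a normalized What into one, pooling their evidence (useful to
#' shrink large merged maps). Per edge, the evidence score is recomputed
#' from the pooled counts, and complete provenance (which map and which
#' experiment or hypothesis contributed) is retained. Selecting which maps
#' enter the merge is also how visibility/user filtering is expressed.
#'
#' @param maps A list of [research_map()] objects with distinct `map_id`s
#'   (a single map may be given bare).
#' @param mode `"full"` or `"what_only"` node keying.
#' @param priors Prior table used to re-score pooled edges.
#' @return An object of class `global_map` with fields `mode`, `nodes`
#'   (data frame), `edges` (named list of edge records, each with
#'   `counts`, `evidence`, `experiments`, `hypotheses`,
#'   `empirical_provenance`, `hypothetical_provenance`), and `sources`.
#' @export
merge_maps <- function(maps, mode = c("full", "what_only"),
                       priors = default_priors()) {
  mode <- match.arg(mode)
  if (is_research_map(maps)) maps <- list(maps)
  if (!length(maps) || !all(vapply(maps, is_research_map, TRUE))) {
    stop("`maps` must be a non-empty list of research maps", call. = FALSE)
  }
  ids <- vapply(maps, function(m) m$map_id, "")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate map_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  maps <- maps[order(ids)]  # order-independent merge

  phens <- list()
  edges <- list()
  edge_of <- function(ak, tk) {
    id <- paste(ak, tk, sep = KEY_SEP)
    if (is.null(edges[[id]])) {
      edges[[id]] <<- list(agent_key = ak, target_key = tk,
                           experiments = list(), hypotheses = list())
    }
    id
  }
  for (m in maps) {
    for (e in m$experiments) {
      phens <- c(phens, list(e$agent, e$target))
      ak <- node_key(e$agent, mode); tk <- node_key(e$target, mode)
      if (identical(ak, tk)) next  # distinct nodes collapsed onto one key
      id <- edge_of(ak, tk)
      edges[[id]]$experiments[[length(edges[[id]]$experiments) + 1L]] <-
        list(map_id = m$map_id, experiment = e)
    }
    for (h in m$hypotheses) {
      phens <- c(phens, list(h$agent, h$target))
      ak <- node_key(h$agent, mode); tk <- node_key(h$target, mode)
      if (identical(ak, tk)) next
      id <- edge_of(ak, tk)
      edges[[id]]$hypotheses[[length(edges[[id]]$hypotheses) + 1L]] <-
        list(map_id = m$map_id, hypothesis = h)
    }
  }

  if (length(edges)) edges <- edges[order(names(edges))]
  edges <- lapply(edges, function(ed) {
    # deterministic within-edge ordering
    if (length(ed$experiments)) {
      ord <- order(vapply(ed$experiments, function(r) r$map_id, ""),
                   vapply(ed$experiments, function(r) r$experiment$experiment_id %||% "", ""))
      ed$experiments <- ed$experiments[ord]
    }
    if (length(ed$hypotheses)) {
      ord <- order(vapply(ed$hypotheses, function(r) r$map_id, ""),
                   vapply(ed$hypotheses, function(r) r$hypothesis$relation, ""))
      ed$hypotheses <- ed$hypotheses[ord]
    }
    exps <- lapply(ed$experiments, function(r) r$experiment)
    ed$counts <- evidence_counts(exps)
    ed$evidence <- score_counts(ed$counts, priors)
    ed$empirical_provenance <- data.frame(
      map_id = vapply(ed$experiments, function(r) r$map_id, ""),
      experiment_id = vapply(ed$experiments, function(r) r$experiment$experiment_id %||% NA_character_, ""),
      stringsAsFactors = FALSE)
    ed$hypothetical_provenance <- data.frame(
      map_id = vapply(ed$hypotheses, function(r) r$map_id, ""),
      relation = vapply(ed$hypotheses, function(r) r$hypothesis$relation, ""),
      stringsAsFactors = FALSE)
    ed
  })

  structure(list(mode = mode,
                 nodes = nodes_from_phenomena(phens, mode),
                 edges = edges,
                 sources = sort(unique(ids)),
                 priors = as_priors(priors)),
            class = "global_map")
}

is_global_map <- function(x) inherits(x, "global_map")

#' Coerce to a global map
#'
#' A research map is viewed as the global map of itself; queries and
#' conflict detection accept either.
#'
#' @param x A [research_map()] or `global_map`.
#' @param mode Node-keying mode used when coercing a research map.
#' @return A `global_map`.
#' @export
as_global_map <- function(x, mode = "full") {
  if (is_global_map(x)) return(x)
  if (is_research_map(x)) return(merge_maps(list(x), mode))
  stop("cannot coerce object to a global map", call. = FALSE)
}

#' Edge table of a global map
#'
#' Flattens the merged edges into a data frame, one row per directed pair.
#'
#' @param g A `global_map` (or a research map, coerced).
#' @return A data frame with columns `agent_key`, `target_key`, `relation`
#'   (including `INDETERMINATE`, or `NA` for hypothesis-only edges),
#'   `score`, `n_experiments`, `n_hypotheses`, `empirical`, `hypothetical`.
#' @export
global_edges <- function(g) {
  g <- as_global_map(g)
  n <- length(g$edges)
  df <- data.frame(
    agent_key = character(n), target_key = character(n),
    relation = character(n), score = numeric(n),
    n_experiments = integer(n), n_hypotheses = integer(n),
    empirical = logical(n), hypothetical = logical(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ed <- g$edges[[i]]
    ne <- length(ed$experiments)
    df$agent_key[i] <- ed$agent_key
    df$target_key[i] <- ed$target_key
    df$relation[i] <- if (ne > 0) ed$evidence$relation else NA_character_
    df$score[i] <- if (ne > 0) ed$evidence$score else NA_real_
    df$n_experiments[i] <- ne
    df$n_hypotheses[i] <- length(ed$hypotheses)
    df$empirical[i] <- ne > 0
    df$hypothetical[i] <- length(ed$hypotheses) > 0
  }
  df
}

#' Provenance of a global-map edge
#'
#' Lists every experiment and hypothetical assertion contributing to a
#' directed edge, one row per record, with its source map. This is the table
#' a user consults to trace a merged edge back to the individual research
#' maps it came from.
#'
#' @param g A `global_map`.
#' @param agent,target Node keys (strings) or [phenomenon()] objects.
#' @return A data frame with columns `map_id`, `record_id`, `type`
#'   (`"experiment"` or `"hypothesis"`), `exp_class`, `outcome`, `relation`,
#'   `agent_method`, `target_method`, `stat_test`, `p_value`.
#' @export
edge_provenance <- function(g, agent, target) {
  g <- as_global_map(g)
  ak <- if (is_phenomenon(agent)) node_key(agent, g$mode) else as.character(agent)
  tk <- if (is_phenomenon(target)) node_key(target, g$mode) else as.character(target)
  ed <- g$edges[[paste(ak, tk, sep = KEY_SEP)]]
  if (is.null(ed)) {
    stop(sprintf("no edge %s -> %s in the global map", ak, tk), call. = FALSE)
  }
  rows <- list()
  for (r in ed$experiments) {
    e <- r$experiment
    rows[[length(rows) + 1L]] <- data.frame(
      map_id = r$map_id, record_id = e$experiment_id %||% NA_character_,
      type = "experiment", exp_class = e$exp_class, outcome = e$outcome,
      relation = e$relation_evidenced,
      agent_method = e$agent_method %||% NA_character_,
      target_method = e$target_method %||% NA_character_,
      stat_test = e$stat_test %||% NA_character_,
      p_value = e$p_value %||% NA_real_,
      stringsAsFactors = FALSE)
  }
  for (r in ed$hypotheses) {
    rows[[length(rows) + 1L]] <- data.frame(
      map_id = r$map_id, record_id = NA_character_,
      type = "hypothesis", exp_class = NA_character_, outcome = NA_character_,
      relation = r$hypothesis$relation,
      agent_method = NA_character_, target_method = NA_character_,
      stat_test = NA_character_, p_value = NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.global_map <- function(x, ...) {
  cat(sprintf("<global_map> mode=%s: %d nodes, %d edges, %d source map(s)\n",
              x$mode, nrow(x$nodes), length(x$edges), length(x$sources)))
  invisible(x)
}
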