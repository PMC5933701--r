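# A research map: the per-source collection of experiments and hypothetical
# assertions curated from one article (or private project). Nodes and edges
# are derived views: all experiments on the same directed Agent -> Target
# pair aggregate on one empirical edge (A -> B and B -> A are distinct).

#' Create an empty research map
#'
#' A research map holds all experiments and hypothetical assertions curated
#' from a single source, plus a set of highlighted edges marking the
#' source's main findings. Highlighting is a presentation attribute only; it
#' never affects scores or queries.
#'
#' @param map_id Map identifier, e.g. a PubMed ID or a private label.
#' @param visibility `"public"` or `"private"`.
#' @param metadata Optional named list of free-form metadata (the fixture
#'   generator records its parameters here).
#' @return An object of class `research_map`.
#' @seealso [add_experiment()], [add_hypothesis()], [highlight_edge()],
#'   [validate_map()], [merge_maps()]
#' @export
research_map <- function(map_id, visibility = c("public", "private"),
                         metadata = list()) {
  visibility <- match.arg(visibility)
  map_id <- as_field(map_id)
  if (!nzchar(map_id)) stop("map_id must be non-empty", call. = FALSE)
  structure(list(
    map_id = map_id,
    visibility = visibility,
    experiments = list(),
    hypotheses = list(),
    highlighted = data.frame(agent_key = character(), target_key = character(),
                             stringsAsFactors = FALSE),
    metadata = metadata
  ), class = "research_map")
}

is_research_map <- function(x) inherits(x, "research_map")

#' Add an experiment to a research map
#'
#' Nodes are created implicitly from the experiment's Agent and Target. All
#' experiments sharing a directed (Agent, Target) pair aggregate on a single
#' empirical edge; no parallel edges are created. When the experiment has no
#' `experiment_id`, a fresh `e<k>` identifier unique within the map is
#' assigned; a duplicate identifier is an error.
#'
#' @param map A [research_map()].
#' @param e An [experiment()].
#' @return The updated map.
#' @export
add_experiment <- function(map, e) {
  stopifnot(is_research_map(map))
  if (!inherits(e, "experiment")) stop("`e` must be an experiment", call. = FALSE)
  if (is.null(e$experiment_id)) {
    k <- length(map$experiments) + 1L
    repeat {
      cand <- paste0("e", k)
      if (is.null(map$experiments[[cand]])) break
      k <- k + 1L
    }
    e$experiment_id <- cand
  } else if (!is.null(map$experiments[[e$experiment_id]])) {
    stop(sprintf("duplicate experiment_id %s in map %s",
                 deparse(e$experiment_id), deparse(map$map_id)), call. = FALSE)
  }
  if (is.null(e$source_id)) e$source_id <- map$map_id
  map$experiments[[e$experiment_id]] <- e
  map
}

#' Add a hypothetical assertion to a research map
#'
#' @param map A [research_map()].
#' @param h A [hypothesis()].
#' @return The updated map.
#' @export
add_hypothesis <- function(map, h) {
  stopifnot(is_research_map(map))
  if (!inherits(h, "hypothesis")) stop("`h` must be a hypothesis", call. = FALSE)
  if (is.null(h$source_id)) h$source_id <- map$map_id
  map$hypotheses[[length(map$hypotheses) + 1L]] <- h
  map
}

#' Highlight a directed edge as a main finding
#'
#' @param map A [research_map()].
#' @param agent,target [phenomenon()] endpoints of an existing empirical or
#'   hypothetical edge (checked by [validate_map()]).
#' @return The updated map.
#' @export
highlight_edge <- function(map, agent, target) {
  stopifnot(is_research_map(map))
  row <- data.frame(agent_key = node_key(as_phenomenon(agent)),
                    target_key = node_key(as_phenomenon(target)),
                    stringsAsFactors = FALSE)
  map$highlighted <- unique(rbind(map$highlighted, row))
  map
}

#' Nodes of a research map
#'
#' Derives the node table from the map's experiments and hypotheses. Display
#' casing is the first-seen spelling of each node.
#'
#' @param map A [research_map()].
#' @return A data frame with columns `key`, `what`, `where`, `when`.
#' @export
map_nodes <- function(map) {
  stopifnot(is_research_map(map))
  phens <- list()
  for (e in map$experiments) phens <- c(phens, list(e$agent, e$target))
  for (h in map$hypotheses) phens <- c(phens, list(h$agent, h$target))
  nodes_from_phenomena(phens)
}

nodes_from_phenomena <- function(phens, mode = "full") {
  if (length(phens) == 0) {
    return(data.frame(key = character(), what = character(),
                      where = character(), when = character(),
                      stringsAsFactors = FALSE))
  }
  keys <- vapply(phens, node_key, "", mode = mode)
  first <- !duplicated(keys)
  df <- data.frame(
    key = keys[first],
    what = vapply(phens[first], function(p) p$what, ""),
    where = if (mode == "full") vapply(phens[first], function(p) p$where, "") else "",
    when = if (mode == "full") vapply(phens[first], function(p) p$when, "") else "",
    stringsAsFactors = FALSE
  )
  df[order(df$key), , drop = FALSE]
}

#' Edges of a research map
#'
#' Derives the directed edge table: one row per directed (Agent, Target)
#' pair carrying at least one experiment or hypothesis.
#'
#' @param map A [research_map()].
#' @return A data frame with columns `agent_key`, `target_key`,
#'   `n_experiments`, `n_hypotheses`, `empirical`, `hypothetical`,
#'   `highlighted`.
#' @export
map_edges <- function(map) {
  stopifnot(is_research_map(map))
  ek <- t(vapply(map$experiments,
                 function(e) c(node_key(e$agent), node_key(e$target)),
                 character(2)))
  hk <- t(vapply(map$hypotheses,
                 function(h) c(node_key(h$agent), node_key(h$target)),
                 character(2)))
  pairs <- rbind(if (length(map$experiments)) ek, if (length(map$hypotheses)) hk)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(agent_key = character(), target_key = character(),
                      n_experiments = integer(), n_hypotheses = integer(),
                      empirical = logical(), hypothetical = logical(),
                      highlighted = logical(), stringsAsFactors = FALSE))
  }
  id <- paste(pairs[, 1], pairs[, 2], sep = KEY_SEP)
  n_exp <- if (length(map$experiments)) table(paste(ek[, 1], ek[, 2], sep = KEY_SEP)) else table(character())
  n_hyp <- if (length(map$hypotheses)) table(paste(hk[, 1], hk[, 2], sep = KEY_SEP)) else table(character())
  uidx <- which(!duplicated(id))
  uidx <- uidx[order(id[uidx])]
  uid <- id[uidx]
  hl <- paste(map$highlighted$agent_key, map$highlighted$target_key, sep = KEY_SEP)
  data.frame(
    agent_key = pairs[uidx, 1],
    target_key = pairs[uidx, 2],
    n_experiments = as.integer(ifelse(uid %in% names(n_exp), n_exp[uid], 0L)),
    n_hypotheses = as.integer(ifelse(uid %in% names(n_hyp), n_hyp[uid], 0L)),
    empirical = uid %in% names(n_exp),
    hypothetical = uid %in% names(n_hyp),
    highlighted = uid %in% hl,
    stringsAsFactors = FALSE
  )
}

#' Validate a research map
#'
#' Checks every map invariant and reports all violations with their
#' location: unique experiment identifiers, no self-loops, p-values within
#' `[0, 1]`, and every highlighted pair backed by an existing empirical or
#' hypothetical edge.
#'
#' @param map A [research_map()].
#' @return A character vector of human-readable violations; empty when the
#'   map is well-formed.
#' @export
validate_map <- function(map) {
  stopifnot(is_research_map(map))
  out <- character()
  ids <- vapply(map$experiments, function(e) e$experiment_id %||% "", "")
  dup <- unique(ids[duplicated(ids) & nzchar(ids)])
  for (d in dup) {
    out <- c(out, sprintf("experiments: duplicate experiment_id %s", deparse(d)))
  }
  for (i in seq_along(map$experiments)) {
    e <- map$experiments[[i]]
    loc <- sprintf("experiments[%d]", i)
    if (same_phenomenon(e$agent, e$target)) {
      out <- c(out, sprintf("%s: self-loop (%s)", loc, format(e$agent)))
    }
    if (!is.null(e$p_value) && (e$p_value < 0 || e$p_value > 1)) {
      out <- c(out, sprintf("%s: p_value %g outside [0, 1]", loc, e$p_value))
    }
  }
  edges <- map_edges(map)
  epairs <- paste(edges$agent_key, edges$target_key, sep = KEY_SEP)
  if (nrow(map$highlighted)) {
    hpairs <- paste(map$highlighted$agent_key, map$highlighted$target_key, sep = KEY_SEP)
    for (i in which(!hpairs %in% epairs)) {
      out <- c(out, sprintf("highlighted[%d]: no empirical or hypothetical edge for this pair", i))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.research_map <- function(x, ...) {
  edges <- map_edges(x)
  cat(sprintf("<research_map> %s (%s): %d experiments, %d hypotheses, %d nodes, %d edges\n",
              x$map_id, x$visibility, length(x$experiments), length(x$hypotheses),
              nrow(map_nodes(x)), nrow(edges)))
  invisible(x)
}
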