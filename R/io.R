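# Canonical JSON serialization, graph exports, and bulk CSV import.
#
# JSON is the canonical on-disk format. Each document carries a
# schema_version, the raw map block (experiments, hypotheses, highlights),
# and a derived block (per-edge relation, score, experiment symbols). The
# derived block exists for human and downstream consumption only: it is
# never trusted on load — scores are always recomputed from the raw
# experiments, and any mismatch with the stored values is reported, with
# the recomputed values winning. Layout/coordinates are a rendering concern
# and are never serialized.

SCHEMA_VERSION <- "1.0"

ph_to_list <- function(p) list(what = p$what, where = p$where, when = p$when)

ph_from_list <- function(x, loc) {
  if (is.null(x$what)) stop(sprintf("%s: missing `what`", loc), call. = FALSE)
  phenomenon(x$what, x$where %||% "", x$when %||% "")
}

exp_to_list <- function(e) {
  out <- list(experiment_id = e$experiment_id,
              agent = ph_to_list(e$agent), target = ph_to_list(e$target),
              class = e$exp_class, outcome = e$outcome)
  for (f in c("agent_method", "target_method", "stat_test", "p_value", "source_id")) {
    if (!is.null(e[[f]])) out[[f]] <- e[[f]]
  }
  if (!is.null(e$secondary_agent)) out$secondary_agent <- ph_to_list(e$secondary_agent)
  out
}

hyp_to_list <- function(h) {
  out <- list(agent = ph_to_list(h$agent), target = ph_to_list(h$target),
              relation = h$relation)
  if (!is.null(h$source_id)) out$source_id <- h$source_id
  out
}

# Per-edge derived block of a research map: relation, score, and the
# experiment-class symbols, recomputed from the raw experiments.
derived_edges <- function(map) {
  g <- as_global_map(map)
  lapply(unname(g$edges), function(ed) {
    ne <- length(ed$experiments)
    symbols <- vapply(ed$experiments, function(r) CLASS_SYMBOLS[[r$experiment$exp_class]], "")
    list(agent_key = ed$agent_key, target_key = ed$target_key,
         empirical = ne > 0, hypothetical = length(ed$hypotheses) > 0,
         n_experiments = ne,
         relation = if (ne > 0) ed$evidence$relation else NULL,
         score = if (ne > 0 && !is.na(ed$evidence$score)) ed$evidence$score else NULL,
         class_symbols = if (ne > 0) paste(symbols, collapse = "") else NULL)
  })
}

#' Serialize a map to canonical JSON
#'
#' Writes a research map or global map as a JSON document with a
#' `schema_version`, the raw records, and a derived per-edge block
#' (relation, score, experiment symbols). The derived block is recomputed
#' and cross-checked on load, never trusted.
#'
#' @param x A [research_map()] or `global_map`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return The JSON text, invisibly when `path` is given.
#' @export
save_map <- function(x, path = NULL) {
  if (is_research_map(x)) {
    doc <- list(
      schema_version = SCHEMA_VERSION,
      type = "research_map",
      map = list(
        map_id = x$map_id,
        visibility = x$visibility,
        metadata = x$metadata,
        experiments = lapply(unname(x$experiments), exp_to_list),
        hypotheses = lapply(unname(x$hypotheses), hyp_to_list),
        highlighted = lapply(seq_len(nrow(x$highlighted)), function(i) {
          list(agent_key = x$highlighted$agent_key[i],
               target_key = x$highlighted$target_key[i])
        })
      ),
      derived = list(edges = derived_edges(x))
    )
  } else if (is_global_map(x)) {
    doc <- list(
      schema_version = SCHEMA_VERSION,
      type = "global_map",
      mode = x$mode,
      sources = as.list(x$sources),
      edges = lapply(unname(x$edges), function(ed) {
        list(agent_key = ed$agent_key, target_key = ed$target_key,
             experiments = lapply(ed$experiments, function(r) {
               c(list(map_id = r$map_id), exp_to_list(r$experiment))
             }),
             hypotheses = lapply(ed$hypotheses, function(r) {
               c(list(map_id = r$map_id), hyp_to_list(r$hypothesis))
             }),
             derived = list(
               relation = if (length(ed$experiments)) ed$evidence$relation else NULL,
               score = if (length(ed$experiments) && !is.na(ed$evidence$score))
                 ed$evidence$score else NULL))
      })
    )
  } else {
    stop("`x` must be a research map or a global map", call. = FALSE)
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path, useBytes = TRUE)
  invisible(json)
}

#' Load a map from canonical JSON
#'
#' Parses and validates a JSON map document, reporting schema violations
#' with their JSON-path locations. The map is rebuilt through the package
#' constructors (so every invariant is re-checked) and the derived per-edge
#' block is recomputed; if the stored derived values disagree, a warning is
#' emitted and the recomputed values win.
#'
#' @param path File path, or a JSON string.
#' @return A [research_map()] or `global_map`.
#' @export
load_map <- function(path) {
  txt <- if (length(path) == 1 && !grepl("[{\n]", path)) {
    paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    paste(path, collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("malformed JSON map document: %s", conditionMessage(e)),
                         call. = FALSE)
                  })
  type <- doc$type %||% "research_map"
  if (is.null(doc$schema_version)) {
    stop("$.schema_version: missing", call. = FALSE)
  }
  if (type == "research_map") {
    load_research_map_doc(doc)
  } else if (type == "global_map") {
    load_global_map_doc(doc)
  } else {
    stop(sprintf("$.type: unknown document type %s", deparse(type)), call. = FALSE)
  }
}

exp_from_list <- function(x, loc) {
  tryCatch(
    experiment(agent = ph_from_list(x$agent, paste0(loc, ".agent")),
               target = ph_from_list(x$target, paste0(loc, ".target")),
               exp_class = x$class %||% stop(sprintf("%s.class: missing", loc), call. = FALSE),
               outcome = x$outcome %||% stop(sprintf("%s.outcome: missing", loc), call. = FALSE),
               agent_method = x$agent_method, target_method = x$target_method,
               stat_test = x$stat_test, p_value = x$p_value,
               source_id = x$source_id,
               secondary_agent = if (!is.null(x$secondary_agent))
                 ph_from_list(x$secondary_agent, paste0(loc, ".secondary_agent")),
               experiment_id = x$experiment_id),
    error = function(e) stop(sprintf("%s: %s", loc, conditionMessage(e)), call. = FALSE))
}

load_research_map_doc <- function(doc) {
  mb <- doc$map
  if (is.null(mb)) stop("$.map: missing", call. = FALSE)
  if (is.null(mb$map_id)) stop("$.map.map_id: missing", call. = FALSE)
  metadata <- lapply(mb$metadata %||% list(), function(v) {
    # jsonlite parses arrays as lists; restore atomic vectors of scalars so
    # save -> load -> save is byte-stable
    if (is.list(v) && length(v) && all(lengths(v) == 1) &&
        all(vapply(v, is.atomic, TRUE))) unlist(v) else v
  })
  map <- research_map(mb$map_id, mb$visibility %||% "public",
                      metadata = metadata)
  for (i in seq_along(mb$experiments)) {
    loc <- sprintf("$.map.experiments[%d]", i)
    e <- exp_from_list(mb$experiments[[i]], loc)
    map <- tryCatch(add_experiment(map, e),
                    error = function(err) stop(sprintf("%s: %s", loc, conditionMessage(err)),
                                               call. = FALSE))
  }
  for (i in seq_along(mb$hypotheses)) {
    loc <- sprintf("$.map.hypotheses[%d]", i)
    h <- mb$hypotheses[[i]]
    hyp <- tryCatch(hypothesis(ph_from_list(h$agent, paste0(loc, ".agent")),
                               ph_from_list(h$target, paste0(loc, ".target")),
                               h$relation %||% stop("missing relation"),
                               source_id = h$source_id),
                    error = function(err) stop(sprintf("%s: %s", loc, conditionMessage(err)),
                                               call. = FALSE))
    map <- add_hypothesis(map, hyp)
  }
  for (h in mb$highlighted) {
    map$highlighted <- unique(rbind(map$highlighted, data.frame(
      agent_key = h$agent_key, target_key = h$target_key,
      stringsAsFactors = FALSE)))
  }
  check_stored_derived(map, doc$derived)
  map
}

load_global_map_doc <- function(doc) {
  if (is.null(doc$edges)) stop("$.edges: missing", call. = FALSE)
  # regroup the per-edge records into their source maps, then re-merge, so
  # pooled counts and scores are recomputed rather than trusted
  sources <- list()
  get_map <- function(id) {
    if (is.null(sources[[id]])) sources[[id]] <<- research_map(id)
    sources[[id]]
  }
  for (i in seq_along(doc$edges)) {
    ed <- doc$edges[[i]]
    for (j in seq_along(ed$experiments)) {
      loc <- sprintf("$.edges[%d].experiments[%d]", i, j)
      r <- ed$experiments[[j]]
      if (is.null(r$map_id)) stop(sprintf("%s.map_id: missing", loc), call. = FALSE)
      e <- exp_from_list(r, loc)
      sources[[r$map_id]] <- add_experiment(get_map(r$map_id), e)
    }
    for (j in seq_along(ed$hypotheses)) {
      loc <- sprintf("$.edges[%d].hypotheses[%d]", i, j)
      r <- ed$hypotheses[[j]]
      if (is.null(r$map_id)) stop(sprintf("%s.map_id: missing", loc), call. = FALSE)
      h <- hypothesis(ph_from_list(r$agent, paste0(loc, ".agent")),
                      ph_from_list(r$target, paste0(loc, ".target")),
                      r$relation, source_id = r$source_id)
      sources[[r$map_id]] <- add_hypothesis(get_map(r$map_id), h)
    }
  }
  g <- merge_maps(unname(sources), mode = doc$mode %||% "full")
  # cross-check stored derived scores against the recomputed ones
  mismatches <- character()
  for (ed in doc$edges) {
    if (is.null(ed$derived) || is.null(ed$derived$score)) next
    id <- paste(ed$agent_key, ed$target_key, sep = KEY_SEP)
    got <- g$edges[[id]]
    if (is.null(got) || is.na(got$evidence$score) ||
        abs(got$evidence$score - ed$derived$score) > 1e-9 ||
        !identical(got$evidence$relation, ed$derived$relation %||% "")) {
      mismatches <- c(mismatches, sprintf("%s -> %s", ed$agent_key, ed$target_key))
    }
  }
  if (length(mismatches)) {
    warning(sprintf("stored derived scores disagree with recomputed values for edge(s) %s; recomputed values win",
                    paste(mismatches, collapse = "; ")), call. = FALSE)
  }
  g
}

check_stored_derived <- function(map, derived) {
  if (is.null(derived) || is.null(derived$edges)) return(invisible(NULL))
  recomputed <- derived_edges(map)
  names(recomputed) <- vapply(recomputed, function(d)
    paste(d$agent_key, d$target_key, sep = KEY_SEP), "")
  mismatches <- character()
  for (st in derived$edges) {
    id <- paste(st$agent_key, st$target_key, sep = KEY_SEP)
    rc <- recomputed[[id]]
    if (is.null(rc)) { mismatches <- c(mismatches, id); next }
    rel_differs <- !identical(st$relation %||% NULL, rc$relation %||% NULL)
    sc_differs <- xor(is.null(st$score), is.null(rc$score)) ||
      (!is.null(st$score) && !is.null(rc$score) && abs(st$score - rc$score) > 1e-9)
    if (rel_differs || sc_differs) {
      mismatches <- c(mismatches, sprintf("%s -> %s", st$agent_key, st$target_key))
    }
  }
  if (length(mismatches)) {
    warning(sprintf("stored derived values disagree with recomputed scores for edge(s) %s; recomputed values win",
                    paste(mismatches, collapse = "; ")), call. = FALSE)
  }
  invisible(NULL)
}

#' Import experiments from a CSV table
#'
#' Reads one experiment per row. The header must provide at least
#' `agent_what`, `target_what`, `class`, and `outcome`; the full set of
#' recognized columns is `agent_what`, `agent_where`, `agent_when`,
#' `target_what`, `target_where`, `target_when`, `class`, `outcome`,
#' `agent_method`, `target_method`, `stat_test`, `p_value`, `source_id`.
#' The `class` column accepts canonical names, display symbols, and the
#' shorthands `PI`/`NI`/`PNO`/`NNO`. All token errors are collected and
#' reported together with their row numbers.
#'
#' @param path CSV file path.
#' @return A list of [experiment()] objects (empty for a header-only file).
#' @export
import_experiments_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("agent_what", "target_what", "class", "outcome")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("CSV header is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  opt <- function(row, col) {
    if (!col %in% names(df)) return(NULL)
    v <- trimws(row[[col]])
    if (is.na(v) || !nzchar(v)) NULL else v
  }
  out <- list()
  errors <- character()
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    e <- tryCatch(
      experiment(
        agent = phenomenon(row[["agent_what"]], opt(row, "agent_where") %||% "",
                           opt(row, "agent_when") %||% ""),
        target = phenomenon(row[["target_what"]], opt(row, "target_where") %||% "",
                            opt(row, "target_when") %||% ""),
        exp_class = row[["class"]], outcome = row[["outcome"]],
        agent_method = opt(row, "agent_method"),
        target_method = opt(row, "target_method"),
        stat_test = opt(row, "stat_test"),
        p_value = opt(row, "p_value"),
        source_id = opt(row, "source_id")),
      error = function(err) sprintf("row %d: %s", i, conditionMessage(err)))
    if (is.character(e)) errors <- c(errors, e) else out[[length(out) + 1L]] <- e
  }
  if (length(errors)) stop(paste(errors, collapse = "\n"), call. = FALSE)
  out
}

dot_quote <- function(x) {
  paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)), '"')
}

ARROWHEADS <- c(EXCITATORY = "normal", INHIBITORY = "tee",
                NO_CONNECTION = "odot", INDETERMINATE = "diamond")

#' Export a map as DOT or GraphML
#'
#' Nodes carry the What/Where/When properties on three display lines. Each
#' empirical edge carries its relation (rendered as the conventional
#' arrowhead: sharp for Excitatory, blunt for Inhibitory, dotted with a
#' circular head for No-connection, diamond for indeterminate), its score,
#' and its experiment-class symbols; hypothetical edges are styled lighter
#' and carry neither score nor symbols.
#'
#' @param x A [research_map()] or `global_map`.
#' @param format `"dot"` or `"graphml"`.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return The export text (invisibly when `path` is given).
#' @export
export_graph <- function(x, format = c("dot", "graphml"), path = NULL) {
  format <- match.arg(format)
  g <- as_global_map(x)
  nodes <- g$nodes
  ids <- stats::setNames(sprintf("n%d", seq_len(nrow(nodes))), nodes$key)
  edf <- global_edges(g)
  symbols_of <- function(ed) {
    paste(vapply(ed$experiments, function(r) CLASS_SYMBOLS[[r$experiment$exp_class]], ""),
          collapse = "")
  }
  if (format == "dot") {
    lines <- c("digraph evidence_map {", "  node [shape=box];")
    for (i in seq_len(nrow(nodes))) {
      label <- paste(nodes$what[i], nodes$where[i], nodes$when[i], sep = "\\n")
      lines <- c(lines, sprintf("  %s [label=%s];", ids[[nodes$key[i]]], dot_quote(label)))
    }
    for (i in seq_len(nrow(edf))) {
      ed <- g$edges[[paste(edf$agent_key[i], edf$target_key[i], sep = KEY_SEP)]]
      from <- ids[[edf$agent_key[i]]]; to <- ids[[edf$target_key[i]]]
      if (edf$empirical[i]) {
        rel <- edf$relation[i]
        attrs <- sprintf("arrowhead=%s", ARROWHEADS[[rel]])
        if (rel == "NO_CONNECTION") attrs <- paste0(attrs, ", style=dotted")
        label <- if (!is.na(edf$score[i])) {
          sprintf("%.4f %s", display_score(edf$score[i]), symbols_of(ed))
        } else {
          symbols_of(ed)
        }
        attrs <- paste0(attrs, sprintf(", label=%s", dot_quote(label)))
        if (edf$highlighted[i] %||% FALSE) attrs <- paste0(attrs, ", color=orange")
      } else {
        rel <- ed$hypotheses[[1]]$hypothesis$relation
        attrs <- sprintf("arrowhead=%s, style=dashed, color=gray60", ARROWHEADS[[rel]])
      }
      lines <- c(lines, sprintf("  %s -> %s [%s];", from, to, attrs))
    }
    out <- paste(c(lines, "}"), collapse = "\n")
  } else {
    doc <- xml2::xml_new_root("graphml",
                              xmlns = "http://graphml.graphdrawing.org/xmlns")
    keys <- list(c("what", "node"), c("where", "node"), c("when", "node"),
                 c("relation", "edge"), c("score", "edge"),
                 c("symbols", "edge"), c("hypothetical", "edge"))
    for (k in keys) {
      xml2::xml_add_child(doc, "key", id = k[1], "for" = k[2],
                          "attr.name" = k[1],
                          "attr.type" = if (k[1] == "score") "double" else "string")
    }
    gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
    for (i in seq_len(nrow(nodes))) {
      nd <- xml2::xml_add_child(gr, "node", id = ids[[nodes$key[i]]])
      for (f in c("what", "where", "when")) {
        d <- xml2::xml_add_child(nd, "data", key = f)
        xml2::xml_text(d) <- nodes[[f]][i]
      }
    }
    for (i in seq_len(nrow(edf))) {
      ed <- g$edges[[paste(edf$agent_key[i], edf$target_key[i], sep = KEY_SEP)]]
      e <- xml2::xml_add_child(gr, "edge",
                               source = ids[[edf$agent_key[i]]],
                               target = ids[[edf$target_key[i]]])
      add_data <- function(key, value) {
        d <- xml2::xml_add_child(e, "data", key = key)
        xml2::xml_text(d) <- as.character(value)
      }
      if (edf$empirical[i]) {
        add_data("relation", edf$relation[i])
        if (!is.na(edf$score[i])) add_data("score", edf$score[i])
        add_data("symbols", symbols_of(ed))
        add_data("hypothetical", "false")
      } else {
        add_data("relation", ed$hypotheses[[1]]$hypothesis$relation)
        add_data("hypothetical", "true")
      }
    }
    out <- as.character(doc)
  }
  if (is.null(path)) return(out)
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Generate a seeded synthetic research map
#'
#' Builds a reproducible random map for tests and demonstrations: a simple
#' directed graph in which each empirical edge is assigned a designated true
#' relation, and experiment outcomes are drawn to support that relation with
#' probability `agreement_prob` (otherwise a conflicting outcome is drawn
#' uniformly). The generator's parameters, including the seed, are recorded
#' in the map's metadata. The caller's RNG state is left untouched.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param n_empirical_edges Number of distinct directed empirical edges; at
#'   most `n_nodes * (n_nodes - 1)`.
#' @param n_hypothetical_edges Number of hypothetical assertions (pairs may
#'   coincide with empirical edges).
#' @param experiments_per_edge Integer vector from which each edge's
#'   experiment count is drawn uniformly.
#' @param class_mix Length-4 probability weights over [EXPERIMENT_CLASSES].
#' @param agreement_prob Probability that each experiment supports its
#'   edge's designated relation.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @param map_id Optional map identifier; derived from the seed by default.
#' @return A [research_map()].
#' @export
generate_fixture <- function(n_nodes, n_empirical_edges,
                             n_hypothetical_edges = 0,
                             experiments_per_edge = 1:4,
                             class_mix = rep(1, 4),
                             agreement_prob = 0.9, seed = 1L,
                             map_id = NULL) {
  n_nodes <- as.integer(n_nodes)
  n_empirical_edges <- as.integer(n_empirical_edges)
  n_hypothetical_edges <- as.integer(n_hypothetical_edges)
  if (n_nodes < 2) stop("n_nodes must be >= 2", call. = FALSE)
  max_edges <- n_nodes * (n_nodes - 1L)
  if (n_empirical_edges < 0 || n_empirical_edges > max_edges) {
    stop(sprintf("n_empirical_edges must be in [0, %d] for %d nodes",
                 max_edges, n_nodes), call. = FALSE)
  }
  if (n_hypothetical_edges < 0 || n_hypothetical_edges > max_edges) {
    stop(sprintf("n_hypothetical_edges must be in [0, %d] for %d nodes",
                 max_edges, n_nodes), call. = FALSE)
  }
  if (length(class_mix) != 4 || any(class_mix < 0) || sum(class_mix) <= 0) {
    stop("class_mix must be 4 non-negative weights", call. = FALSE)
  }
  if (agreement_prob < 0 || agreement_prob > 1) {
    stop("agreement_prob must be in [0, 1]", call. = FALSE)
  }
  experiments_per_edge <- as.integer(experiments_per_edge)
  if (any(experiments_per_edge < 1)) {
    stop("experiments_per_edge values must be >= 1", call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  wheres <- c("hippocampus", "amygdala", "cortex", "")
  whens <- c("", "adult", "training")
  nodes <- lapply(seq_len(n_nodes), function(i) {
    phenomenon(sprintf("phen%02d", i),
               wheres[sample.int(length(wheres), 1)],
               whens[sample.int(length(whens), 1)])
  })

  pick_pairs <- function(k) {
    idx <- sample.int(max_edges, k)
    a <- (idx - 1L) %/% (n_nodes - 1L) + 1L
    b <- (idx - 1L) %% (n_nodes - 1L) + 1L
    b <- ifelse(b >= a, b + 1L, b)
    cbind(a, b)
  }

  map <- research_map(map_id %||% sprintf("fixture-%d", as.integer(seed)),
                      metadata = list(
                        generator = "generate_fixture",
                        seed = as.integer(seed), n_nodes = n_nodes,
                        n_empirical_edges = n_empirical_edges,
                        n_hypothetical_edges = n_hypothetical_edges,
                        experiments_per_edge = experiments_per_edge,
                        class_mix = as.numeric(class_mix),
                        agreement_prob = agreement_prob))
  epairs <- pick_pairs(n_empirical_edges)
  true_relations <- stats::setNames(
    character(n_empirical_edges),
    paste(vapply(seq_len(n_empirical_edges),
                 function(i) node_key(nodes[[epairs[i, 1]]]), ""),
          vapply(seq_len(n_empirical_edges),
                 function(i) node_key(nodes[[epairs[i, 2]]]), ""),
          sep = KEY_SEP))
  for (i in seq_len(n_empirical_edges)) {
    true_rel <- RELATIONS[sample.int(3, 1)]
    true_relations[i] <- true_rel
    k <- experiments_per_edge[sample.int(length(experiments_per_edge), 1)]
    for (j in seq_len(k)) {
      cls <- EXPERIMENT_CLASSES[sample.int(4, 1, prob = class_mix / sum(class_mix))]
      supporting <- relation_to_outcome(cls, true_rel)
      outcome <- if (stats::runif(1) < agreement_prob) supporting else
        sample(setdiff(OUTCOMES, supporting), 1)
      map <- add_experiment(map, experiment(
        nodes[[epairs[i, 1]]], nodes[[epairs[i, 2]]], cls, outcome))
    }
  }
  map$metadata$true_relations <- true_relations
  hpairs <- if (n_hypothetical_edges > 0) pick_pairs(n_hypothetical_edges) else
    matrix(integer(), ncol = 2)
  for (i in seq_len(nrow(hpairs))) {
    map <- add_hypothesis(map, hypothesis(
      nodes[[hpairs[i, 1]]], nodes[[hpairs[i, 2]]],
      RELATIONS[sample.int(3, 1)]))
  }
  map
}
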