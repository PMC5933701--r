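# Connection experiments and their semantics.
#
# Four experiment classes probe a hypothesized Agent -> Target connection:
# two interventions (the Agent is actively increased or decreased) and two
# non-interventions (the Agent is merely observed to increase or decrease
# while the Target is measured). The measured Target outcome (increase / no
# change / decrease) combined with the class yields evidence for one of
# three relations: Excitatory, No-connection, or Inhibitory.

#' Experiment classes, outcomes, and relations
#'
#' `EXPERIMENT_CLASSES` lists the four connection-experiment classes, in the
#' canonical order positive intervention, positive non-intervention,
#' negative non-intervention, negative intervention. `CLASS_SYMBOLS` gives
#' their conventional display glyphs. `OUTCOMES` lists the three measured
#' Target outcomes and `RELATIONS` the three relations an experiment can
#' evidence (Excitatory, No-connection, Inhibitory); `INDETERMINATE` is the
#' additional edge state used when evidence is tied, which never carries a
#' score.
#'
#' @format Character vectors.
#' @name evidence-vocabulary
NULL

#' @rdname evidence-vocabulary
#' @export
EXPERIMENT_CLASSES <- c("POS_INTERVENTION", "POS_NONINTERVENTION",
                        "NEG_NONINTERVENTION", "NEG_INTERVENTION")

#' @rdname evidence-vocabulary
#' @export
CLASS_SYMBOLS <- c(POS_INTERVENTION = "\u2191",
                   POS_NONINTERVENTION = "\u2300\u2191",
                   NEG_NONINTERVENTION = "\u2300\u2193",
                   NEG_INTERVENTION = "\u2193")

#' @rdname evidence-vocabulary
#' @export
OUTCOMES <- c("INCREASE", "NO_CHANGE", "DECREASE")

#' @rdname evidence-vocabulary
#' @export
RELATIONS <- c("EXCITATORY", "NO_CONNECTION", "INHIBITORY")

#' @rdname evidence-vocabulary
#' @export
INDETERMINATE <- "INDETERMINATE"

# Short column labels used in counts tables.
RELATION_ABBREV <- c(EXCITATORY = "E", NO_CONNECTION = "N", INHIBITORY = "I")

#' Map an experiment class and outcome to the relation it evidences
#'
#' A relation is Excitatory when Agent and Target move in the same direction
#' and Inhibitory when they move in opposite directions; a Target that does
#' not change evidences No-connection. The Agent moves up in the positive
#' classes (intervention or observation) and down in the negative classes,
#' so e.g. a negative intervention followed by a Target decrease evidences
#' an Excitatory relation.
#'
#' @param exp_class One of [EXPERIMENT_CLASSES] (names or display symbols).
#' @param outcome One of [OUTCOMES].
#' @return One of [RELATIONS]. The mapping is total: every class/outcome
#'   combination evidences exactly one relation.
#' @examples
#' outcome_to_relation("POS_INTERVENTION", "INCREASE")   # EXCITATORY
#' outcome_to_relation("NEG_NONINTERVENTION", "DECREASE") # EXCITATORY
#' outcome_to_relation("NEG_INTERVENTION", "NO_CHANGE")  # NO_CONNECTION
#' @export
outcome_to_relation <- function(exp_class, outcome) {
  exp_class <- match_class(exp_class)
  outcome <- match_outcome(outcome)
  if (outcome == "NO_CHANGE") return("NO_CONNECTION")
  agent_up <- exp_class %in% c("POS_INTERVENTION", "POS_NONINTERVENTION")
  same_direction <- (outcome == "INCREASE") == agent_up
  if (same_direction) "EXCITATORY" else "INHIBITORY"
}

# The Target outcome that would support a given relation under a given
# class; inverse of outcome_to_relation, used by the fixture generator.
relation_to_outcome <- function(exp_class, relation) {
  exp_class <- match_class(exp_class)
  relation <- match.arg(relation, RELATIONS)
  if (relation == "NO_CONNECTION") return("NO_CHANGE")
  agent_up <- exp_class %in% c("POS_INTERVENTION", "POS_NONINTERVENTION")
  same_direction <- relation == "EXCITATORY"
  if (agent_up == same_direction) "INCREASE" else "DECREASE"
}

# Tolerant token parsing: accepts canonical names, display symbols, and a
# few common shorthands. Used by constructors, CSV import, and the CLI.
match_class <- function(x) {
  if (length(x) != 1 || is.na(x)) stop("experiment class must be a single string", call. = FALSE)
  x <- as.character(x)
  if (x %in% EXPERIMENT_CLASSES) return(x)
  idx <- match(x, CLASS_SYMBOLS)
  if (!is.na(idx)) return(names(CLASS_SYMBOLS)[idx])
  up <- toupper(gsub("[^A-Za-z]+", "_", trimws(x)))
  up <- gsub("_+", "_", gsub("^_|_$", "", up))
  aliases <- c(PI = "POS_INTERVENTION", NI = "NEG_INTERVENTION",
               PNO = "POS_NONINTERVENTION", NNO = "NEG_NONINTERVENTION",
               POSITIVE_INTERVENTION = "POS_INTERVENTION",
               NEGATIVE_INTERVENTION = "NEG_INTERVENTION",
               POSITIVE_NON_INTERVENTION = "POS_NONINTERVENTION",
               NEGATIVE_NON_INTERVENTION = "NEG_NONINTERVENTION",
               POSITIVE_NONINTERVENTION = "POS_NONINTERVENTION",
               NEGATIVE_NONINTERVENTION = "NEG_NONINTERVENTION",
               POS_NON_INTERVENTION = "POS_NONINTERVENTION",
               NEG_NON_INTERVENTION = "NEG_NONINTERVENTION")
  if (up %in% EXPERIMENT_CLASSES) return(up)
  if (up %in% names(aliases)) return(unname(aliases[up]))
  stop(sprintf("unknown experiment class: %s", deparse(x)), call. = FALSE)
}

match_outcome <- function(x) {
  if (length(x) != 1 || is.na(x)) stop("outcome must be a single string", call. = FALSE)
  x <- as.character(x)
  if (x %in% OUTCOMES) return(x)
  up <- toupper(gsub("[^A-Za-z0-9+-]+", "_", trimws(x)))
  up <- gsub("_+", "_", gsub("^_|_$", "", up))
  aliases <- c(INCREASE = "INCREASE", NO_CHANGE = "NO_CHANGE", DECREASE = "DECREASE",
               "B+" = "INCREASE", "B0" = "NO_CHANGE", "B-" = "DECREASE",
               "+" = "INCREASE", "0" = "NO_CHANGE", "-" = "DECREASE",
               NOCHANGE = "NO_CHANGE", NONE = "NO_CHANGE")
  if (up %in% names(aliases)) return(unname(aliases[up]))
  stop(sprintf("unknown outcome: %s", deparse(x)), call. = FALSE)
}

match_relation <- function(x) {
  if (length(x) != 1 || is.na(x)) stop("relation must be a single string", call. = FALSE)
  x <- as.character(x)
  up <- toupper(gsub("[^A-Za-z]+", "_", trimws(x)))
  up <- gsub("_+", "_", gsub("^_|_$", "", up))
  aliases <- c(E = "EXCITATORY", N = "NO_CONNECTION", I = "INHIBITORY",
               EXCITATORY = "EXCITATORY", INHIBITORY = "INHIBITORY",
               NO_CONNECTION = "NO_CONNECTION", NOCONNECTION = "NO_CONNECTION")
  if (up %in% names(aliases)) return(unname(aliases[up]))
  stop(sprintf("unknown relation: %s", deparse(x)), call. = FALSE)
}

#' Record one connection experiment
#'
#' An experiment records a single empirical result about a directed
#' Agent -> Target pair: the experiment class, the measured Target outcome,
#' and optional metadata (techniques, statistical test, p-value, source).
#' The p-value is tracked but never enters the evidence score.
#'
#' Intervention experiments with two Agents are accommodated by recording
#' the second Agent as `secondary_agent` metadata; for scoring the
#' experiment contributes only to the primary Agent -> Target edge, and any
#' putative mechanism among the three entities is expressed with
#' user-entered hypothetical edges.
#'
#' @param agent,target [phenomenon()] objects; must be distinct nodes
#'   (self-loops are rejected).
#' @param exp_class One of [EXPERIMENT_CLASSES] (symbols and common
#'   shorthands such as `"PI"` are accepted).
#' @param outcome One of [OUTCOMES].
#' @param agent_method,target_method Optional free-text technique
#'   descriptions (how the Agent was manipulated/observed and how the Target
#'   was measured).
#' @param stat_test Optional free-text name of the statistical test.
#' @param p_value Optional numeric in `[0, 1]`; stored metadata only.
#' @param source_id Optional article or map identifier.
#' @param secondary_agent Optional second Agent [phenomenon()].
#' @param experiment_id Optional unique identifier; assigned automatically
#'   by [add_experiment()] when missing.
#' @return An object of class `experiment`.
#' @examples
#' e <- experiment(phenomenon("CREB"), phenomenon("Arc"), "PI", "NO_CHANGE")
#' e$relation_evidenced
#' @export
experiment <- function(agent, target, exp_class, outcome,
                       agent_method = NULL, target_method = NULL,
                       stat_test = NULL, p_value = NULL,
                       source_id = NULL, secondary_agent = NULL,
                       experiment_id = NULL) {
  agent <- as_phenomenon(agent)
  target <- as_phenomenon(target)
  if (same_phenomenon(agent, target)) {
    stop("agent and target must be distinct phenomena (no self-loops)", call. = FALSE)
  }
  exp_class <- match_class(exp_class)
  outcome <- match_outcome(outcome)
  if (!is.null(p_value)) {
    p_value <- as.numeric(p_value)
    if (is.na(p_value) || p_value < 0 || p_value > 1) {
      stop("p_value must be in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(secondary_agent)) secondary_agent <- as_phenomenon(secondary_agent)
  structure(list(
    agent = agent, target = target,
    exp_class = exp_class, outcome = outcome,
    relation_evidenced = outcome_to_relation(exp_class, outcome),
    agent_method = if (is.null(agent_method)) NULL else as_field(agent_method),
    target_method = if (is.null(target_method)) NULL else as_field(target_method),
    stat_test = if (is.null(stat_test)) NULL else as_field(stat_test),
    p_value = p_value,
    source_id = if (is.null(source_id)) NULL else as_field(source_id),
    secondary_agent = secondary_agent,
    experiment_id = if (is.null(experiment_id)) NULL else as_field(experiment_id)
  ), class = "experiment")
}

#' @export
format.experiment <- function(x, ...) {
  sprintf("%s %s: %s -> %s [%s]",
          CLASS_SYMBOLS[[x$exp_class]], tolower(x$outcome),
          format(x$agent), format(x$target), x$relation_evidenced)
}

#' @export
print.experiment <- function(x, ...) {
  cat("<experiment> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Record a hypothetical assertion
#'
#' A hypothetical edge is a putative Agent -> Target connection asserted
#' without direct experimental evidence, used to structure and contextualize
#' empirical edges. Hypothetical edges carry neither a score nor experiment
#' symbols.
#'
#' @param agent,target [phenomenon()] objects (distinct).
#' @param relation `"EXCITATORY"`, `"INHIBITORY"`, or `"NO_CONNECTION"`.
#' @param source_id Optional article or map identifier.
#' @return An object of class `hypothesis`.
#' @export
hypothesis <- function(agent, target, relation, source_id = NULL) {
  agent <- as_phenomenon(agent)
  target <- as_phenomenon(target)
  if (same_phenomenon(agent, target)) {
    stop("agent and target must be distinct phenomena (no self-loops)", call. = FALSE)
  }
  structure(list(
    agent = agent, target = target,
    relation = match_relation(relation),
    source_id = if (is.null(source_id)) NULL else as_field(source_id)
  ), class = "hypothesis")
}

#' @export
format.hypothesis <- function(x, ...) {
  sprintf("hypothetical %s: %s -> %s", x$relation, format(x$agent), format(x$target))
}

#' @export
print.hypothesis <- function(x, ...) {
  cat("<hypothesis> ", format(x), "\n", sep = "")
  invisible(x)
}
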