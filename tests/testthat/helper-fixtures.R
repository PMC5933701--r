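# Shared builders used across the suite.

ph <- function(what, where = "", when = "") phenomenon(what, where, when)

exp_ab <- function(exp_class, outcome,
                   agent = ph("CREB", "lateral amygdala"),
                   target = ph("number of Arc neurons", "lateral amygdala"), ...) {
  experiment(agent, target, exp_class, outcome, ...)
}

# The three-experiment No-connection sequence of the worked example:
# two positive interventions and one negative intervention, all no-change.
worked_example <- function() {
  list(exp_ab("PI", "NO_CHANGE"),
       exp_ab("PI", "NO_CHANGE"),
       exp_ab("NI", "NO_CHANGE"))
}

# Pin a relation on a -> b with a single maximally informative experiment.
pin_relation <- function(map, a, b, rel) {
  out <- switch(rel,
                EXCITATORY = "INCREASE",
                INHIBITORY = "DECREASE",
                NO_CONNECTION = "NO_CHANGE")
  add_experiment(map, experiment(ph(a), ph(b), "POS_INTERVENTION", out))
}

# Six-node conflict benchmark: independence findings A-B and C-D, and
# excitatory edges A->C, D->B, A->E, E->D, D->E, E->A.
conflict_benchmark_map <- function() {
  m <- research_map("conflict-benchmark")
  m <- pin_relation(m, "A", "B", "NO_CONNECTION")
  m <- pin_relation(m, "C", "D", "NO_CONNECTION")
  m <- pin_relation(m, "A", "C", "EXCITATORY")
  m <- pin_relation(m, "D", "B", "EXCITATORY")
  m <- pin_relation(m, "A", "E", "EXCITATORY")
  m <- pin_relation(m, "E", "D", "EXCITATORY")
  m <- pin_relation(m, "D", "E", "EXCITATORY")
  m <- pin_relation(m, "E", "A", "EXCITATORY")
  m
}

key_of <- function(what) vapply(what, function(w) node_key(ph(w)), "", USE.NAMES = FALSE)

# Random experiment multiset on one fixed edge.
random_experiments <- function(n) {
  lapply(seq_len(n), function(i) {
    exp_ab(sample(EXPERIMENT_CLASSES, 1), sample(OUTCOMES, 1))
  })
}

# Worked-example CSV written to a temp file.
worked_example_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    paste("agent_what,agent_where,agent_when,target_what,target_where,target_when",
          "class,outcome,agent_method,target_method,stat_test,p_value,source_id",
          sep = ","),
    "CREB,lateral amygdala,,number of Arc neurons,lateral amygdala,,PI,no change,,,,,pmid1",
    "CREB,lateral amygdala,,number of Arc neurons,lateral amygdala,,PI,no change,,,,,pmid1",
    "CREB,lateral amygdala,,number of Arc neurons,lateral amygdala,,NI,no change,,,,,pmid1"),
    path)
  path
}
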