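---
title: "Evidence maps: model, scoring calculus, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence maps: model, scoring calculus, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evimap)
```

## The representation

An evidence map is a directed graph over *phenomena* — anything a biologist
can manipulate or measure: a gene, a protein level, a cell population's
activity, a behaviour. A phenomenon is identified by three free-text
properties, What / Where / When, compared after trimming, whitespace
collapsing, and case folding. The triple is deliberately not bound to an
ontology: the representation targets personal curation, where users keep
their own vocabularies, and Where/When distinctions (the same protein in
excitatory versus inhibitory neurons, or at different developmental stages)
are scientifically load-bearing, so empty fields still participate in
identity.

Two kinds of assertions attach to directed Agent → Target edges:

* **Experiments** — one empirical result each, classified into four
  connection-experiment classes: positive/negative intervention (the Agent
  is actively raised or lowered) and positive/negative non-intervention
  (the Agent is observed to rise or fall). Interventions probe causation
  directly but can have side effects; non-interventions check that the
  relation holds outside the manipulated setting. The measured Target
  outcome (increase / no change / decrease) combined with the class
  evidences an Excitatory, No-connection, or Inhibitory relation — e.g. a
  negative intervention followed by a Target decrease is Excitatory
  evidence, since Agent and Target moved together.
* **Hypotheses** — putative connections with no direct evidence. They carry
  neither score nor experiment symbols, but they structure maps (making an
  implied pathway explicit) and can optionally join conflict analysis.

All experiments on one directed pair aggregate on a single edge; A → B and
B → A are distinct edges. Experiments with a second Agent are stored with
`secondary_agent` metadata but score only the primary edge: there is no
formal multi-node experiment representation, and any putative mechanism
among the three entities is expressed with user-entered hypothetical edges.
Statistical tests and p-values are tracked as metadata and never enter the
score, because reporting conventions vary too much across fields to pool
them meaningfully. Highlighting marks a map's main findings and is purely
presentational.

## The scoring calculus

Evidence on an edge reduces to the 4×3 counts table $x_{c,r}$ (class $c$,
relation $r$), the sufficient statistic of the model: permuting the
experiment multiset cannot change a score. Each class row carries an
independent Dirichlet prior $\alpha_c$ over the three relations and a
multinomial likelihood, so the posterior mean probability that the next
experiment of class $c$ supports relation $r$ is

$$\mathrm{E}[\theta_{c,r}] = \frac{\alpha_{c,r} + x_{c,r}}
{\sum_r \alpha_{c,r} + n_c},$$

which with the all-ones default prior is Laplace add-one smoothing,
$(1+x_{c,r})/(3+n_c)$. Only this posterior expectation is needed; the
package never samples from the Dirichlet. The four class rows are averaged
into the convergence vector $\bar\theta$, the edge takes the relation with
the strict maximum of $\bar\theta$, and the score rescales that maximum to
$(0,1)$:

$$\mathrm{score} = \frac{\max\bar\theta - \theta_o}{1 - \theta_o},$$

with $\theta_o$ the no-evidence baseline ($1/3$ under uniform priors). The
construction encodes four axioms: consistency within a class raises the
score with strictly diminishing increments; convergence across classes
raises it faster (each class contributes an amount in $(-1/8, 1/4)$, and in
$(0, 1/4)$ when all its evidence supports the winning relation); conflicts
always lower it; and no class is privileged a priori — though a non-uniform
$\alpha$ can deliberately re-weight classes for fields where one design
dominates.

Worked numbers (all reproduced in the test suite): one positive
intervention with no change gives the class row $(0.25, 0.50, 0.25)$ and
score $0.0625$; a second consistent one gives $0.1000$ (increment $0.0375$);
a negative intervention with no change gives $0.1625$; a conflicting
positive non-intervention/increase drops it to $0.13125$ (displayed
$0.1313$), while the same conflict inside the already-represented
intervention class drops it further to $0.1250$. Four consistent
experiments, one per class, give exactly $0.25$.

### Numerical choices

* Scores are computed in double precision and stored unrounded; display
  rounds half-away-from-zero to 4 decimals (`display_score()`), so
  $0.13125$ prints as $0.1313$.
* Tie detection in $\bar\theta$ uses an absolute tolerance of $10^{-9}$.
  Counts are integers, so genuine ties are exact in rational arithmetic;
  the tolerance only absorbs floating-point noise. Tied edges are
  *indeterminate*: no relation, no score, excluded from signed pathways and
  score filters unless explicitly requested.
* Under non-uniform priors the baseline $\theta_o$ generalizes to the
  largest component of the zero-evidence convergence vector implied by
  $\alpha$, so the score is exactly zero before any experiment regardless
  of prior weighting.
* Zero evidence on an edge is representable (the edge then exists only if a
  hypothesis asserts it); an empty experiment list is accepted by the
  counting and scoring functions and yields the baseline state.

## Merging and provenance

`merge_maps()` pools many per-source maps onto one graph. Scores on the
merged graph are always recomputed from pooled counts — never averaged
across maps — because the calculus is count-based: two maps each holding
one consistent positive intervention (each scoring $0.0625$ alone) merge
into a two-experiment edge scoring $0.1000$. Every pooled edge retains the
full list of contributing experiments and hypotheses with their source map
identifiers, and an edge may be empirical and hypothetical at once.
Merging sorts maps, edges, and within-edge records canonically, so the
same multiset of maps yields a byte-identical global map in any input
order. Visibility filtering (public versus private, or one user's maps
only) is modelled simply as the choice of which maps enter the merge.

Node keying has two modes: `full` (the normalized What/Where/When triple)
and `what_only`, which collapses all nodes sharing a What and pools their
evidence — useful for shrinking large merged graphs at the cost of
conflating locations and times. In `what_only` mode an experiment whose two
endpoints collapse onto one key is dropped from that view (a graph edge
needs two distinct endpoints), which is the one situation where pooled
counts can undercount the inputs.

## Queries

Term search is case-insensitive substring matching over the three node
properties. Neighborhood queries filter edges first — inclusive score
bounds on scored empirical edges; flags for hypothetical and indeterminate
edges — and then expand breadth-first from the seed nodes up to a hop
bound, in the chosen direction (ignoring edge direction by default).
Filtering before traversal means a low-scored edge cannot act as a bridge
to deeper neighbors; the alternative (bound first, then filter for display)
would show fewer edges but more nodes, and was rejected to keep the
subgraph self-consistent: every displayed node is reachable through
displayed edges. The connectivity profile counts, for each hop count, the
non-seed nodes first reachable ignoring direction; it is validated on
analytic path-graph cases, since the published large-database profile
depends on a private corpus.

## Conflict detection

A No-connection finding between A and B is treated as orientation-free
independence. Any simple directed pathway of Excitatory/Inhibitory edges
from A to B (or B to A) implies dependence — regardless of the pathway's
polarity, which is why inhibitory chains conflict too, although only the
excitatory case is usually illustrated — so each (pathway, independence
edge) pair is one conflict. Defaults: pathways up to 4 edges, any scored
edge qualifies (`min_score = 0`), hypothetical edges excluded. The length
default covers the benchmark's length-3 pathways with headroom; no
published threshold exists, so both knobs are exposed. Conflict severity is
deliberately not aggregated into one number: each report carries the
pathway's minimum edge score and the independence edge's score separately,
because the calculus gives no principled way to combine them. A caveat
applies to all such reports: maps omit background conditions, so a
"conflict" may dissolve under closer reading — the report is a pointer, not
a verdict.

`forbidden_causation()` inverts the same logic: X cannot cause Y (directly
or indirectly) if Y already has a signed pathway to some B that is
independent of X, since a hypothetical X → Y edge would complete a
conflicting pathway. On the six-node benchmark this derives that the two
pathway-linked nodes can not be causes of each other in either direction.
`match_template()` generalizes both: any relation-labelled pattern of at
most six nodes can be searched for as a subgraph monomorphism (No-connection
edges matching in either orientation), so an inference made once can be
recycled across a database of maps regardless of node identities. The
matcher is a small backtracking search written in-package because available
graph-isomorphism routines handle either induced colored isomorphism or
unlabelled monomorphism, but not relation-labelled monomorphism with
symmetric edges; tests check it against exhaustive enumeration of injective
assignments.

## Serialization and the synthetic generator

JSON is the canonical format: a `schema_version`, the raw records, and a
derived per-edge block (relation, score, class symbols). Derived values are
never trusted on load — they are recomputed from the raw experiments and
compared, with a warning on mismatch and the recomputed values winning —
so a hand-edited score cannot survive a round trip. Layout is a rendering
concern and is never serialized. DOT and GraphML exports carry the three
node display lines and the conventional edge styling (sharp arrowhead for
Excitatory, blunt for Inhibitory, dotted/circle for No-connection, diamond
for indeterminate; hypothetical edges lighter, without score or symbols).
Machine-facing fields use ASCII class names; the ↑/⌀↑/⌀↓/↓ glyphs appear
only in display fields.

`generate_fixture()` produces seeded random maps for the property suites: a
simple directed graph whose edges each get a designated true relation, with
experiment outcomes drawn to support that relation with probability
`agreement_prob`. Defaults — 1 to 4 experiments per edge, uniform class
mix, `agreement_prob = 0.9`, no hypothetical edges — reflect a plausible
curation profile: a typical article contributes a handful of experiments
per connection, dominated by agreement, with occasional conflicting
results; no published statistics pin these values, so they were fixed once
as defaults and tests that need other regimes (e.g. `agreement_prob = 1`
for relation-recovery checks) say so explicitly. The generator emulates the
*shape* of curated maps, not their content: real maps have heavy-tailed
node degrees, correlated class usage within articles, and shared nodes
across sources. Passing tests on these fixtures therefore demonstrates the
algebraic invariants (order-independence, count conservation, round-trip
identity, oracle equivalence) — not fidelity to any real literature.

## Problem sizes used by the test suite

Deterministic benchmarks are desk-scale (single edges, a six-node conflict
graph). Property suites use 1,000 random experiment multisets of up to 10
experiments for the scoring-oracle equivalence (tolerance $10^{-12}$),
1,000 seeded 4-node fixtures for JSON round-trip identity plus 333 disjoint
map triples for merge order-independence, and 25 random graphs of up to 8
nodes for exhaustive conflict-enumeration cross-checks. These sizes were
chosen to exercise the combinatorics thoroughly while keeping the default
suite fast to run.

## Known limitations

* Free-text identity means synonyms split nodes and homonyms merge them;
  the package deliberately performs no ontology reconciliation.
* The score is an evidence weight with relative semantics; comparing scores
  across unrelated edges of very different evidence volumes is not
  meaningful, and the score is silent about effect sizes.
* Edges are not edges of a formal causal graph (no distinction between
  direct and ancestral relations, no d-separation reasoning); conflict
  detection is purely structural.
* Two-Agent experiments are metadata; interactions are representable only
  through user-asserted hypothetical edges.
* An earlier heuristic scoring variant of the same table is out of scope:
  its defining equations live in supplementary material that is not fully
  reproduced in accessible text, and guessing them would be worse than
  omitting them.
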