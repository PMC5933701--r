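# evimap

Evidence maps of causal relations between biological phenomena: build them,
score them, merge them, query them, and mine them for structural conflicts.

## The problem

A biologist reading across molecular, cellular, physiological, and
behavioural literatures accumulates two kinds of assertions about pairs of
phenomena: empirical findings ("optogenetically increasing the activity of
cell type *A* enhanced spatial learning") and hypotheses ("*A* excites *B*"
with no direct test). `evimap` represents both on one directed graph. Nodes
are phenomena identified by three free-text properties — **What** (the
entity), **Where** (its location), and **When** (its temporal context) — so
the same protein in two cell types is two nodes. Each directed edge from an
**Agent** to a **Target** aggregates every experiment recorded for that
pair.

Experiments testing a connection fall into four classes: **positive
intervention** (↑, the Agent is actively increased), **negative
intervention** (↓, actively decreased), and **positive / negative
non-intervention** (⌀↑ / ⌀↓, the Agent is merely observed to rise or fall)
while the Target's outcome (increase, no change, decrease) is measured.
Class and outcome jointly evidence one of three relations: **Excitatory**
(Agent and Target move together), **Inhibitory** (they move oppositely), or
**No-connection** (the Target does not move).

## The evidence score

Evidence on one edge is summarized by the 4×3 counts table *x₍c,r₎* of
experiments of class *c* supporting relation *r*. Each class row gets a
Dirichlet prior α₍c,r₎ (all ones by default — Laplace add-one smoothing),
giving the posterior mean probability that the next experiment of class *c*
supports relation *r*:

    E[θ₍c,r₎] = (α₍c,r₎ + x₍c,r₎) / (Σᵣ α₍c,r₎ + n_c)

The per-relation means averaged across the four classes form the
convergence vector θ̄. The edge takes the relation with the strict maximum
of θ̄ (ties leave the edge indeterminate and unscored) and the score

    score = (max θ̄ − θₒ) / (1 − θₒ),   θₒ = 1/3 under uniform priors,

which lies in (0, 1). The construction expresses how biologists weigh
evidence: repeated consistent results within one class help, but with
diminishing returns; consistent results spread across classes
(convergence) help more; conflicting results always lower the score. It is
an evidence weight, not a causal effect size.

Beyond single-edge scoring, the package merges many per-source maps into a
global map (pooling counts, re-scoring, and keeping full per-edge
provenance), supports filtered hop-limited neighborhood queries, and
detects structural conflicts: a signed causal pathway between two nodes and
a No-connection finding between the same nodes cannot all be true, and such
inferences can be recycled as node-identity-free templates.

## A worked example

Two positive interventions on CREB leave the number of Arc-expressing
neurons unchanged, then a negative intervention agrees:

```r
library(evimap)

creb <- phenomenon("CREB", "lateral amygdala")
arc  <- phenomenon("number of Arc neurons", "lateral amygdala")

m <- research_map("pmid-example")
m <- add_experiment(m, experiment(creb, arc, "PI", "no change"))
m <- add_experiment(m, experiment(creb, arc, "PI", "no change"))
m <- add_experiment(m, experiment(creb, arc, "NI", "no change"))

score_edge(m$experiments)
#> <evidence_score> NO_CONNECTION, score 0.1625 (0.1625)
#> counts (classes x relations):
#>    E N I
#> ↑  0 2 0
#> ⌀↑ 0 0 0
#> ⌀↓ 0 0 0
#> ↓  0 1 0
#> theta_bar: E=0.2792 N=0.4417 I=0.2792

score_trajectory(m$experiments)
#>   k        exp_class   outcome      relation  score
#> 1 1 POS_INTERVENTION NO_CHANGE NO_CONNECTION 0.0625
#> 2 2 POS_INTERVENTION NO_CHANGE NO_CONNECTION 0.1000
#> 3 3 NEG_INTERVENTION NO_CHANGE NO_CONNECTION 0.1625
```

The first experiment moves the score from 0 to 0.0625; the second,
consistent but in the same class, adds only 0.0375; the third opens a new
class and adds 0.0625 again — convergence outweighs consistency. A
conflicting fourth experiment lowers the score (to 0.1313 for a positive
non-intervention with an increase, or 0.1250 if the conflict lands in the
already-represented positive-intervention class).

The same operations are scriptable from a shell via the bundled CLI
(`inst/exec/evimap`): `score`, `trajectory`, `add`, `merge`, `query`,
`conflicts`, `export` (DOT/GraphML), and `fixture`.

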