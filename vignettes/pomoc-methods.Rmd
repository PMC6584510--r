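---
title: "Counting partially overlapping motifs under edge capacities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting partially overlapping motifs under edge capacities}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomoc)
```

## The model

A biological network is a directed graph `G = (V, E, c)` whose nodes are
molecules and whose edges are interactions, each edge `e_i` annotated with a
positive integer capacity `c_i` — the number of motif instances that
interaction can sustain simultaneously, a proxy for the abundance of the
molecules realizing it. An embedding of a motif pattern `M` is a subset of
network edges whose edge-subgraph is isomorphic to `M`; the identity of an
embedding is its edge set, so node mappings related by a motif automorphism
(e.g. swapping the two bifan regulators) count once. A set of embeddings is
*feasible* when no edge belongs to more of them than its capacity, and the
partially overlapping motif count is the size of a largest feasible subset
of all embeddings.

Two classical measures bracket this quantity. Unbounded capacities make
every embedding selectable (the F1 count); unit capacities forbid any edge
sharing (the F2 count, a maximum independent set on the overlap graph). The
capacity-constrained optimum is NP-hard for the same reason F2 is, which is
why the package pairs a heuristic solver with an exact oracle for small
instances.

## The search

`pomoc()` proceeds in four steps.

**Enumeration.** All embeddings are enumerated by subgraph matching,
delegated to igraph's LAD solver and collapsed to distinct edge sets in
lexicographic order. Matching is *non-induced* by default — extra network
edges among the matched nodes do not disqualify an occurrence, the standard
convention for motif frequency — with `induced = TRUE` available where the
stricter semantics is wanted. Enumeration is a replaceable front end: any
method producing the complete embedding set yields the same downstream
result, and the test suite cross-checks the matcher against exhaustive
injective node mapping on small instances.

**Guaranteed embeddings.** An embedding all of whose edges have capacity
for every embedding using them can be added to any feasible set without
breaking feasibility, so some optimum contains it. These are fixed into the
solution first and the capacities of their edges decremented. After the
decrement, any remaining embedding containing an exhausted edge can never be
selected; it is dropped before the overlap graph is built. (The search
would discard such embeddings at the first pick anyway; pre-dropping is
equivalent and keeps the invariant "every overlap-graph vertex is
individually addable" simple.)

**Random feasible start.** On the overlap graph of the remaining
embeddings, a maximal feasible solution is grown by repeatedly picking a
uniformly random vertex, decrementing the capacities of its edges, and
removing every remaining embedding that uses an edge whose residual dropped
to zero. Termination with an empty graph guarantees maximality.

**Iterated local search.** Each outer iteration first *perturbs* the
incumbent — every member independently undergoes a Bernoulli trial with
probability `p`, and a selected member is replaced by a uniformly chosen
valid non-solution neighbor (one whose substitution keeps feasibility), so
the size never changes — and then runs an improvement pass: members are
scanned in random order, all pairs of non-solution neighbors whose 1-out/2-in
swap preserves feasibility are enumerated (in sorted order, one applied
uniformly at random), and afterwards any embedding that still fits is added
greedily. The best solution is tracked separately from the perturbed
incumbent; the search stops when the best size has not improved for
`stall_limit` consecutive iterations, with a `max_iter` safety cap
(default 10,000) against pathological non-termination.

### Tunable parameters

* `p` (default **0.1**): per-member perturbation probability. A solution of
  size `s` receives about `s * p` random replacements per iteration — enough
  to leave a local optimum's basin without destroying the solution. The
  stopping rule and perturbation strength interact: both are user-supplied
  knobs, and the defaults were chosen so that the worked example and the
  small-instance oracle suite converge reliably.
* `stall_limit` (default **20** iterations): patience of the stopping rule,
  in consecutive non-improving outer iterations.
* `seed`: every stochastic component (initialization, scan order, swap and
  perturbation choices) runs under one seeded RNG stream, restored
  afterwards, so a `(network, motif, control)` triple reproduces bit-identical
  solutions.

The solver never returns an infeasible set, always contains the guaranteed
embeddings, and satisfies F2 ≤ POMOC ≤ F1 by construction; these invariants
are asserted across the test suite rather than assumed.

## The exact oracle

`max_feasible_exact()` finds the true optimum by include/exclude depth-first
search over embeddings: guaranteed embeddings are fixed up front, branching
follows decreasing overlap-graph degree (most-constrained first), inclusion
is pruned on capacity violation, and a branch is abandoned when even taking
everything remaining cannot beat the incumbent. The bound is intentionally
loose (`current + remaining < best` rather than `<=`) so that ties are
explored and the lexicographically smallest optimal index set can be
returned deterministically. Instances above `max_embeddings` (default 25)
are refused with an explicit error rather than silently approximated: the
oracle exists to validate the heuristic, not to replace it. The test suite
double-checks it against full `2^n` subset enumeration up to `n = 12`.

## Expression-derived capacities

For regulatory networks, the capacity of an interaction is derived from the
expression of its *reactant gene* as `log2(e_g) / κ` with capacity constant
`κ = 2`. Four aspects of this mapping are genuinely open and are explicit,
documented package decisions rather than inferences:

* **Log base 2** — the microarray convention; the log transform is there to
  compress highly skewed expression values.
* **Integerization** — capacities must be positive integers while the raw
  value is real; `floor` then clamp at 1 is the default as the most
  conservative rule, with `round` and `ceiling` selectable.
* **Reactant endpoint** — interpreted as the edge's *source* (the regulator
  whose product realizes the interaction); `rule = "target"` is available.
* **Variation base** — "more than 10% variation" between two conditions is
  evaluated relative to the larger of the two values, making the
  significance code symmetric and scale-invariant; two zeros are defined as
  non-significant.

## Synthetic networks

`generate_network()` emulates the synthetic evaluation conditions: an
undirected skeleton from one of three topology models, every edge oriented
by an independent fair coin, and capacities attached per scheme (all equal
to 1, 2 or 3, or uniform on 1..3). Defaults are average total degree 6 and
fixed capacity 2. Three parameterizations are fixed here because the
underlying models leave them open: ER uses the `G(n, m)` variant with
`m = n * avg_degree / 2` so the degree target is exact; Watts–Strogatz uses
rewiring probability 0.1, the canonical small-world regime; Barabási–Albert
attaches `avg_degree / 2 = 3` edges per vertex. The three models span the
qualitative regimes that matter for capacity-constrained counting: ER and WS
spread embeddings roughly uniformly over edges, so modest capacities
accommodate most of the F1 set, while BA's hubs concentrate many embeddings
on few edges and force the partially overlapping count well below F1 — the
biparallel motif, whose two internal paths pass through hub-adjacent edges,
shows this most strongly.

What the generator does *not* emulate: real regulatory networks have
degree-correlated wiring, autoregulation (self-loops are rejected by the
data model here), condition-dependent capacities spanning a wider range, and
motif distributions far from any of the three models (the yeast network is
bifan-dominated). Passing the synthetic suites therefore demonstrates
correctness of the counting machinery under controlled topologies, not
biological conclusions.

## The worked example

The package's reference instance (`fig2_instance()`) reproduces a published
worked example whose original form is a drawing. Since the drawing itself is
not machine-readable, the instance shipped here is a **synthetic
transcription**: a network and motif constructed so that *every* printed
property of the original holds — the capacity vector `(1,2,2,2,1,2,2,1)`,
six embeddings, the usage vectors `(1,1,1,0,0,1,1,1)` for `{H1,H6}` and
`(1,1,0,2,1,2,1,1)` for `{H2,H5,H6}`, infeasibility of `{H1,H2}` through
edge `e1`, `H6` as the only guaranteed embedding, feasibility of
`{H1,H4,H5,H6}`, and optima 6/4/2 under unbounded/stated/unit capacities.
These constraints over-determine the instance, so a wrong transcription
cannot pass silently; `validate_fig2()` re-derives all of them from scratch
and the test suite additionally checks that perturbed instances fail.

```{r fig2}
fx <- fig2_instance()
validate_fig2()
pomoc(fx$network, fx$motif, pomoc_control(seed = 7))
```

## Validation suite sizes and numerical choices

The shipped tests and the acceptance script exercise, by choice, problem
sizes where exhaustive ground truth is computable and full runs stay
interactive: oracle comparisons on 200 Erdős–Rényi instances of 8–15 nodes
with at most 15 embeddings each; capacity-monotonicity sweeps on 50 such
instances; and end-to-end runs on ER/WS/BA networks of 200–400 nodes at
average degree 6 for all four builtin motifs (with the solver's
`stall_limit` lowered to 5 there, since those checks assert feasibility and
the F2 ≤ POMOC ≤ F1 sandwich, not optimality). On the small-instance suite
the heuristic with default settings matches the exact optimum in ≥ 95% of
runs — a regression threshold for this implementation, not a guarantee: the
search carries no approximation bound, and adversarial instances can hold
the gap open.

Other numerical conventions, fixed for reproducibility: embeddings and
their sets are kept in lexicographic edge-index order; all user-facing edge
indices are 1-based; capacity comparisons treat `Inf` as always satisfied,
keeping F1 exact without overflow tricks; parallel edges are invalid (the
edge set is a set) while antiparallel pairs are allowed; self-loops are
rejected at load time — no builtin motif contains one, and silently
dropping them would hide data errors — with an explicit
`drop_self_loops = TRUE` downgrade.

## Limitations

* The heuristic has no optimality guarantee; the oracle covers only small
  instances (≤ 25 embeddings by default).
* Capacities constrain edges, not nodes; weighted-motif semantics and
  undirected networks are out of scope.
* The package counts; it does not assess statistical over-representation
  against randomized ensembles.
* Enumeration cost grows with motif size and network density; dense
  networks with unbounded capacities are best counted with F1 directly.
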