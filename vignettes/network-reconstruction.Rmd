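---
title: "Training signaling topologies by conflict-scored shortest paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training signaling topologies by conflict-scored shortest paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrecon)
```

## The problem and the model

Literature-derived protein interaction networks list candidate signaling
reactions without cellular context: in any particular cell type only a
subset of those reactions is functional. `sigrecon` compresses such a prior
knowledge network (PKN) — a directed graph $G = (V, E)$ of named proteins
with every reaction carrying unit weight — against a Boolean single-treatment
experiment: a matrix $x$ with one row per stimulus $r$ and one column per
measured signal $c$, where $x_{rc} = 1$ records an activated phosphorylation
state and $x_{rc} = 0$ an unchanged one.

Each activation implies a *dependency*: the trained network must contain a
directed route from stimulus $r$ to signal $c$. Each zero defines a
*conflict node* for that stimulus row: a path used on behalf of stimulus
$r$ that passes through a signal measured inactive under $r$ contradicts
the data. Conflicts are strictly per-row; a node inactive under one
stimulus constrains no other stimulus. The trained model is a subgraph of
the PKN; no reaction is ever invented, so a dependency whose signal is
unreachable in the scaffold stays unmet by design and simply contributes to
the fit error.

## The pipeline

**Direct Paths.** All-pairs shortest paths are computed once by
Floyd–Warshall on the unit-weight graph, with a next-hop matrix that fixes
one canonical path per ordered pair. Dependencies are processed in
row-major matrix order; a dependency whose canonical path is conflict-free
commits that path's reactions immediately.

**Alternative paths.** For a dependency whose canonical path is
conflicted, the search first asks whether *any* conflict-free route exists:
the canonical path is taken if it qualifies, otherwise a breadth-first
search on the conflict-masked graph returns the shortest conflict-free
route as the sole candidate. Only when no conflict-free route exists are
scored candidates enumerated: a BFS from the stimulus visits alternative
starting points $v$ in deterministic first-in-first-out order (neighbours
expanded in edge-input order), and each BFS-tree prefix is composed with
the canonical shortest path from $v$ to the signal. Distinct simple
composites are collected up to a configurable cap (default 1000, warning
when hit) and ordered by total length, ties broken by discovery order.
The two-stage design is our reading of an under-specified step: returning
a conflict-free route the moment one exists is exactly what the composite
scan is for, and doing it on the masked graph makes the guarantee checked
in the planted-subnetwork simulations provable rather than incidental.

**Scoring.** A conflicted candidate is accepted only if the dependencies
it serves balance the conflict nodes it introduces:
$\mathrm{score} = n_\mathrm{served} - n_\mathrm{conflicts}$. A candidate
serves its own dependency, every still-unmet dependency of the same
stimulus whose signal lies on the path, and every previously satisfied
dependency of that stimulus whose committed route runs through one of the
candidate's conflict nodes — admitting the conflict is what keeps those
routes alive, so they are credited to it. We deliberately do *not* credit
previously satisfied dependencies that merely share conflict-free reactions
with the candidate (every path of a stimulus shares its first reaction, so
that reading would inflate nearly every score), and we do not credit
dependencies that merely become reachable through reactions committed for
the *other* stimulus; both alternatives change the published toy scores and
make draw cases vanish. Under this rule the three conflicted toy
dependencies score 1−1, 2−2 and 1−1 in any processing order.

Candidates are scanned shortest-first and the first one with score > 0 is
committed — or score ≥ 0 when draw cases are included (the default:
`include_draws = TRUE`). A zero-score *draw* adds connectivity information
at the price of admitted conflicts; switching draws off demands strictly
positive evidence. After every commit the remaining unmet dependencies are
re-checked for incidental satisfaction, defined as a *conflict-free* route
over the reactions already included: plain reachability is not enough,
because a route through an inactive node would silently contradict the
data the scoring step just weighed.

**Nullification.** Conflicts committed into the model are sunk costs: a
final pass rescores the remaining unmet dependencies with the admitted
conflict nodes of their stimulus removed from the count, repeating until no
status changes (the pass is idempotent). Some conflicts pay off only
jointly, across several dependencies, and this pass is what lets a
combination succeed where each single dependency failed. In the ordinary
scoring pass conflicts are counted in full even when already admitted —
that is what the published worked example does (its second draw counts a
previously admitted node again) — so nullification is an explicit final
stage, not a running discount.

## Evaluation

The reachable-signals matrix $x^{cm}$ of the compressed model marks
$x^{cm}_{rc} = 1$ iff signal $c$ is reachable from stimulus $r$ over the
included reactions, and the fit error is

$$\mathrm{Error} = \frac{\sum_{r}\sum_{c}\,|x^{cm}_{rc} - x_{rc}|}{n_s}
  \cdot 100\%,$$

with $n_s = n_{st} \times n_{sig}$ the total number of measurements (all
bundled matrices are complete grids). The same metric applied to the full
PKN gives the untrained baseline. `jaccard_index()` compares reaction sets
with externally derived topologies (e.g. an ILP solution supplied as an
edge list), and `cross_validate()` reruns the training on random data
matrices with the template's activation count held constant, reporting
per-reaction incidence at the halfway checkpoint and at completion so the
convergence of the reaction ranking can be inspected. One master seed
spawns per-run child seeds, making any single run replayable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `include_draws` | `TRUE` | accept score-0 pathways; off requires score > 0 |
| `cap` | 1000 | scored composites collected per dependency (warning when hit) |
| `runs` (cross-validation) | 500 | random datasets per analysis |
| `keep_frac` (planted instances) | 0.6 | fraction of non-stimulus nodes in the hidden subnetwork |
| `trim_observable` | `FALSE` | restrict cross-validation to the observable–controllable part |

Distances are integers with `NA` as the unreachable sentinel; no floating
point enters the graph core. Node names are case-sensitive and
whitespace-trimmed, with no alias mapping. Self-loops are dropped at parse
time with a warning. Cyclic PKNs are accepted (composites that would
revisit a node are discarded), though canonical-path choices inside cycles
are a tie-break convention, not a biological statement.

## Determinism and tie-breaking

Every source of arbitrariness is pinned: Floyd–Warshall scans intermediate
nodes in ascending first-appearance index and replaces a path only on
strict improvement; BFS uses a FIFO frontier with neighbours in edge-input
order; candidate lists sort by length then discovery order; dependencies
are processed in row-major matrix order. Two runs on the same inputs are
byte-identical. Results can depend on the dependency order — that order is
a modelling choice, and the decision log records every commit (status,
route, score, conflicts) so any solution can be replayed and audited.

## What the synthetic generators emulate

`random_dag()` draws acyclic scaffolds with stimuli as genuine sources —
convenient, though nothing in the method requires acyclicity.
`planted_instance()` builds *consistency* benchmarks: every non-stimulus
node is measured and the data records exact reachability inside a hidden
induced subnetwork. Because the planted part is induced and fully
observed, any conflict-free path in the scaffold stays inside the planted
reactions, so zero fit error is attainable and the tests demand it.
Real phosphoproteomic data differ in every inconvenient way: only a few
proteins are measured, discretization is noisy, and feedback loops exist.
Passing the planted suite therefore shows the machinery is sound — it does
not show that real data are realizable, and on real inputs a residual
error (from unreachable dependencies and unresolved conflicts) is the
expected outcome, as in the bundled hepatocyte design whose
TNFA-to-SHP2 dependency has no supporting route in its published scaffold.

Test problem sizes (hundreds of graphs at ≤ 8 nodes for the exhaustive
oracles, 100 replicates at 10–16 nodes for the planted and subset
properties, 20–40 cross-validation runs) were chosen so the exhaustive
oracles stay exact and the whole suite runs in well under a minute; the
algorithmic cost on the bundled fixtures is negligible.

## Known limitations

* Static Boolean formalism: no kinetics, no time courses, no inhibitors,
  single treatments only (no stimulus combinations).
* Heuristic, order-dependent training: no global optimality claim; the
  method aims at a small superset of the optimum, and comparison against
  an exact formulation is delegated to `jaccard_index()` on an external
  edge set.
* Edge signs and confidences are out of scope — reactions are unsigned and
  unit-weight throughout.
* The published medium/large scaffolds are external inputs; only the
  printed hepatocyte data matrix ships with the package, so their headline
  error figures are not re-derivable from bundled material alone.
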