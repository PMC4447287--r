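# sigrecon

Cell-type-specific signaling topologies from prior knowledge and Boolean
phosphoproteomic data.

Literature-curated protein interaction networks list *candidate* reactions;
in any given cell type only some of them are functional. `sigrecon` trains
such a prior knowledge network (PKN) — a directed graph G = (V, E) of
proteins with unit-weight reactions — against a Boolean single-treatment
experiment: a stimulus × signal matrix x where x_rc = 1 records activated
phosphorylation of signal c under stimulus r. Every activation implies a
dependency (the model must connect r to c); every zero marks a conflict
node for that stimulus row (a path for r through a node measured inactive
under r contradicts the data).

The training pipeline is graph-theoretic rather than optimization-based:

1. **Direct Paths** — Floyd–Warshall all-pairs shortest paths with
   deterministic next-hop reconstruction; a dependency whose canonical
   shortest path is conflict-free commits that path.
2. **Alternative paths** — a breadth-first search finds alternative
   starting points; conflict-free routes are taken as soon as one exists,
   otherwise composite candidates (BFS prefix + shortest-path suffix) are
   scored shortest-first.
3. **Scoring** — a conflicted candidate is accepted when
   `score = n_served − n_conflicts` clears the threshold (> 0, or ≥ 0 when
   draw cases are included, the default).
4. **Nullification** — remaining unmet dependencies are rescored with
   already-admitted conflicts exempt from counting, until stable.

The compressed model is evaluated by its reachable-signals matrix and the
percentage fit error `Error = Σ|x_rc^cm − x_rc| / n_s · 100%`, can be
cross-validated against random data matrices with a constant activation
count, and compared to external topologies via the Jaccard index. Outputs
include Graphviz DOT text, TSV reports, and a JSON decision log that makes
every commit auditable.

## Worked example

The bundled two-stimulus EGF/TNFA fixture (27 proteins, 28 reactions, 10
measured signals) illustrates the whole pipeline:

```r
library(sigrecon)

fx  <- toy_fixture()
sol <- reconstruct(fx$net, fx$data)
sol
#> compressed model: 24 node(s), 25 reaction(s) of 28 in the PKN
#> dependencies: 11 satisfied / 14 total (satisfied-direct: 8, satisfied-draw: 3, unmet-unreachable: 3)
#> fit error: 35.0%

reachable_matrix(sol, fx$data)
#> reachable-signals matrix: 2 stimuli x 10 signals (15 reachable)
#>      RAF-1 ERK AP1 GSK-3 P38 NFKB IKK MAP3K1 MAP3K7 PI3K
#> EGF      1   1   1     1   1    0   0      1      0    1
#> TNFA     0   0   1     1   1    1   1      1      1    1
```

Fourteen dependencies are extracted from the data matrix. Eight are
satisfied by conflict-free Direct Paths; NFKB, IKK and MAP3K7 are
unreachable from EGF in the scaffold and stay unmet (no reaction is ever
invented); and the three conflicted TNFA dependencies commit as draw
cases — e.g. the TNFA → NFKB route serves two dependencies (NFKB and P38)
while introducing the two inactive intermediates MAP3K7 and IKK, scoring
2 − 2 = 0. The three dashed decoy reactions (the FADD/CASP8 arm and
RAS → RAL) are excluded from the trained model. The reachable matrix
disagrees with the data in 7 of 20 cells, hence the 35% fit error; with
`include_draws = FALSE` the three draws stay unmet and the model keeps 20
reactions.

A file-based front end writes the full output set (DOT, reachable matrix,
error report, decision log, optional incidence table):

```r
run_reconstruction("network.txt", "stimuli.txt", "signals.txt", "data.txt",
                   out = "results", cv_runs = 100, seed = 7)
```

or from a shell via `inst/scripts/sigrecon --network ... --stimuli ...
--signals ... --data ...` (flags `--no-draws`, `--cap`, `--cross-validate`,
`--seed`, `--out`, `--sif3`).

The discretized 5 × 16 hepatocyte stimulus-response matrix ships in
`inst/extdata/` (`hepatocyte_data()`, 22 dependencies); its medium-scale
PKN is an external input and is not bundled.

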