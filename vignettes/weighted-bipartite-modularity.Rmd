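---
title: "Weighted modularity and module detection in bipartite networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted modularity and module detection in bipartite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bipartmod)
```

## The model

A bipartite (two-mode) network records interactions between two disjoint
node classes — say `r` plant species (rows) and `c` pollinator species
(columns) — as an incidence matrix `W` of non-negative weights (visit
counts, biomass flows, ...). A *module* is a joint set of row and column
nodes; a partition assigns one module label `g_u` to every row node and
`h_v` to every column node.

The quality function is the weighted extension of Barber's bipartite
modularity,

$$Q_W = \frac{1}{M} \sum_{u=1}^{r}\sum_{v=1}^{c}
  \left(W_{uv} - \frac{y_u z_v}{M}\right)\,\delta(g_u, h_v),$$

where `M` is the total edge weight, `y` and `z` are the row and column
marginal totals, and the Kronecker delta selects within-module pairs. The
null term `y_u z_v / M` is the weight expected between `u` and `v` if
interactions attached to nodes proportionally to their marginal totals, so
`Q_W` measures excess within-module weight. On a presence/absence matrix the
marginals are node degrees and `M` is the number of edges, recovering the
binary definition exactly; `binary_modularity()` is therefore just
`weighted_modularity()` after `binarize()`. Key elementary properties, all
enforced by tests: the single-module partition scores 0; `Q_W` is invariant
to module relabelling; and `Q_W <= Q_max` (below).

For computation the package uses the algebraically identical matrix form
`Q_W = tr(R (W - E) C)/M`, with `R` and `C` the module membership indicator
matrices; the explicit double sum is retained as a second code path
(`form = "sum"`) purely so the equivalence can be asserted to 1e-12.

### Companion statistics

* **Maximum and normalized modularity.** `max_modularity()` evaluates the
  partition in the "perfectly mixed" network where all weight is
  within-module, `Q_max = 1 - \sum_t Y_t Z_t / M^2` over modules `t`;
  `normalized_modularity()` is `Q / Q_max`, comparable across networks of
  different size and fill. For the single-module partition `Q_max = 0` and
  the ratio is undefined: the package returns `NA` as an explicit undefined
  marker rather than 0 or an error, since the quantity has no value there.
* **Realized modularity** `Q'_R = 2H/M - 1`, with `H` the within-module
  weight: a null-model-free fraction-based view, 1 when all weight is
  within modules and 0 when half is.
* **NMI.** `nmi()` compares two partitions over all `r + c` nodes of both
  classes jointly via the confusion matrix. The logarithm base cancels
  between numerator and denominator; a `base` argument is exposed only so
  tests can assert that invariance. Two degenerate choices are documented:
  when both partitions are the single-module partition the defining ratio
  is 0/0 but the structures are identical, so NMI is defined as 1; and when
  the confusion matrix shows a one-to-one module correspondence the value
  is returned as exactly 1, avoiding spurious `1 - 2e-16` results from
  floating-point log arithmetic.

## The optimizers

Maximizing modularity is NP-hard; the package implements a two-stage label
propagation heuristic (`lpawb_plus()`) and a restart sweep around it
(`dirtlpawb_plus()`).

**Initialization.** Each node of the smaller class receives a unique label
(bounding the module count by `min(r, c)`); the larger class starts
unassigned and is resolved by its first propagation half-sweep. The
alternative of copying a best neighbour's label was rejected for
simplicity — the first half-sweep performs exactly that arg-max anyway.

**Stage 1 — label propagation.** Alternating half-sweeps update all column
labels given the row labels, then all row labels given the column labels.
A column node `x` adopts `argmax_h (N_{xh} - Y_h z_x / M)`, where `N_{xh}`
is its weight into rows labelled `h` and `Y_h` their summed marginals (and
symmetrically for rows). Because every score in a half-sweep depends only
on the *other* class's labels, per-node visit order cannot affect any
choice; the package therefore updates a whole class jointly as one matrix
operation rather than visiting nodes in random order — same fixed points,
same monotonicity, and the half-sweep vectorizes. Ties in the arg-max are
broken uniformly at random from the run's RNG stream. Each half-sweep can
only increase `Q_W` (the candidate scores for a node sum to zero, so its
best is non-negative relative to abandoning an orphaned label, and a
currently-held label is always among the candidates otherwise); sweeps stop
when a full double sweep gains at most the package tolerance.

**Stage 2 — agglomeration.** Propagation alone gets stuck splitting true
modules (it cannot move groups of nodes together). The merge gain for
modules `a, b` is computed from module-level aggregates,
`\Delta Q = (X_{ab} + X_{ba} - (Y_a Z_b + Y_b Z_a)/M)/M` with `X` the
cross-module weight matrix, and validated in tests against full before/after
recomputation. A pair merges only when its gain exceeds the tolerance *and*
the two modules are each other's best partner — which enforces the rule
that no third module offers a larger gain with either — and all such
(necessarily disjoint) pairs are applied in one pass. Stages alternate until
no merge is applied; every merge strictly increases `Q_W`, so termination
is guaranteed.

**Restart sweep.** `dirtlpawb_plus()` first runs the unique-label start,
whose module count fixes an upper limit for the label-pool size `mu`; then
for every `mu` from `min(min_modules, limit)` up to the limit (ascending)
it reruns the optimizer `reps` times from labels drawn uniformly from `mu`
values on both classes. Defaults are `reps = 10` and `min_modules = 4`;
merging can still end below `min_modules`, and when the initial run already
finds fewer modules than `min_modules` the sweep simply runs at that limit
rather than failing. The best run is returned, so the sweep can never score
below the single run — asserted per-network in tests.

### Numerical choices

* A single package-wide tolerance (`modularity_tolerance()`, default
  `1e-10`, settable via `options(bipartmod.tolerance=)`) governs every
  "did Q increase" comparison in both stages.
* Module labels are opaque integers compared by exact equality; no string
  coercion ever occurs in the hot path.
* All randomness (tie-breaks, restart draws) flows from one RNG stream, so
  a single `seed` argument makes any run bit-for-bit reproducible; seeds
  are saved in the result objects.
* Degenerate inputs: a zero-total-weight network is a domain error for all
  statistics and optimizers; an all-zero row or column contributes nothing
  to any score and survives optimization unchanged, but `clean_network()`
  should normally be applied first (the CLI does so automatically).

## The synthetic benchmark generator

`plant_modules()` builds "perfectly modular" planted-partition networks:
rows and columns are each cut into `n_modules` contiguous blocks, every
within-module cell receives an independent negative-binomial draw
(`size = nb_size`, `mu = nb_mean`, variance `mu + mu^2/size` — the R
parameterization), and between-module cells are zero. Zero draws inside
modules are allowed; with `size = 0.5, mu = 4` about a third of
within-module cells are empty, giving the low-connectance treatment, while
`size = 2.5` gives the denser one. A row or column left entirely empty is
redrawn so the network stays clean at its exact nominal dimensions.

**Block placement.** Block sizes are multinomial: one guaranteed node per
block, the remaining nodes assigned uniformly at random. Sizes therefore
differ between realizations, but extreme imbalance is rare. This choice is
deliberate: under uniform random breakpoints, degenerate splits (such as a
49/1 column division) are common, and for those the planted partition is
*not even the modularity optimum* of the noiseless network — a large
dominant block's internal random structure supports spurious sub-modules
with higher `Q_W`, so no maximizer could "recover" the planted structure.
Multinomial sizes keep noiseless networks genuinely optimally partitioned
by their planted labels in the overwhelming majority of draws.

**Noise.** `rewire_noise()` selects `ceiling(noise * n_positive)` positive
cells without replacement and relocates each cell's full weight to a
uniformly chosen currently-zero cell, sequentially. This alters node
connections while conserving `M` and the number of positive cells exactly.
Degree-preserving double-edge swaps were rejected: they cannot change
marginal totals and degrade modular structure far too weakly. One bias of
the sequential design is documented rather than hidden: destination cells
are drawn from the *currently* zero cells, which early in the process lie
mostly between modules, so at `noise = 1` the final within-module weight
fraction settles measurably below the naive module cell-area fraction
(about 0.17 vs 0.26 in the test configuration). The unit test therefore
validates the implementation against an independent re-simulation of the
relocation process, plus the qualitative bound that structure is destroyed
at least down to the uniform level.

`generate_ensemble()` reproduces the full benchmark design — 4 treatments
(2 or 10 modules crossed with dispersion 0.5 or 2.5) x 10 initial 30 x 50
networks x 4 noise levels (0, 0.01, 0.25, 0.5) x 5 replicates = 800
networks — with per-network seeds derived from one base seed, so the same
base seed always regenerates the identical ensemble.

### What the generator does and does not emulate

The generator emulates block-structured count weights with realistic skew
and sparsity. It does not emulate nestedness within modules, degree
heterogeneity beyond what negative-binomial draws produce, sampling effort
artefacts, or hierarchical (multi-scale) module structure — all present in
real visitation webs. Passing the planted-recovery tests therefore shows
the optimizer finds planted block optima under count noise; it does not
certify behaviour on real data, where the modularity landscape is known to
be glassy and no algorithm guarantees the global maximum.

## Evaluation harness and study sizes

`repeated_runs()` applies the standard protocol for stochastic maximizers:
`n_runs` seeded runs (default 100), keeping every score and all distinct
best partitions (distinct up to relabelling — ties at the maximum with
different structures are all reported, and downstream NMI comparisons can
then be read as ranges). `benchmark_indicators()` scores a result against
a planted network by module-count ratio, modularity ratio and NMI, with the
planted modularity evaluated on the network as analysed (after noise), so
the ratio can exceed 1 once noise makes the planted labels suboptimal.
`binary_vs_weighted()` and `comparison_report()` assemble the
cross-representation and cross-algorithm comparisons, serialized losslessly
to TSV + JSON by `write_report()`/`read_report()`.

The shipped test suite exercises: exhaustive-enumeration equality on 500
networks up to 3 x 3 (the whole joint label space is searchable there); a
40-network noiseless sub-ensemble plus one replicate per noise level for
degradation trends; and 20–30-run repeated-run protocols on the bundled
10 x 12 example. These sizes keep the full suite under a minute while
leaving every statistical conclusion at ensemble scale.

A known and deliberate limitation surfaced by the noiseless benchmark: with
sparse within-module draws (`size = 0.5`), the planted partition is
occasionally strictly dominated by a finer partition (the optimizer's `Q`
exceeds the planted `Q` by 1e-4 to 5e-2 in such cases). Recovery of the
planted labels is then impossible *by construction* for any correct
maximizer, and the recovery rate on noiseless sub-ensembles plateaus around
70–85% rather than 100%; module-count over-reporting shrinks as the number
of planted modules grows. This is a property of the generative conditions,
not of the optimizer — in every such case the optimizer's score dominates
the planted score.

## The bundled worked example

The package ships a single small fixture,
`worked_example_network()`, a 10 x 12 integer-weight network used in the
README, the CLI examples and the acceptance script. It is synthetic — drawn
once from `plant_modules()` at a fixed seed and perturbed with
`rewire_noise()`, as recorded in its file header — and stands in for a
published plant–pollinator visitation matrix that cannot be redistributed
with the package. Statistics computed on it illustrate the workflow; they
are not field results.

## Known limitations

* Only non-negative weights are supported; signed interaction strengths
  need a different modularity definition.
* No null-model ensemble standardization (z-scores) is provided: what
  constitutes an appropriate weighted null model is unsettled, and
  normalized plus realized modularity are offered as the comparable
  summaries instead.
* Modularity maximization finds one resolution; hierarchical structure
  within or across modules is out of scope.
* The optimizers are heuristics: monotone improvement and restart
  dominance are guaranteed, global optimality is not (and is verified
  exhaustively only on tiny networks in the tests).
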