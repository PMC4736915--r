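# bipartmod

Community detection in **weighted bipartite networks** by modularity
maximization, for ecologists and network scientists working with two-mode
interaction data — plant–pollinator visitation webs, host–parasite records,
trade or affiliation networks. Most community detection discards interaction
strengths; `bipartmod` keeps them, finding joint modules of row and column
nodes whose *weight* density beats a marginal-total null model.

## The statistic and the algorithms

For an `r x c` incidence matrix `W` with row/column marginal totals `y`, `z`
and total weight `M`, the weighted bipartite modularity of a partition
assigning labels `g` to rows and `h` to columns is

    Q_W = (1/M) * sum_{u,v} ( W[u,v] - y[u] z[v] / M ) * delta(g[u], h[v])

(Barber's binary modularity is the special case of a 0/1 matrix). The
package maximizes `Q_W` with:

* **LPAwb+** (`lpawb_plus()`): label propagation (each node repeatedly
  adopts the label maximizing its own modularity contribution) alternating
  with multi-step agglomeration (mutually-best module pairs merge while
  that increases `Q_W`);
* **DIRTLPAwb+** (`dirtlpawb_plus()`): a restart sweep rerunning LPAwb+
  from random label pools of every size up to the single-run module count —
  slower, but never worse and much less likely to over-split.

Companion statistics: `max_modularity()` / `normalized_modularity()`
(`Q/Q_max`, comparable across networks), `realized_modularity()`
(within-module weight fraction, rescaled), and `nmi()` (partition
similarity over all `r + c` nodes). A planted-partition generator
(`plant_modules()`, `rewire_noise()`, `generate_ensemble()`) provides
ground-truthed benchmarks, and `repeated_runs()` / `comparison_report()`
implement the standard repeated-seeded-run evaluation protocol.

## Worked example

The bundled 10 x 12 network (synthetic, generated at a fixed seed — see
`?worked_example_network`) plays the role of a small visitation web:

```r
library(bipartmod)
net <- worked_example_network()
net
#> <bipartite_network> 10 x 12 nodes, total weight M = 100, fill m = 23

res <- dirtlpawb_plus(net, seed = 1)
res
#> <optimization_result> DIRTLPAwb+: Q = 0.5979 with 4 module(s) (seed 1)

normalized_modularity(net, res$partition)
#> [1] 0.7994384
realized_modularity(net, res$partition)
#> [1] 0.7
```

So the best partition found captures `Q_W = 0.598`, which is 80% of the
modularity this module assignment could reach in a perfectly mixed network,
and 85% of the edge weight falls within modules (`Q'_R = 0.7` means
`(1 + 0.7)/2 = 0.85` of `M`). Contrasting representations:

```r
cmp <- binary_vs_weighted(net, n_runs = 20, base_seed = 1)
cmp$binary$max_modularity    #> 0.557656   (Q_B, 4 modules)
cmp$weighted$max_modularity  #> 0.5979     (Q_W, 4 modules)
cmp$delta_q_norm             #> 0.03716453
cmp$nmi                      #> 0.7070318
```

The weighted and binary representations give related but different module
structures (NMI 0.71), with slightly stronger assortative mixing in the
weighted view.

The same workflow is scriptable from a shell via the CLI launcher
(`inst/scripts/bipartmod`): subcommands `fit`, `metrics`, `nmi`, `synth`
and `compare`; metrics are emitted as JSON
(`{"Q": ..., "Q_max": ..., "Q_norm": ..., "Q_realized": ..., "n_modules": ...}`).

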