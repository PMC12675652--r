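# asymweb

Directed causal structure from undirected food webs.

Food webs are usually recorded as binary, undirected networks: species A
and species B interact, and nothing more. Yet the *effects* species exert
on one another through such a network are not symmetric. `asymweb`
implements a purely topological route from an undirected food web to a
directed, weighted graph of its most clearly one-way interspecific
effects — the **asymmetry graph** — together with a panel of 21 systemic
indicators and a correlation screen relating asymmetry-graph structure to
ecosystem-level properties such as total biomass. It is aimed at food-web
ecologists working with Ecopath-style models (e.g. EcoBase exports) or any
binary interaction network.

## The method

**Topological importance.** For an undirected web, the one-step effect of
species *i* on species *j* is defined as 1/*D<sub>j</sub>* when they
interact (each species divides the influence it receives equally among its
*D<sub>j</sub>* neighbours), and 0 otherwise. Writing *M* for this matrix,
the *m*-step effect is the matrix power *M<sup>m</sup>* — a sum over all
*m*-step walks of the products of one-step effects. The topological
importance index aggregates steps up to *n*:

TI<sup>n</sup><sub>ij</sub> = (1/n) Σ<sub>m=1..n</sub> (M<sup>m</sup>)<sub>ij</sub>

with *n* = 3 as the standard working depth: three steps capture most
ecologically meaningful indirect effects while longer chains decay.
Entry (*i*, *j*) is the effect **of** *i* **on** *j*.

**Asymmetry graph.** The asymmetry of a pair is
A<sub>ij</sub> = |TI³<sub>ij</sub> − TI³<sub>ji</sub>|. Ranking all
*N*(*N*−1)/2 pairs and keeping the top 1% — a budget of
max(1, ⌊*t·N*(*N*−1)/2⌋) links, so a 67-node web keeps 22 and a small
8-node web keeps a single one — gives the asymmetry graph: each retained
pair becomes a directed link from the stronger affecter to the weaker,
weighted by the asymmetry. Candidate pairs are **not** restricted to
food-web links; strongly asymmetric indirect effects compete equally.

**Indicators and screen.** Per web the package computes 8 food-web
indicators (N, L, connectance, mean distance, transitivity, mean/max
prey-averaged trophic level, fraction of species with TL > 2), 8
asymmetry-graph indicators (nodes, links, components, bottom-up and
top-down link counts by trophic direction, their ratio, sources, sinks),
2 combined ratios, and 3 non-network measures (Shannon diversity of
biomass, total biomass, mean ecotrophic efficiency with unrealistic
values outside [0, 1] omitted). Indicator pairs across a collection are
screened with Kendall's τ (tau-b) under Benjamini–Hochberg FDR control at
q < 0.05.

A seeded generator (`ecopath_web`, `niche_model_web`,
`synthetic_collection`) builds realistic synthetic collections with
biomass and ecotrophic-efficiency attributes so the entire pipeline runs
offline.

## Worked example

```r
library(asymweb)

web <- fixtures()$toy8          # small didactic web: 8 nodes, 9 links
ag  <- asymmetry_graph(web, n = 3, t = 0.01)
summary(ag)
#> asymmetry_graph 'toy8': 2 nodes, 1 links (budget 1 at t = 0.01, n = 3 steps)
#> directed acyclic graph, 1 weakly connected component(s)
#>
#> links (by asymmetry):
#>  source target     weight
#>       F      H 0.05128205

tl <- trophic_levels(web)
classify_links(ag, tl)$classes
#>   source target     weight     class
#> 1      F      H 0.05128205 bottom-up
```

At the 1% threshold this web's budget is a single link (28 pairs × 0.01,
promoted to 1). The strongest asymmetry is the F–H pair, oriented F → H
because TI³(F→H) > TI³(H→F): the mid-level species F affects the sparsely
connected top species H far more than the reverse — a bottom-up effect,
since F sits at trophic level 3 and H at 4. The weight is the asymmetry
value on the normalized TI³ scale (all off-diagonal effects sum to 1).

Collection-level screen on a synthetic collection:

```r
coll <- synthetic_collection(n_webs = 34, seed = 1)
tab  <- indicator_table(coll)      # 34 x 22: web_id + 21 indicators
ct   <- correlation_table(tab)     # 210 indicator pairs, BH-adjusted
ct[ct$var1 == "BUag" & ct$var2 == "TB", ]
#>  var1 var2    tau     p     q n_used significant
#>  BUag   TB 0.0565 0.645 0.796     34       FALSE
```

`tau` is the tie-corrected Kendall correlation across webs, `q` the
BH-adjusted p-value; `significant` flags q < 0.05. Any single seed is
noisy — the bottom-up/biomass association is a directional tendency
across collections (see the acceptance tests), not a fixed constant.

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/scripts/asymweb-cli.R simulate --n-webs 34 --seed 1 --out webs/
Rscript inst/scripts/asymweb-cli.R compute webs/synth_001.tsv --out results/
Rscript inst/scripts/asymweb-cli.R batch webs/ --min-nodes 50 --out results/
Rscript inst/scripts/asymweb-cli.R sensitivity webs/synth_001.tsv --out results/
```

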