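---
title: "Asymmetry graphs from food-web topology: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetry graphs from food-web topology: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymweb)
```

## The model

A binary, undirected food web records who interacts with whom and nothing
about direction or strength. The asymmetry-graph method extracts directed
structure from that topology alone. Its single mechanistic assumption is
the one-step effect rule: species *j* divides the influence it receives
equally among its D~j~ neighbours, so the one-step effect of *i* on *j*
is 1/D~j~ if they interact and 0 otherwise. Everything else follows by
composition:

* the m-step effect of *i* on *j* is the sum over all m-step **walks**
  (walks may revisit nodes — this is the matrix power M^m^, not a
  simple-path sum);
* TI^n^(i, j) averages the 1- to n-step effects (the 1/n mean; a plain-sum
  variant is available via `aggregate = "sum"` for sensitivity work);
* the pair asymmetry is A(i, j) = |TI^n^(i, j) − TI^n^(j, i)|;
* the asymmetry graph keeps the top fraction *t* of the N(N−1)/2 pairs,
  each oriented from the stronger affecter to the weaker.

The effect matrix is oriented row-acts-on-column: entry (i, j) is the
effect of *i* on *j*. Because columns of M sum to one over non-isolated
nodes, total influence is conserved step by step; asymmetries arise purely
from degree heterogeneity and wiring, which is the point of the method —
symmetric inputs generate directed, weighted outputs.

```{r toy}
web <- fixtures()$path3
ti_matrix(web, n = 3, normalize = FALSE)
```

On the 3-chain the endpoint affects the hub with 1/3 while the hub affects
the endpoint with 2/3: hubs dilute incoming influence but concentrate
outgoing influence on poorly connected partners. That intuition scales up:
in real webs the extreme asymmetries typically join richly connected
low-trophic-level species to sparsely connected predators, oriented
bottom-up.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n` (steps) | 3 | depth of indirect-effect propagation. Three steps carry most ecologically meaningful influence; effects decay with each division by degree, and deeper propagation mostly re-mixes what shorter walks already capture. |
| `t` (threshold) | 0.01 | fraction of all unordered pairs admitted to the asymmetry graph. The link budget is max(1, ⌊t·N(N−1)/2⌋); the floor is promoted to one link so small webs are never empty by arithmetic. Sensitivity runs use t ∈ {0.005, 0.01, 0.05, 0.10, 0.20} (`sensitivity_table`). |
| `normalize` | `TRUE` | divide TI^n^ by its grand off-diagonal total. This is a pure rescaling: ranks, orientations, and hence the asymmetry graph's topology are invariant to it; only reported weights change. The exact normalising constant used by other implementations may differ, so only scale-free quantities should be compared across tools. |
| `min_nodes` | 50 | collection filter, strict inequality (webs with *more than* 50 nodes are kept). |
| `ee_valid_range` | [0, 1] | ecotrophic efficiencies outside this interval are treated as artefacts of unbalanced mass-balance models and omitted from the EE mean, with a log message naming each node. |

## Numerical and convention choices

**Budget rounding.** max(1, floor(t·N(N−1)/2)) reconciles the two
behaviours a user expects: a 0.28-link budget at N = 8 is promoted to a
single link, while 22.11 at N = 67 truncates to 22 (a ceiling would give
23).

**Ties and zeros.** Pairs are sorted by (asymmetry descending, source
label, target label) and exactly the first *k* positive-asymmetry pairs
are kept. Exact-zero pairs are never admitted even when the budget is
unfilled — a zero-weight "causal" link is meaningless. This makes the link
count exactly min(k, #positive pairs) and the whole construction
deterministic. On vertex-transitive graphs (cycles, complete graphs) every
asymmetry is zero and the asymmetry graph is empty by design.

**Orientation.** A link runs source → target iff TI^n^(source → target) >
TI^n^(target → source); equality implies zero asymmetry, so no tie-break
is needed for orientation itself.

**Trophic levels.** Prey-averaged (the mass-balance convention): basal
species sit at 1; otherwise TL~i~ = 1 + mean TL of prey. The linear system
is solved exactly, so loops are fine as long as it is non-singular; a pure
reciprocal loop with no outside prey makes it singular and the error names
the strongly connected cycle. If the input supplies trophic levels, those
take precedence (`method = "provided"`). Asymmetry links between
equal-level species (within 1e-9) are classed *lateral* and counted in
neither the bottom-up nor top-down tally — silently assigning ties would
bias the ratio. The TD/BU ratio is reported missing (never 0 or ∞) when no
bottom-up link exists, and the TL > 2 carnivore cut uses a 1e-9 tolerance
so exact herbivores are excluded.

**Distances and connectance.** Mean shortest-path length is computed on
the undirected graph over reachable pairs only (unreachable pairs are
excluded with a log message — the only finite convention). Connectance
uses the undirected pair universe L/(N(N−1)/2), the same universe as the
link budget; transitivity is the global clustering coefficient.

**Degenerate inputs.** Edgeless webs error on normalization (zero grand
total); isolated nodes carry zero effect rows/columns; cannibalistic
self-loops are dropped on read with a warning because they would distort
degree and hence every TI value.

## Statistics

The screen computes tie-corrected Kendall τ (tau-b — count indicators tie
heavily across webs) with `cor.test`'s two-sided p-value per pair,
pairwise-complete deletion, and Benjamini–Hochberg adjustment **jointly**
across the computable pairs (constant columns are excluded from the
family, and the family size is therefore data-dependent, not a fixed
210). Significance is declared at q < 0.05; star annotations in the
exported matrix also use q thresholds, not raw p.

## The synthetic generator

Two topology generators are provided. `niche_model_web` is the classic
niche model: niche values uniform on (0, 1), contiguous feeding ranges of
beta-distributed width proportional to the niche value, calibrated so the
expected directed connectance (links/N²) matches the target; isolated or
trophically duplicate species get their range redrawn (per-species repair,
as in the original construction) and the web is redrawn until connected
with solvable trophic levels.

`synthetic_collection` (the default source of test collections) instead
uses `ecopath_web`, for a structural reason worth spelling out. Under the
classic width rule, range width grows with niche position, so
high-trophic-level species become the most connected generalists — degree
*rises* with trophic level. Mass-balance models of real ecosystems show
the opposite: the basal guild (producers, detritus) is an explicit,
sizeable block of compartments consumed by much of the web, and top
predators are few and sparsely linked, so degree *falls* with trophic
level. Because asymmetric effects orient toward the lower-degree member of
a pair, this relation decides whether a collection's asymmetry graphs come
out bottom-up- or top-down-dominated. `ecopath_web` therefore wires
niche-structured consumers over an explicit basal guild whose resources
are consumed preferentially by low-niche consumers (herbivores and
detritivores; attachment probability 0.05 + 0.75(1 − η)² for a consumer
at niche position η). The resulting webs have mean trophic level near
2.4, degree declining in trophic level, and bottom-up-dominated asymmetry
graphs — the regime observed in real model collections.

Collection defaults, chosen once as representative of a filtered
collection of larger mass-balance models and then frozen: 34 webs, 55–90
compartments, consumer connectance uniform on (0.05, 0.12), basal
fraction uniform on (0.1, 0.3). Attributes emulate mass-balance outputs:
biomass lognormal (sdlog 1) with median decaying geometrically in trophic
level (median at TL equals 100 × 0.1^TL−1^ mass-per-area units, i.e. two
orders of magnitude per level — a strong biomass pyramid), ecotrophic
efficiency uniform on [0, 1]. All draws are seed-deterministic with no
hidden entropy.

What the generator does *not* emulate: flow magnitudes (diets are
binarized anyway), multi-stanza group structure, sampling error in the
underlying models, and the ecological covariance between ecosystem type
and topology. Passing tests on synthetic collections therefore shows that
the pipeline is correct and that the bottom-up/biomass association
follows mechanistically from a biomass pyramid over a broad base — not
that any particular empirical collection will show a given τ.

## Verification strategy

The TI computation is cross-checked against an independent brute-force
oracle that enumerates every walk explicitly and sums effect products
(agreement to 1e-12 on hundreds of random graphs up to 8 nodes); worked
values on the 3-chain and star are asserted exactly (TI³ values 1/3 and
2/3; star asymmetry 4/9). FDR control is verified by simulating 1000
global-null indicator tables (21 variables × 34 rows) and checking the
BH discovery rate against its binomial band. The directional
biomass/bottom-up property is asserted as a sign test across seeded
collections of 34 webs. Problem sizes in the test-suite (webs of 15–90
nodes, collections of up to 34) were chosen so the full suite exercises
every code path at the study's scale.

## Known limitations

* The method is purely topological: where flow data exist, a
  flow-weighted variant would use strictly more information; this package
  deliberately binarizes.
* Normalization constants differ between implementations; compare only
  scale-free outputs (link sets, orientations, counts) across tools.
* Prey-averaged trophic levels are unweighted; a diet-weighted average is
  a documented extension point but not implemented.
* The asymmetry graph's link count is budget-driven, so indicators such
  as Lag correlate with N by construction; interpret correlations with
  size-dependent indicators accordingly.
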