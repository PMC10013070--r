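# cfnsim — evolutionary assembly of microbial cross-feeding networks

Microbial communities rework their own chemical environment: consumers take
up organic compounds and excrete transformed metabolites, which become
resources for others. `cfnsim` simulates how such **cross-feeding networks
(CFNs)** assemble by evolution from a single founding consumer in a static
environment, for researchers studying microbial diversity, consumer–
resource models and evolving ecological networks.

The model is a bipartite flow network. Consumer *i* has affinities
*u*<sub>*i*,*j*</sub> (budget Σ<sub>*j*</sub> *u*<sub>*i*,*j*</sub> = ū) and
release proportions *ϱ*<sub>*j*,*i*</sub> (Σ<sub>*j*</sub>
*ϱ*<sub>*j*,*i*</sub> = 1). Resource throughput is split by affinity,
σ<sub>*i*,*j*</sub> = *u*<sub>*i*,*j*</sub>/Σ<sub>*k*</sub>
*u*<sub>*k*,*j*</sub>; a fraction η of consumed flow is re-released (the
rest is respired), so the stationary resource flows solve the linear
balance

> **F** = **s** + η *T* **F**,  *T* = *R S*,  i.e.  **F** = (Id − η*T*)⁻¹ **s** = Σ<sub>*n*</sub> η<sup>*n*</sup>*T*<sup>*n*</sup> **s**,

with supply **s** and consumer uptakes *J*<sub>*i*</sub> =
η Σ<sub>*j*</sub> σ<sub>*i*,*j*</sub>*F*<sub>*j*</sub>. Evolution proceeds
in discrete steps: a flow-weighted random resident spawns a mutated
descendant (per-entry noise ±α plus an equalizing drift, occasional
substitution of an uptake resource or release product, the latter drawn
from a global compound pool); then consumers with uptake below the
threshold μ are removed one at a time, lowest first with flows recomputed,
until the community is stable. Flow into produced-but-unconsumed compounds
is the accumulation flow *A*, which bounds the sustainable richness:
*N* ≤ ⌊η(s̄ − *A*)/(μ(1 − η))⌋.

On top of the simulator the package provides the community observables of
the analysis — similarity-sensitive (order-2) diversity, evolutionary
potential ΔJ, effective richness, Pielou and uptake evenness, displacement
classification (competitive vs cascade), turnover, degree/flow statistics,
Blackman smoothing — plus dynamic similarity clustering with lineage
tracking, parameter sweeps, and text-format exports (CSV, TSV edge lists,
GraphML, Newick, JSON state dumps).

## A worked example

```r
library(cfnsim)

params <- cfn_params(n_steps = 4000, seed = 5, snapshot_every = 250)
sim <- cfn_simulate(params)
summary(sim)
```

```
Window [2001, 4000] of the evolutionary CFN simulation
  consumer richness N  = 169.2 (sd 10.6), bound N_max = 189 (A = 0: 233)
  resource richness M  = 62.9 (sd 6.0)
  accumulation flow A  = 0.1865, surplus flow = 0.2065
  establishment rate   = 0.84, extinction rate = 0.83 (cascade 0.13)
  diversity D          = 2.27 (genotypic), 2.44 (functional)
  evolutionary potential = 0.01059
```

Starting from one random founder on a single supplied compound, the
community has grown to ~170 coexisting consumers on ~63 compounds — all but
one of which the community created itself. The richness sits close to the
accumulation-corrected capacity bound (189), far below the structure-free
bound of 233: about 19% of the supplied flow is stuck in compounds nobody
has yet evolved to eat. Establishments and extinctions balance at ~0.84 per
step — the community composition keeps turning over even though the
environment is static — and the order-2 diversity of ~2.3 "effective
species" reflects one large cluster of supply specialists beside smaller
generalist groups.

```r
fl <- sim$final$flow
evenness(fl$J)                              # Pielou evenness of consumer flows
#> [1] 0.9982535
affinity_flow_slope(sim$snapshots[sim$snapshot_steps >= 2000])$slope
#> [1] 1.031016
```

Consumer flows are almost perfectly even (every survivor hovers just above
the subsistence threshold), and the community's total affinity for a
compound scales linearly with that compound's flow (log–log slope ≈ 1):
collective uptake effort tracks availability.

Cluster lineages, sweeps, exports:

```r
sim2 <- cfn_simulate(cfn_params(n_steps = 2000, seed = 1), cluster_from = 1500)
cluster_statistics(sim2$clusters)$turnover  # consumer vs cluster turnover

run_sweep("eta", c(0.3, 0.5, 0.7, 0.8), n_steps = 2000, seeds = 1:2)$summary

flow_edges(sim$final$flow, "network.tsv")   # or flow_graphml(), save_cfn_state()
```

A thin command-line front end with `run`, `sweep`, `analyze` and
`fixtures` verbs lives in `inst/cli/cfn.R`.

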