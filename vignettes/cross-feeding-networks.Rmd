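---
title: "Evolving cross-feeding networks: model, methods and design choices"
author: "cfnsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving cross-feeding networks: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfnsim)
```

## The model

`cfnsim` simulates the evolutionary assembly of microbial cross-feeding
networks (CFNs). A CFN is a directed bipartite network of **resources**
(organic compounds) and **consumers** (microbial populations): links from
resources to consumers are uptake, links from consumers to resources are
release of transformed metabolites. The model tracks only stationary mass
*flow*, not concentrations or population densities — a consumer is present
or absent, and persistence is decided by comparing its stationary uptake
flow against a subsistence threshold.

### Stationary flow

Each consumer $i$ carries an affinity vector $u_{i,j} \ge 0$ over resources
(with fixed budget $\sum_j u_{i,j} = \bar u$) and a release composition
$\varrho_{j,i} \ge 0$ (with $\sum_j \varrho_{j,i} = 1$). Consumers split
each resource's throughput in proportion to their affinities,

$$\sigma_{i,j} = \frac{u_{i,j}}{\sum_k u_{k,j}},$$

with $\sigma_{\cdot,j} \equiv 0$ when nobody consumes resource $j$. A
fraction $\eta$ of consumed flow is retained in organic form and
re-released according to $\varrho$; $1 - \eta$ is respired and leaves the
system. Writing $S = (\sigma_{i,j})$ and $R = (\varrho_{j,i})$, one pass of
flow through the community projects onto the resource space as the
transformation matrix $T = R S$, and the stationary resource flows solve

$$F = s + \eta T F \quad\Longleftrightarrow\quad F = (\mathrm{Id} - \eta T)^{-1} s
  = \sum_{n \ge 0} \eta^n T^n s,$$

where $s$ is the external supply. Because $T$ redistributes flow without
creating it ($\lVert Tv \rVert_1 \le \lVert v \rVert_1$ for $v \ge 0$) and
$0 < \eta < 1$, the inverse always exists. Consumer uptake is
$J_i = \eta \sum_j \sigma_{i,j} F_j$.

Resources that are produced (or supplied) but currently have no consumer
are sinks; their summed inflow is the **accumulation flow** $A$. Exact
identities link the totals: $\bar F = (\bar s - \eta A)/(1-\eta)$,
$\bar J = \eta(\bar F - A)$, and since every persistent consumer needs
$J_i \ge \mu$, the community can never exceed
$N_{max} = \lfloor \eta (\bar s - A) / (\mu (1-\eta)) \rfloor$ consumers.
These identities are verified to $10^{-9}$ relative error on randomly
generated communities in the test suite, and the direct solve is checked
against the truncated geometric series.

### The evolutionary step

Each discrete step introduces one candidate consumer and lets the
community relax:

1. **Ancestor choice.** A resident is drawn with probability proportional
   to its uptake flow $J_a$.
2. **Gradual mutation.** Every positive trait entry $x$ of the ancestor is
   perturbed to $\max(0,\, x (1 + \epsilon_1 + \epsilon_2))$ with
   $\epsilon_1 \sim U(-\alpha, \alpha)$ per entry and an equalizing drift
   $\epsilon_2 \sim U(0, \alpha/n_u)$ (affinities) or
   $U(0, \alpha/n_\varrho)$ (release) on positive entries only; totals are
   renormalized afterwards. The drift counteracts the slow concentration of
   weight onto a single entry that symmetric multiplicative noise plus
   normalization would otherwise produce.
3. **Qualitative substitution.** With probability $p_u$ one utilized
   resource is swapped for a resource the consumer does not utilize (the
   full affinity moves with it), and with probability $p_\varrho$ one
   released product is swapped for a new product drawn from the global
   compound pool $\mathcal G$ — this is the only mechanism that introduces
   genuinely new resources into the system.
4. **Insertion and extinction loop.** The candidate joins the community,
   flows are recomputed, and while any consumer has $J_i < \mu$ the one
   with the lowest uptake is removed and the flows are recomputed again.
   The candidate takes part like any resident; it "establishes" when it is
   still present once all survivors clear the threshold.

Support sizes $n_u$ and $n_\varrho$ are invariant along lineages: mutation
perturbs magnitudes only and substitution moves whole entries.

## Parameters

| name | meaning | default | units / range |
|------|---------|---------|----------------|
| `eta` | recycling (non-respired) fraction | 0.7 | (0, 1) |
| `mu` | extinction threshold on uptake flow | 0.01 | flow units |
| `alpha` | mutation amplitude | 0.2 | $\ge 0$ |
| `p_u`, `p_rho` | substitution probabilities | 0.2 | [0, 1] |
| `n_u`, `n_rho` | uptake / release diversity | 3 | positive integers |
| `pool_size` | global compound pool size $G$ | 250 | integer |
| `supply` | external supply rates | 1.0 at resource 1 | flow units |
| `u_bar` | affinity budget per consumer | 1.0 | arbitrary |
| `theta` | cluster diameter threshold | 0.4 | (0, 1] |
| `w_u`, `w_rho` | dissimilarity weights | 1.0, 0.2 | $\ge 0$ |

The defaults constitute the reference configuration studied throughout the
package: a single supplied compound entering at unit rate into an otherwise
closed system. `u_bar` is observationally neutral (uptake shares are
invariant under common rescaling of all affinities) and is exposed only for
completeness. With the default `eta`, `mu` and supply, the structure-free
capacity bound is `capacity(1, 0.7, 0.01)$N_max` = 233 consumers.

## Observables

* **Evolutionary potential.** The marginal uptake gain from affinity on
  resource $j$ is $\mathrm{d}J_i/\mathrm{d}u_{i,j} = \eta (1 -
  \sigma_{i,j}) F_j / U_j$ with $U_j = \sum_n u_{n,j}$; the potential
  $\Delta J_i$ is the spread of this gain over the consumer's utilized
  resources. The max/min is taken over utilized entries only, because the
  affinity budget constrains reallocation to the existing support; a
  utilized resource with no flow contributes zero gain. The community mean
  of $\Delta J_i$ measures how far the ensemble is from an uninvadable
  state; it stays bounded away from zero in all our simulations —
  co-evolution never stops.
* **Similarity-sensitive diversity.** Pairwise cosine similarities
  $z_{i,k}$ of affinity vectors (genotypic) or of per-link uptake flows
  (functional) give the ordinarity $\bar z_i = \sum_k z_{i,k}$ and an
  order-2 diversity. We implement $D = N^2 / \sum_{i,k} z_{i,k}$, which is
  1 for a community of identical consumers and $N$ for pairwise orthogonal
  ones. An alternative normalization $D = N / \sum_i \bar z_i$ circulates
  for this index, but it is bounded above by 1 for any community and can
  therefore not be compared across community sizes; it is available behind
  the `literal` flag and is deliberately not the default. The two readings
  are never averaged or mixed.
* **Effective richness and evenness.** The exponential Shannon entropy of a
  consumer's relative affinities (or inflows) interpolates between 1
  (specialist) and $n_u$ (full generalist). Evenness divides the Shannon
  entropy by $\log$(count) (Pielou, for ensembles) or by $\log n_u$ (for
  per-consumer uptake profiles); a singleton is defined perfectly even.
* **Displacement statistics.** Each resident extinction in a step is
  classified *competitive* when the victim shares at least one utilized
  resource with the incoming consumer and *cascade* otherwise (indirect
  displacement through the altered flow pattern). Establishment success is
  reported conditional on the pre-step community size; bins with fewer than
  ten trials are dropped by default because success rates over a handful of
  trials are noise. Cascade sizes (extinctions per step) are summarized by
  a least-squares fit of log relative frequency against size.
* **Turnover.** $|A \Delta B| / (|A| + |B|)$ between two sets of consumer
  or cluster ids; 0 for identical, 1 for disjoint sets.
* **Smoothing.** Displacement-rate series are smoothed with a unit-sum
  Blackman window (coefficients 0.42, 0.5, 0.08); near the series edges the
  kernel is truncated and renormalized so that constants are preserved
  exactly.

## Dynamic clustering

Consumers are grouped into taxon-like units using the genotypic
dissimilarity

$$d_{i,k} = \frac{w_u \sum_j |u_{i,j} - u_{k,j}| +
  w_\varrho \sum_j |\varrho_{j,i} - \varrho_{j,k}|}{2 w_u \bar u + 2 w_\varrho}
  \in [0, 1].$$

An initial complete-linkage clustering (ignoring ancestry) is cut at the
diameter threshold $\vartheta$; afterwards each established consumer joins
its ancestor's cluster. If the extended cluster's diameter exceeds
$\vartheta$, its membership is re-clustered (complete linkage, again cut at
$\vartheta$) and the part containing the newcomer receives a fresh cluster
id while the largest remaining part keeps the old id — only the affected
cluster is touched, the rest of the partition is left alone. Because
complete-linkage merge heights are subtree diameters, cutting at
$\vartheta$ guarantees every part's diameter is at most $\vartheta$; the
cut produces exactly two parts in all but degenerate geometries, in which
case each extra part also receives a fresh id. Removals never trigger
splits; a cluster closes when its last member dies, and its lifespan is the
number of steps between first appearance and that closure.

For clusters extended by a single drifted offspring — the only situation in
which splits occur — the complete-linkage top cut coincides with the
minimal-maximal-diameter bipartition found by brute force over all
2-partitions (verified exhaustively for up to eight members in the test
suite). For arbitrary unstructured point sets the greedy cut need not be
optimal; this is a property of the split situation, not of complete linkage
in general.

## Numerical choices

* The stationary solve uses a dense LU factorization on the
  present-resource subspace (typically below 10² resources); the residual
  is checked against an absolute tolerance of $10^{-10}$ and the geometric
  series is kept as an independent test oracle only.
* Flows below $10^{-14}$ are clamped to zero so accumulation sums are free
  of sign noise.
* Extinction ties (exactly equal minimal uptake, which occurs for clonal
  lineages at `alpha = 0`) are broken towards the youngest consumer, making
  runs deterministic.
* All randomness flows through R's global generator, seeded once per run;
  the draw order within a step is fixed (ancestor; affinity noise and
  drift; release noise and drift; uptake substitution coin/index/target;
  release substitution coin/index/target), so a given seed reproduces a
  run bit for bit.
* Degenerate inputs fail loudly: empty supply, non-normalizable traits,
  all-zero weight vectors and turnover of two empty sets are errors, not
  silent conventions.

## Design choices where the rules leave room

* **Uptake substitution source pool.** The target of an uptake substitution
  is drawn uniformly from the resources currently present in the system
  (`uptake_substitution_pool = "present"`), because a new uptake capability
  for a compound that does not exist carries zero flow and cannot aid
  establishment. The alternative — drawing from the whole global pool — is
  available as a configuration switch. The choice matters: with the global
  pool most new capabilities point at absent compounds, so communities stay
  smaller, poorer in resources and more concentrated on the supplied
  compound. Under the default, simulated communities
  reproduce the characteristic structure of evolved CFNs (a large
  supply-specialist cluster beside overlapping generalists, resource
  richness near 65 with the default parameters); the stationary *consumer*
  richness level is the quantity most sensitive to this choice.
* **Equalizing drift granularity.** The drifts are drawn independently per
  positive entry rather than once per offspring; a single shared value
  would still be well-defined but would only damp, not reshape, the
  relative noise between entries.
* **Founder.** The founding consumer utilizes every supplied resource
  (remaining uptake slots drawn uniformly from the pool), with magnitudes
  drawn uniformly and normalized; its release targets are drawn uniformly
  from the whole pool, so it typically seeds the system with compounds
  nobody consumes yet.
* **Resource presence.** A resource is "present" when supplied or currently
  produced. A resource whose producers all died leaves the system even if
  consumers retain affinity for it (those affinities simply earn nothing
  until a producer re-evolves).

## What the simulator emulates — and what it does not

All study data are produced by the simulator itself; there is no external
input. The generator emulates a *static* environment (constant supply into
one compound) so that all observed turnover is internally generated. It
does **not** model population densities, concentration-dependent uptake,
abiotic degradation of compounds, lateral gene transfer, or any biochemical
structure on the compound pool (no stoichiometry, no energetic ordering —
all compounds are equivalent a priori). Consequently, passing tests show
that the *mechanism* (resource diversification by release drift, niche
creation, threshold extinction) self-organizes into diverse, persistently
turning-over communities; they do not show that any particular natural
community follows these rules, and quantities tied to absolute flow scales
(e.g. $\mu$, $\bar s$) have no physical units attached.

A further honest caveat: reciprocal cross-feeding pairs are not stabilized
by the model — any consumer with a superior affinity combination can
displace one partner regardless of the products the pair exchanges — so
syntrophic loops observed in nature are outside its scope.

## Problem sizes used by the tests and the acceptance script

Full study-scale runs use $10^5$ steps with windows over the second half.
The package's own test suite and the bundled acceptance script use
shortened versions of the same conditions, chosen so that the statistics
they check are already stationary: the bundled acceptance analysis uses
three seeds of 3×10⁴ steps with the window [1.5×10⁴, 3×10⁴] and snapshots
every 250 steps (the consumer-richness plateau is reached before step
5×10³, the resource richness before step 10⁴); the test suite uses three
seeds of 2.4×10⁴ steps windowed over the second half, comparative runs of
0.8–1.2×10⁴ steps for the uptake/release-diversity contrasts (the
release-diverse community assembles more slowly and gets the longer runs),
and trend sweeps of 2 seeds × 6×10³ steps per parameter value. These sizes
are stated here as the package's reference configuration for its own
analyses; all of them are arguments, not constants.

## Known limitations

* The stationary consumer richness under the reference configuration
  (≈170, as computed by the acceptance analysis) depends visibly on the
  uptake-substitution pool choice discussed above; structural observables
  (resource richness, diversity, evenness, slope of affinity against flow)
  are far less sensitive to it.
* The extinction loop recomputes a dense solve after every removal; for
  communities far beyond a few hundred consumers a sparse or low-rank
  update would be needed.
* Cluster tracking stores pairwise dissimilarities of the resident
  community and is meant for windows of 10³–10⁴ steps, not whole runs.
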