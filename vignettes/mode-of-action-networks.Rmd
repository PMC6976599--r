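---
title: "Inferring small-molecule modes of action from multi-omics network optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring small-molecule modes of action from multi-omics network optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moanet)
```

## The problem

A compound that rescues a disease phenotype often does so through cellular
processes far removed from its nominal binding target.  Individually, each
omics readout of a treated cell line — differential transcripts, proteins,
phosphosites, untargeted metabolite peaks — yields hundreds of significant
features and no mechanism.  `moanet` implements the interpretable
network-optimization strategy for this situation: place the differential
evidence as *prizes* on a heterogeneous molecular interactome, extract the
cheapest subnetwork that collects enough prize mass to pay for its own
edges (a Prize-Collecting Steiner Forest, PCSF), harden the subnetwork by
randomization, and read the result through pathway enrichment.  The
surviving, connected neighborhoods are candidate modes of action.

## The optimization model

Given an undirected interactome with edge costs $c(e) > 0$, node prizes
$p(v) \ge 0$ and node degrees $\deg(v)$, the method minimizes over forests
$F$ (acyclic subgraphs of the interactome):

$$
\mathrm{Obj}(F) \;=\; \beta \sum_{v \notin F} p(v)
  \;+\; \sum_{e \in F} c(e)
  \;+\; \omega\, \kappa(F)
  \;+\; \mu \sum_{v \in F} \deg(v)
$$

where $\kappa(F)$ is the number of trees.  Forfeiting a prized node costs
$\beta\,p(v)$; including an edge costs $c(e)$; opening a tree costs
$\omega$ (realized as the cost of an edge from a virtual root to a prized
node); and $\mu$ penalizes promiscuous hubs in proportion to their degree
in the *full* interactome, which is equivalent to reducing each node's
effective prize to $\beta\,p(v) - \mu \deg(v)$.

### Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `beta`  | 1     | Prize scale (dimensionless). With prizes = \|log2 fold change\| and edge costs in $[0,1]$, 1 balances a typical differential feature (prize $\approx 2$) against a few confident edges. |
| `omega` | 1     | Per-tree penalty, in cost units. Chosen so a module of 3–5 prized nodes joined by confident edges (costs $\approx 0.1$) is collected as one tree, while an isolated weak feature (prize below 1) cannot open a tree by itself. |
| `mu`    | 0.005 | Hub penalty per unit degree. Small by design: it tilts ties away from hubs without vetoing biologically real hub usage. |
| `sigma` | 0.1   | SD of the additive zero-mean Gaussian edge-cost noise used for robustness reruns; about 20–40% of a typical edge cost. |
| `n_runs`| 100   | Randomized reruns per arm (robustness and specificity). |
| `min_robustness`, `min_specificity` | 0.40 | Inclusive node-retention thresholds applied to the unperturbed solution. |
| `ppm_tol` | 10 ppm | Peak–metabolite matching tolerance, typical for Orbitrap-class untargeted data. |
| `alpha` | 0.05  | BH-adjusted significance threshold, applied strictly (`p_adj < alpha`) so the boundary case is deterministic. |

Edge confidences in $[0,1]$ become costs by $c = \max(1 -
\text{confidence}, \epsilon)$ with $\epsilon = 10^{-6}$: the simplest
monotone mapping that keeps costs strictly positive, as the solver
requires.  When layers disagree on a duplicated edge, the minimum cost
(most confident evidence) wins.

## The solver

The PCSF instance is solved by a deterministic heuristic written for this
package (`src/pcsf_solver.cpp`):

1. **Growth** — a virtual root is joined to every positive-net-prize node
   by an edge of cost $\omega$; missing prized nodes are attached to the
   current solution along shortest paths (Takahashi–Matsuyama), so a far
   node enters either through the network or as a new tree, whichever is
   cheaper.
2. **Optimal pruning per tree** — strong pruning evaluated from every
   candidate root of each component; a component whose best pruned net
   worth does not exceed $\omega$ is dropped entirely.  This lets a
   profitable node detach from a losing chain, which single-root pruning
   cannot do.
3. **Local search** — exact single-node removals and Steiner-node
   additions, each scored by re-deriving the optimal edge set for the
   candidate node set (a spanning forest that takes an edge only when it
   is cheaper than opening a tree — a greedy matroid argument makes that
   edge choice exact for a fixed node set).  On instances up to 150 nodes
   the neighborhood is widened to adjacent-pair removals and
   remove-one/add-one swaps; beyond that the cheaper first-improvement
   neighborhood keeps randomization studies fast.
4. **Deterministic restarts** — marginal routing decisions can tip either
   way, so the heuristic reruns eight times under small deterministic
   cost jitters (an internal xorshift stream, independent of R's RNG) and
   the candidate scoring best under the *true* costs is kept.

Ties are broken everywhere by lexicographic node id (through a canonical
sorted node indexing), so identical inputs produce byte-identical outputs.
The exact reference `brute_force_pcsf()` enumerates all node subsets (with
the per-subset optimal forest) for instances up to 12 nodes; the test
suite requires the heuristic to stay within 5% of the enumerated optimum
on 200 random instances and match it on at least 90% — in practice it
matches on essentially all of them.

## Untargeted peaks as hidden nodes

Untargeted m/z peaks are never hard-assigned to metabolites.
`match_peaks()` emits one near-zero-cost edge per (peak, metabolite,
adduct) candidate within the ppm tolerance, and the optimizer decides
which candidates participate: a peak whose candidate metabolite sits in a
prize-dense neighborhood is resolved there, the rest stay unconnected.
The default adduct set ([M+H]+, [M+Na]+, [M+NH4]+; [M−H]−, [M+Cl]−) is a
minimal common choice and fully configurable; the ppm error is computed
against the theoretical m/z, the standard convention.

## Robustness and specificity filtering

The unperturbed solution is the base network.  Two randomization arms rerun
the full solve `n_runs` times each:

* **Robustness** — edge costs perturbed by $\mathcal N(0, \sigma^2)$,
  clamped at $\epsilon$.  A node's robustness is the fraction of noisy
  solutions containing it.
* **Specificity** — the prize *values* are kept but reassigned to random
  nodes, sampled without replacement and degree-matched within decile bins
  (so hubs are compared against hubs; otherwise every hub would trivially
  look non-specific).  A node's specificity is one minus its frequency in
  these random-input solutions, so that higher is better for both scores
  and the published "at least 40%" rule reads as an inclusive `>=` on
  both.

Nodes of the base solution failing either threshold are removed; the
induced subgraph may split into more trees, which are recounted.

What this filter does and does not do deserves care.  It removes hub
connectors (low specificity) and fragile multi-hop attachments (low
robustness).  It does **not** remove a spurious prized node that attaches
to the solution with a clearly positive margin: under symmetric zero-mean
cost noise, such a node stays in more than half of the noisy reruns, and a
uniformly placed low-degree node almost never appears in degree-matched
random-prize runs, so both of its scores sit comfortably above 0.40.  The
decoy-rejection benchmark (`recovery_benchmark(decoy_count = ...)`)
measures exactly this and reports low removal rates; treat the filter as a
stabilizer of the solution's topology, not as a false-positive control on
individual prizes — false-positive control belongs to the upstream BH
threshold.

## The synthetic benchmark and what it shows

`generate_interactome()` grows a preferential-attachment graph
(heavy-tailed degrees, the regime specificity filtering must survive;
exactly $(n - m)\,m$ edges, connected by construction), with uniform
confidences in $(0.5, 1)$.  `plant_modules()` grows node-disjoint
connected modules by seeded breadth-first expansion — the ground truth.
`generate_omics()` gives module members $|\log_2\mathrm{FC}| \sim
\mathcal N^+(2, 0.5)$ with raw p-values in $(10^{-6}, 10^{-3})$, and null
features $\log_2\mathrm{FC} \sim \mathcal N(0, 0.2)$ with uniform
p-values, so BH behavior is analytically checkable.  `generate_peaks()`
emits one peak per planted metabolite through a random mode-consistent
adduct with $\mathcal N(0, \text{ppm}^2)$ relative mass error, plus decoy
peaks placed at least five tolerances away from every database entry.
Decoy *prizes* in the filtering benchmark are drawn from the null effect
model — they represent false-positive differential features, the
adversary the filter is asked about.

The standard benchmark sizes (300-node interactome, one 12-node module,
100 null features, 20 seeds for recovery, 10 seeds with 50 reruns per arm
for the decoy study, 200 solver-oracle instances) were chosen as the
smallest instances in which hubs, Steiner nodes, decoys and module
structure all occur, so the whole suite and the acceptance script rerun in
a few minutes.

Passing these benchmarks shows the machinery is correct and calibrated on
data whose generative process matches the model's assumptions.  Real data
differ in ways the generator deliberately omits: correlated features and
batch structure, identifier mapping across omics layers, database
incompleteness and mass-coincident metabolites, non-uniform null
p-values, and interactome annotation bias (well-studied proteins have
more edges).  Recovery rates here are an upper bound on what to expect in
practice.

## Design decisions on points the method leaves open

* Genes do not receive prizes directly; transcription is represented by
  predicted TF regulators (prize $-\log_{10} p_\mathrm{adj}$, capped at
  10) while proteins, phosphosites, peaks and TFs carry measured prizes.
  This is configurable by simply including gene features in the prize
  table.
* Interactome confidences are used unthresholded; any thresholding is the
  caller's preprocessing.
* Phosphosite-to-parent-protein containment edges get confidence 1 (cost
  $\epsilon$): containment is not probabilistic evidence.
* PWM scanning adds a 0.01 pseudocount before log-odds (avoids
  $-\infty$), skips windows containing N, scans both strands, and scores
  in bits.  Promoters default to TSS $\pm$ 2 kb windows supplied as BED;
  the motif stage is illustrative — no motif database or threshold is
  canonical here.
* Enrichment uses the plain hypergeometric upper tail over a universe of
  protein, metabolite and TF nodes, BH-corrected across the collection.
* The interface is the R API plus `run_pipeline()` driven by a single
  YAML configuration; every stage is independently callable.

## Known limitations

The solver is a heuristic: optimality is verified against enumeration only
up to 12 nodes, and the exhaustive local-search neighborhood narrows above
150 nodes.  Identifier unification across omics layers is delegated to a
user-supplied mapping table.  The specificity arm assumes the degree
distribution is informative about "attractiveness" to arbitrary prizes;
graphs with strong community structure may need stratified sampling
instead.  Peak matching ignores retention time, isotope envelopes and MS2
evidence on purpose — those belong upstream of this package.
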