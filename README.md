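# netattack

Quantitative scoring of multi-target drug effects on disease networks
by simulated node-deletion attacks.

## The problem

Multi-target agents — herbal formulas, polypharmacology drugs, broad
kinase inhibitors — cannot be ranked by affinity to a single protein.
One alternative is topological: build the disease's protein–protein
interaction (PPI) network, delete the drug's target nodes, and measure
how much the deletion destabilizes the network. An agent that removes
load-bearing nodes (hubs, central connectors) damages the network far
more than one that removes peripheral nodes of equal number.
`netattack` implements this attack model end to end for disease
networks and for per-pathological-process functional subnetworks
(oxidative stress, inflammation, angiogenesis, ...), so agents can be
ranked both globally and per process.

## The statistic

For a network *G* with *n* nodes, the robustness of the topology is
summarized by four whole-graph statistics:

- **AD** (average degree): `AD = Σ_v deg(v) / n`
- **ASPL** (average shortest path length):
  `ASPL = Σ_{s≠t} d(s,t) / (n(n−1))`, averaged over reachable ordered
  pairs when the graph is disconnected
- **DC** (degree centralization):
  `DC = Σ_v [deg(v*) − deg(v)] / ((n−1)(n−2))`, `v*` the
  maximum-degree node
- **CC** (closeness centralization):
  `CC = Σ_v [clo(v#) − clo(v)] / ((n−1)(n−2)/(2n−3))`, `v#` the
  maximum-closeness node, with Wasserman–Faust component-scaled
  closeness on disconnected graphs

A drug attack deletes the drug's target nodes; each statistic's
**robustness index** is its relative change

    RI = (X_after − X_before) / X_before.

Because the raw RI depends on how many nodes were deleted, each RI is
normalized by a permutation null: the *same* attack is replayed on 100
random networks with identical node labels and edge count (uniform
G(n, m)), and

    normalized RI = (RI_real − mean(RI_random)) / sd(RI_random).

The four z-scores combine into the composite

    Total Score = zASPL − zAD − zDC − zCC,

signed so that a larger total means a more destabilizing (hence
potentially more effective) agent. Agents are then ranked by the
percentage of a reference panel (e.g. FDA-approved drugs) they
strictly exceed.

## Worked example

All inputs here are synthetic: a 120-gene planted-partition disease
network with three functional modules, attacked by a drug whose 12
targets are hubs of the oxidative-stress module.

```r
library(netattack)

spec <- synthetic_spec(n_genes = 120, n_modules = 3, p_within = 0.25,
                       p_between = 0.03, seed = 42)
sim <- generate_disease_network(spec)
drug <- generate_drug(
  synthetic_drug_spec("hub_drug", n_targets = 12,
                      focus_module = "oxidative_stress",
                      specificity = 1, hub_bias = 2, seed = 7),
  sim$network, sim$assignments)
fit <- attack_score(sim$network, drug, n_reps = 100, seed = 1,
                    drug_id = "hub_drug", network_id = "synthetic_disease")
summary(fit)
```

```
Attack score summary [hub_drug]
  targets hit: 12
 metric   before    after       ri null_mean  null_sd       z
     ad 11.71667 10.14815 -0.13387  -0.10273 0.016009 -1.9449
   aspl  2.27969  2.35808  0.03439   0.01760 0.006889  2.4365
     dc  0.07933  0.06524 -0.17759   0.05163 0.135504 -1.6917
     cc  0.15137  0.15400  0.01736   0.05605 0.115411 -0.3352
  total score = 6.408
```

Reading the table: deleting the 12 hub targets drops the average
degree by 13.4%, while deleting the same 12 labels from random
networks of the same size only drops it by 10.3% on average — the
attack removes far more connectivity than a random deletion of equal
size (z(AD) = −1.94). Path lengths stretch more than random
(z(ASPL) = +2.44), and the network decentralizes (z(DC) = −1.69).
The composite total score 6.41 — strongly positive — says the drug's
targets sit at structurally load-bearing positions of this disease
network.

The same pipeline runs per functional subnetwork
(`build_subnetworks()` + `score_subnetworks()`), from TSV inputs via
`run_pipeline()`, or from a shell via the thin CLI in
`inst/cli/netattack`.

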