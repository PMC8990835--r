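---
title: "The drug-attack model of disease-network robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The drug-attack model of disease-network robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`netattack` treats a drug as an attack on a disease network: every
network node that is a drug target is deleted together with its
incident edges, and the damage is read off four whole-graph
statistics — average degree (AD), average shortest path length
(ASPL), degree centralization (DC) and closeness centralization (CC).
Each statistic's relative change, the robustness index
`RI = (after − before)/before`, is normalized against the same attack
replayed on random networks with the same node labels and edge count,
and the four z-scores combine into
`Total Score = z_ASPL − z_AD − z_DC − z_CC`. The signs encode the
direction of destabilization: breaking a network stretches its
surviving paths (ASPL up) and strips degree and centralization (AD,
DC, CC down), so all four terms contribute positively to the total
when the attack is damaging.

The model's assumptions are worth stating plainly:

- interactions are unweighted and undirected; PPI confidence is used
  only as an inclusion cutoff, not as an edge weight;
- a target is either deleted or untouched — no partial knockdown,
  no dose dependence, no sequential attack ordering;
- the null keeps node and edge counts but nothing else (no degree
  sequence preservation), so the z-scores measure how non-random the
  *positions* of the attacked labels are, which is exactly the signal
  of interest but also means dense hub structure in the real network
  inflates every drug's scores relative to a G(n, m) baseline.

## Network assembly

Gene–disease association (GDA) tables are filtered at score
strictly greater than 0.01 and PPI tables at confidence strictly
greater than 0.4 — strict inequalities, matching the usual reading of
"more than"/"greater than" for these cutoffs. STRING-style confidence
columns on the 0–1000 scale are auto-detected (any value above 1) and
divided by 1000; symbols are uppercased, trimmed and stripped of
numeric species prefixes so STRING identifiers match gene symbols.
Genes with no surviving interaction are dropped at construction,
which is why a 685-gene association list can yield a 636-node
network. We deliberately retain *all* non-isolated nodes rather than
restricting to the largest connected component: the choice is
recorded in the graph's `conventions` attribute, and the
reachable-pair ASPL convention (below) makes every downstream
statistic well defined either way.

Functional subnetworks are induced subgraphs on each cluster's genes
(clusters come in as a plain gene→cluster table; genes may belong to
several clusters). An interaction occurring in more than
`max_occurrence = 4` subnetworks is deleted from every subnetwork.
The source wording ("deleted to form a new subnetwork") is ambiguous
between removing the edge from all subnetworks and collecting the
removed edges into an additional subnetwork; we remove from all —
that is what makes the subnetworks process-specific — and write the
pruned edges to a side file so the alternative reading stays
inspectable. Pruned edges are not scored by default.

## Numerical conventions

Attacks fragment networks, so the statistics need explicit
disconnected-graph conventions:

- **ASPL** averages over reachable ordered pairs only. The classical
  formula is undefined when any pair is unreachable; averaging over
  reachable pairs keeps the statistic finite after fragmentation. A
  graph with no edges has no reachable pair: the value is `NA` with a
  warning, and every downstream quantity propagates the flag rather
  than coercing it to 0 (0 is a meaningful robustness index).
- **Closeness** uses the Wasserman–Faust component-scaled form
  `clo(v) = ((n_C − 1)/(n − 1)) · ((n_C − 1)/Σ_{t∈C} d(v, t))`, which
  reduces to the classical `(n − 1)/Σ d` on connected graphs and
  gives isolated nodes closeness 0.
- **Centralizations** with `n < 3` have a vanishing denominator; both
  return 0 with a warning, so attacked subnetworks that shrink below
  3 nodes still produce a full profile instead of aborting a scoring
  matrix.
- The centralization formulas depend only on the *maximal* degree or
  closeness, so ties among maximal nodes need no tie-breaking.
- A robustness index whose before-attack value is 0 (e.g. DC of a
  complete graph) is undefined and reported as `NA` with a warning.
- The closeness-centralization formula is stated in its source with
  "clo(v)" glossed as a degree; that reading would duplicate the
  degree centralization, so it is treated as a typo for closeness.

## The permutation null

The null model is uniform G(n, m) on the same node label set — node
and edge counts are retained and the same drug attack replayed, which
requires the target labels to exist in the random graphs. The default
of `n_reps = 100` random networks per null follows standard practice
for this permutation test; it is configurable. Normalization uses the
sample standard deviation (n − 1): the null is itself an estimate from
finitely many draws. At 100 replicates the difference from the
population SD is below 1%, far inside Monte-Carlo noise.

Draws on which a metric is undefined (a fragmented random graph with
a zero before-value) are excluded from that metric's null vector and
counted, keeping the z-score estimable while making data loss
visible; fewer than two defined draws is an error naming the metric.

Determinism is by a counter scheme: replicate *i* of a null uses seed
`master + i`; cell *k* of a score matrix (column-major over
drugs × networks) uses master seed `seed + (k − 1)(n_reps + 1)`, so
any single cell can be reproduced in isolation from the manifest.
When a pipeline run scores both the disease network and the
subnetworks, the subnetwork matrix continues the counter where the
disease matrix stopped. All seeds stay well below 2³¹.

One worked example is carried as a fixed reference: applying the
total-score formula to the published normalized robustness indices of
the diabetic-retinopathy network (−6.77, 7.01, −0.16, −11.88)
gives 25.82, matching the published total 25.83 within the rounding
of two-decimal inputs. The analogous computation for the published
age-related-macular-degeneration values (−3.53, 4.64, −0.83, 0.5)
gives 8.50, which does *not* match the published 9.49; the formula is
applied as stated and the discrepancy left visible — the test suite
asserts it persists rather than silently matching.

Ranking against a reference panel uses strict inequality
("superior to"): the percentage of panel scores strictly below the
agent's score; ties do not count.

## The synthetic study system

Because the upstream databases behind any real instance (association
scores, PPI snapshots, target predictions, GO clusterings) are
versioned services rather than fixed deposits, validation runs on a
synthetic system with known ground truth.

The generator plants a partition: a stochastic block model with
`n_genes = 600` genes in 6 modules, within-module edge probability
0.12 and between-module probability 0.00624. Those defaults put the
expected edge count at 4500 for a ~600-node network — the scale of
the retinal-disease PPI networks this model is typically applied to
(average degree ≈ 15). Module labels use pathological-process names
(oxidative stress, inflammation, angiogenesis, blood coagulation,
extracellular matrix, neuron death). The generator writes exactly the
table dialects the readers consume, with decoy genes below the 0.01
association cutoff and decoy interactions below the 0.4 confidence
cutoff, so a round trip through the readers exercises the filters and
reproduces the planted graph.

Synthetic drugs sample `n_targets` targets without replacement, a
fraction `specificity` from a focus module and the rest from the
remaining genes, with sampling weight `deg(v)^hub_bias`. Synthetic
compound tables draw log-normal peak-area ratios rescaled to a fixed
total.

What the generator does **not** emulate: scale-free degree
distributions (blocks are locally Erdős–Rényi), edge confidence
correlated with topology, overlapping module membership, and
database-specific identifier noise. Passing tests therefore show the
pipeline recovers planted structure under clean modular conditions,
not that any particular real disease network will behave likewise.

## Validation choices and problem sizes

The test suite validates four layers, at sizes chosen to keep a full
run comfortably inside a normal development cycle:

- *Statistics*: 100 random graphs of up to 15 nodes against an
  independent plain-R Floyd–Warshall/direct-formula oracle at 1e−12,
  plus closed-form families (stars centralize to exactly 1,
  vertex-transitive graphs to exactly 0).
- *Null calibration*: when the "real" network is itself a G(n, m)
  draw (n = 60, m = 180), the normalized RI should be approximately
  standard normal; 200 experiments with 100-replicate nulls check
  empirical mean within ±0.25 and SD within [0.75, 1.3] per metric.
- *Ground-truth recovery*: on 50 planted-partition networks
  (600 genes, 6 modules), a drug whose 30 targets are hubs of one
  module must attain its maximal total score on that module's
  subnetwork in at least 95% of runs, while an unfocused drug shows
  no module preference beyond chance. The recovery drug is fully
  module-specific (`specificity = 1`): with partial specificity even
  a single stray hub hit in another module can dominate that column,
  because the total score measures positional non-randomness, not
  hit count — a known sensitivity of the score worth remembering
  when interpreting single-hit cells in real matrices.
- *Scale*: one full pipeline run at disease scale (~600 nodes, ~4500
  edges, 40 agents, 6 subnetworks, 100 permutations per cell) with a
  complete manifest, and byte-identical reruns under a fixed master
  seed.

## Compound aggregation

Peak area ratios (percent of total chromatographic area) proxy
compound content. A target's sum adds the ratio of every compound
hitting it; a process's sum adds each compound **once** even when it
hits several of the process's targets — content is a mass-like
quantity and double counting could exceed the total. The per-target
sums are left un-deduplicated, matching how per-target contributions
are usually quoted. The deduplication rule for process sums is not
fixed by any published computation we can check against (the printed
process totals rest on unpublished compound-level data), so the
once-per-process rule is this package's documented choice.

## Known limitations

- The G(n, m) null ignores degree structure; a configuration-model
  null would ask a sharper question ("are these targets special given
  the degree sequence?") but is out of scope here.
- Scores are comparable across drugs on one network; comparing raw
  totals across networks of very different size or density is not
  supported by the normalization.
- Cells where the attack hits nothing have zero-variance nulls and
  are reported as undefined, not 0 — consumers must treat empty cells
  as "no evidence", not "no effect".
- All edges are unit length; confidence-weighted or directed variants
  are out of scope.
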