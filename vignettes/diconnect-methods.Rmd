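---
title: "Scoring disease-disease connectivity on a PPI network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring disease-disease connectivity on a PPI network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given a focal disease with a known gene set (for example type 1 or type 2
diabetes), which other diseases are mechanistically connected to it? Gene
sets alone answer this only through direct overlap; a protein–protein
interaction (PPI) network lets two diseases be close even when their genes
are distinct, because the genes interact. `diconnect` scores the association
between a focal gene set $A$ and each disease gene set $S$ of a panel on an
undirected PPI network, ranks the panel, and attaches permutation-based
significance. All analyses run inside the network's largest connected
component, where hop distances are always defined.

## The four score families

**Closest distance (DIcd).** With $d(a,s)$ the hop distance,
$$d_c(A,S) = \frac{1}{|A|} \sum_{a \in A} \min_{s \in S} d(a,s).$$
Genes in $A \cap S$ contribute zero; smaller values mean a stronger
association. The symmetric counterpart $d_c(S,A)$ and the doubly normalized
pairwise mean $d_s(A,S)$ are also provided
(`closest_distance_SA()`, `shortest_distance()`).

**Overlap (DIoverlap).** The Jaccard coefficient
$|A \cap S| / |A \cup S|$.

**Cross-edge connectivity (DIconnectivity).** Nodes are partitioned into
pure-$A$, pure-$S$, overlap and other; edges between the two sets fall into
four categories — $H_1$ pure-$A$–pure-$S$, $H_2$ pure-$S$–overlap, $H_3$
pure-$A$–overlap, $H_4$ overlap–overlap — and the score is
$h_1 + h_2 + h_3 + 2 h_4$, overlap–overlap edges carrying weight 2. Edges
inside one set or touching unrelated genes are never counted: the score
measures *between*-set connectivity only.

**Enrichment reachability (DINet).** On each module (below), both mapped
sets seed random walks with restart (RWR); each walk ranks the module's
genes, and a running-sum statistic scores how early the *other* set's genes
appear: walking the ranked list, a hit adds $(N-G)/G$ and a non-hit
$-G/(N-G)$ ($N$ genes, $G$ hits), the score being the curve's peak. The two
passes combine as $ES_\beta = \beta\,ES_1 + (1-\beta)\,ES_2$ with
$\beta \in (0,1)$.

## Modules: MN, eMN, eDMN

Gene sets connecting two diseases tend to concentrate in a few biological
processes, so each family also runs on GO-BP-derived subnetworks. A
*modularized network* (MN) is the induced subgraph on a BP's genes (BP sets
of 30–500 genes are used). An *expanded MN* (eMN) grows the MN by one RWR
seeded with all its genes, adding top-ranked outside genes until membership
reaches $N$-fold the base size, capped at 500 genes. *eDMN* variants
additionally expand the two mapped disease sets inside each eMN (top
$\min(N |mapped|, |eMN|)$ genes of a seeded RWR) before scoring.

A module enters a pair's score only when strictly more than `min_mapped`
(default 5, i.e. at least 6) genes of *each* set map onto it. For eMN and
eDMN variants eligibility is judged on the parent MN's base genes; DINet
judges it on the expanded membership — both follow the wording of the
methods they implement. Module-family scores are the mean of the per-module
statistic over eligible modules; the eDMN connectivity score averages only
modules with a positive weighted score (an option includes zeros).

## Random walk with restart

The walk iterates $p \leftarrow (1-r)\,W p + r\,p_0$ with $W$ the
degree-column-stochastic adjacency and $p_0$ uniform on the seeds. Defaults:
restart $r = 0.5$, L1 tolerance $10^{-10}$, at most 10\,000 iterations.
The restart value is a declared package default — the midpoint commonly used
in network medicine — because no single canonical value exists; downstream
significance is permutation-based and therefore robust to the precise
choice. Isolated nodes have zero columns; the mass they would swallow is
re-injected into the seed distribution, keeping $p$ stochastic (so a seed
that is itself isolated scores 1). Rankings break score ties
lexicographically by symbol, making every expansion bit-reproducible.

## Significance

**Per-module permutation null.** The focal genes mapped to a module are
replaced by uniform draws of the same size from the module's gene universe;
the score is recomputed per draw (for DINet this re-runs the focal-seeded
RWR; for eDMN it re-expands the permuted set), and the observed score
becomes $z = (x - \hat\mu)/\hat\sigma$ with a one-sided normal-tail p
(lower tail for smaller-is-stronger scores). 100 permutations by default. A
degenerate null ($\hat\sigma = 0$) yields $p = 1$ with a flag rather than an
error, so batch runs over thousands of modules complete; an empirical-rank
p-value is also reported. Per-unit seeds derive from a run seed by a stable
string hash, so batches are reproducible and order-independent.

**Across modules.** DINet adjusts the per-eMN p-values by Benjamini–Hochberg
within the pair and reports the minimum adjusted p. BH is used wherever an
FDR is called for; the key-connector analysis uses Bonferroni.

**Across the panel.** Each method's scores are standardized against the
panel's own score distribution; diseases with one-sided $p < 0.05$ are
flagged. Unscorable pairs (no eligible module) are filled with the
orientation's neutral worst case (0, or 1 for p-value scores) so the panel
statistics stay defined.

## Functional-subnet specificity and key connectors

For one connection, *significant eMNs* are those with positive observed
eDMN connectivity and permutation FDR $\le 0.05$ (inclusive). Counting, for
each eMN, the connections in which it is significant gives its frequency;
restricted to the related-disease subset the count is KF, over all
connections AF, and the specificity index is $SP = KF/AF \in (0,1]$. eMNs
with SP strictly above a threshold (0.3 and 0.2 are the reference choices
for the two diabetes types; the threshold is a parameter) are *specific*;
lists are sorted by KF descending. The per-connection average frequency
(`connection_af()`) is deliberately a separate quantity from the per-eMN AF
used in SP — the two are never mixed.

Key connectors are found by dynamic neighborhood search: the subnet of all
nodes within $L = 2$ hops of the query set is induced; for each gene and
each layer $h = 1, 2$ its $\le h$-hop neighborhood (excluding the gene) is
tested for query-gene enrichment with the hypergeometric upper tail, the
background being the subnet minus the gene itself — a gene is never part of
its own background. The per-gene statistic is the minimum p over layers;
Bonferroni correction runs over the tested genes (not genes × layers), and
genes at adjusted $p \le 0.05$ are reported.

## The synthetic benchmark

`generate_synthetic()` builds a fully seeded instance: a
preferential-attachment backbone (heavy-tailed degrees, as in real
interactomes), planted modules with elevated internal edge density standing
in for GO BPs, a focal set concentrated in a subset of modules, planted
related diseases, and size-matched uniform random unrelated sets. Planted
signal enters *only* through two knobs: the overlap fraction (shared
focal–disease genes allocated inside common modules) and the cross-edge
enrichment factor (extra focal–disease edges there). At overlap 0 and
enrichment 1 the related sets are exactly uniform draws — a pure null.

The benchmark conditions are 2000 genes, 40 modules of 40–60 genes, a
150-gene focal set over 8 modules, 10 related sets (120 genes, overlap 0.2,
enrichment 3×) and 40 unrelated sets. At these sizes the eDMN pipeline at
fold 3 separates planted from random sets with AUC well above 0.8, and the
pure null sits near 0.5; a mean over 10 null instances is the right check,
since a single 10-vs-40 AUC has a null standard deviation near 0.10.

What the generator does *not* emulate: the nested, heavily overlapping
structure of real GO terms (modules here are independent random subsets),
term redundancy, curation biases of disease gene sets, and literature
co-occurrence structure. Passing the synthetic benchmark therefore shows
the pipeline recovers the kind of signal it models — concentrated overlap
plus excess cross-edges — not that any particular real disease pair will
score highly.

## Numerical choices and degenerate inputs

- Unreachable distance contributions are excluded from means with a warning
  (an option imputes diameter + 1); inside a connected component the issue
  cannot arise.
- The running-sum increments follow the asymmetric $(N-G)/G$ / $-G/(N-G)$
  form; a `form = "ks"` switch offers the zero-sum Kolmogorov–Smirnov
  increments $1/G$ / $-1/(N-G)$. The permutation z absorbs the scale
  difference.
- In DINet, $ES_1$ scores the focal hits on the disease-seeded ranking and
  $ES_2$ the converse; $\beta$ defaults to 0.5 and can be swept over
  0.1–0.9.
- Module expansion stops at the component boundary with a warning rather
  than adding unreachable score-0 genes.
- All set orderings and rank ties resolve lexicographically, so every
  result is bit-reproducible given the run seed.

## Problem sizes used by the test suite

The suite exercises full-scale benchmark instances (2000 genes) for the
planted and null AUC checks, 1000 true-null units at 100 permutations for
calibration, and smaller seeded instances (300–600 genes) for the
module-level contracts — sizes chosen so each property is measured with
meaningful replication while the whole suite stays quick to run.

## A worked run

```{r, eval = FALSE}
library(diconnect)
sim <- generate_synthetic(synthetic_spec(seed = 1))
net <- largest_connected_component(sim$network)
fit <- diconnect(net, sim$focal, sim$diseases, sim$bp_sets,
                 method = "DIconnectivity-eDMN", fold = 3,
                 labels = sim$labels, seed = 1)
print(fit)
plot(fit)
```

## Limitations

Scores depend on the completeness of the input gene sets: panels mixing
well-studied and sparsely annotated diseases will rank the latter low
regardless of biology (harmonizing set sizes before scoring mitigates
this). The normal-tail p-values lean on an approximately Gaussian
permutation null; for very sparse modules the empirical-rank p is the safer
flag. The package performs no identifier mapping — symbols must already
agree between the network and the gene sets.
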