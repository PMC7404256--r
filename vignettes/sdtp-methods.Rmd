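---
title: "Mining drug treatment patterns from multilayer tissue networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining drug treatment patterns from multilayer tissue networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdtp)
```

## The problem

A drug that treats several diseases plausibly acts on a recurring piece of
network biology: a small set of proteins that interact strongly with each
other in every disease-relevant tissue. `sdtp` operationalizes this idea.
Each disease contributes one tissue-specific weighted protein-interaction
network (a *layer*); the layers are aligned on their common genes and stacked
into a third-order tensor; *recurrent heavy subgraphs* (RHS) — gene sets
whose induced subgraphs carry high total edge weight across several layers
simultaneously — are mined as candidate drug-target modules; and a cascade of
filters grounded in drug-activity and disease-expression data reduces the
candidates to the modules proposed as the drug's treatment pattern.

## Model and objective

Let $a_{ijk} \in [0,1]$ be the weight of the edge between genes $i$ and $j$
in layer $k$, with $a_{iik} = 0$ and $a_{ijk} = a_{jik}$. For indicator
vectors $x \in \{0,1\}^n$ over genes and $y \in \{0,1\}^m$ over layers, the
**heaviness** of the module $(S, L)$ with $x = \mathbb{1}_S$,
$y = \mathbb{1}_L$ is

$$H(x, y) = \tfrac12 \sum_{i,j,k} a_{ijk}\, x_i x_j y_k,$$

the summed weight of all internal edges across the selected layers. The
**density** of a module is its heaviness per edge slot,
$H / \left(\binom{|S|}{2}\,|L|\right)$ — the mean internal edge weight, a
number in $[0,1]$ for weights in $[0,1]$.

Before mining, each layer's weights are rescaled affinely onto $[0.1, 1]$
(minimum observed weight to 0.1, maximum to 1), and optionally only the top
fraction of edges by weight is retained, mirroring how confidence-weighted
tissue networks are distributed ("top edges"). The tensor is then built on
the sorted intersection of the layers' node sets, with missing edges as 0.

## What "density threshold" means here

The miner takes a density threshold $t$ (default 0.41, the operating point
selected by the enrichment-ratio scan described below). A module is
**feasible** when

1. it has at least `min_size` genes (default 3);
2. every selected layer's internal mean weight is at least $t$; and
3. every member gene's mean attachment weight to the rest of the module,
   averaged over the selected layers, is at least $t$.

Conditions 2 and 3 jointly imply the aggregate bound
$H / (\binom{|S|}{2} |L|) \ge t$. We enforce the threshold layer-wise and
gene-wise rather than only in aggregate for a structural reason: heaviness
is monotone in the gene set, so under an aggregate-only constraint a dense
core can always absorb weakly attached bystander genes — each addition
raises heaviness while the average density decays only slowly, and the
"module" blurs into its periphery. The per-gene condition is the natural
cohesion requirement (every member must be, on average, as strongly attached
as the module is dense), and the per-layer condition is what "recurrent"
means (the module must actually be heavy in each layer it claims). With
these constraints, maximizing heaviness recovers planted modules exactly
instead of padding them, which is what the recovery benchmarks in the test
suite measure.

## The mining algorithm

The miner alternates three phases, repeated until no feasible module
remains or `max_modules` is reached:

**Continuous relaxation.** Starting from uniform positive vectors, alternate
multiplicative updates
$x_i \leftarrow g_i^{1/(p-1)} / \lVert\cdot\rVert$ with
$g_i = \sum_{j,k} a_{ijk} x_j y_k$, and
$y_k \leftarrow h_k / \lVert h \rVert$ with
$h_k = \sum_{i,j} a_{ijk} x_i x_j$, until the relative change of the
continuous heaviness falls below `convergence_tol` (default $10^{-6}$) or
`max_iterations` (default 200). The exponent $p$ (`sparsity_exponent`,
default 2) controls how sharply the gene vector concentrates; $p = 2$ gives
a power iteration on the $y$-weighted average adjacency, whose fixed point
concentrates on the heaviest coherent subgraph.

**Discretization.** Genes are sorted by $x$ (ties broken by gene identifier),
and every prefix from `min_size` up is scored: for the prefix's gene set the
best feasible layer subset is found by enumerating layer subsets in
decreasing total-heaviness order (exact for the small layer counts typical
here) and taking the first that satisfies the per-gene condition. Among all
feasible (prefix, layer set) pairs the one with maximum heaviness is kept.
A local search then polishes it: single-gene additions, removals and swaps
are applied greedily whenever they increase heaviness while preserving
feasibility. Layers are re-chosen by per-layer heaviness for the candidate
gene set rather than by the relaxed $y$ ordering — the exact inner
optimization, which coincides with the $y$ ordering once the relaxation has
converged.

**Masking and restarts.** An accepted module's internal edges are zeroed in
its selected layers only, so overlapping modules sharing a few genes remain
discoverable, and mining repeats. Each round runs the deterministic uniform
start plus `restarts` (default 3) perturbed starts; a perturbed start relaxes
against a seeded diagonally reweighted copy of the tensor (weights
$d_i d_j a_{ijk}$ with $d_i \sim U(0.5, 1.5)$), which moves the relaxation
fixed point and hence the gene ordering handed to discretization, while all
scoring is done against the true tensor. Mining stops when a full round
yields no feasible module. Given the seed, the entire run is bit-for-bit
deterministic.

The miner is a heuristic: it carries no global-optimality guarantee. Its
quality is bounded empirically against an exhaustive-search oracle on small
instances (at most 8 genes and 3 layers, where complete enumeration over all
feasible gene/layer subset pairs is cheap); the acceptance suite requires
the first mined module to reach at least 90% of the oracle optimum on dense
random tensors and to match it exactly on high-contrast planted instances.

## Choosing the threshold: the enrichment scan

`heaviness_scan()` re-mines the tensor over a grid of thresholds and reports,
per threshold, the module count $N_a$, the number $N_e$ of modules with at
least one significantly enriched annotation term, the ratio
$R_{ea} = N_e / N_a$ (reported as undefined, never as 0, when $N_a = 0$),
and per layer the overlap between mined module genes and that layer's
drug-affected gene set. This is how an operating threshold is chosen in
practice: take the point where the enrichment ratio stabilizes while
drug-gene overlap remains high — 0.41 in the trichostatin A case study that
motivated this pipeline, kept here as the default. On synthetic data the
scan's qualitative behaviour (module gene unions shrink as the threshold
rises) is exercised by the tests.

## The filter cascade

Mined modules pass through, in order:

1. **Size filter** — at least three genes.
2. **Differential-expression containment** — the module must contain at
   least one *concordant* gene: a gene with nonzero log fold-change both in
   a disease contrast and under the drug perturbation. Concordance is
   direction-agnostic by default (the drug may move a gene in either
   direction); a strict reversal mode is available
   (`require_opposite_sign`). The default threshold on $|logFC|$ is 0
   (strict inequality), i.e. any nonzero change; it is configurable because
   real estimates are never exactly zero.
3. **Term-overlap filter** — the module's genes are enriched against a local
   annotation map (hypergeometric upper tail per term, Benjamini–Hochberg
   within namespace); the proportion of its significant terms shared with
   the drug-target reference terms must reach `min_proportion` (default
   0.2) in each of the BP, MF and CC namespaces. The proportion denominator
   is the module's *significant* terms, and a module with no significant
   terms in a namespace is dropped with a logged reason. The 0.2 default
   operationalizes "more overlapping terms" as a tunable cutoff.
4. **Disease-term filter** — at least one shared significant term per
   namespace against *every* disease gene set's enrichment.
5. **Neighbor scoring and pathway ranking** — a module's first-order
   neighbor $j$ scores $\sum_{i \in S} w_{ij}$; a sampling threshold (draw
   `n_samples` neighbors uniformly with replacement, default $10^6$, sort
   the scores descending, take the `rank`-th, default 50) retains only
   strongly attached neighbors (strict inequality). Sampling is with
   replacement because the draw count deliberately exceeds the number of
   distinct neighbors. Modules are finally ranked by the number of pathway
   terms their conserved neighbors share with the drug targets' pathways,
   summed over layers, and the top `top_k` (default 2) are kept.

## Statistical validation

**Permutation significance.** With the network topology held fixed, the
multiset of edge weights is globally permuted; the p-value is the fraction
of `n_perm` rounds (default 10,000, configurable up to $10^6$) in which the
permuted internal weight sum of the module reaches the observed one. The
plain estimator can return exactly 0 — this is deliberate, reproducing the
estimator's published form; an add-one variant
$(\text{count}+1)/(n_{\text{perm}}+1)$ is available and is the one used for
calibration checks, since it is never zero and is uniform under the null up
to discreteness. Calibration is verified by a Kolmogorov–Smirnov uniformity
test over 200 independent network/module replicates, and exactness on a
4-edge path where complete enumeration of weight placements gives
$p = 1/4$.

**Differential co-expression.** For a module and one condition's samples
(at least 3), Pearson correlations between all gene pairs define a
co-expression network keeping pairs with $|r| \ge$ `r_threshold` (default
0.8; negative correlations count, since coordinated repression is still
co-expression). Zero-variance genes yield no edges and a warning. The
case/control edge sets are partitioned into case-only, control-only and
shared edges; a module whose connectivity collapses or rewires between
conditions is the signature of disease-linked structure.

## Synthetic data: what it emulates, and what it does not

`simulate_multilayer()` plants complete modules with uniform weights in a
configurable internal range on designated layers, over an Erdős–Rényi
background with uniform weights; planted contrast (internal range strictly
above background) is enforced unless explicitly waived. Uniform weight
distributions are chosen for transparency — every recovery result can be
reasoned about in closed form. `simulate_expression()` draws case-sample
module genes from a one-factor model (pairwise correlation equal to the
factor loading squared), with controls and background genes independent —
case-only co-expression, the qualitative differential-connectivity contrast.
`simulate_logfc_tables()` plants a concordant gene set that the selection
rule recovers exactly at threshold 0. `simulate_annotation()` plants terms
covering a module plus about 1% of the background, which are significant by
construction for modules small relative to the background.

These generators reproduce the *statistical shape* the method assumes, not
real data: no scale-free degree structure, no correlated noise across
layers, no annotation bias, no measurement error in the fold-changes.
Passing the recovery benchmarks therefore demonstrates algorithmic
correctness under the stated model, not performance on any particular real
tissue network compendium.

The package also ships `table1_fixture()`, the 26 candidate drug-target
modules (Entrez identifier lists) from the trichostatin A case study that
motivated the pipeline, used for worked set-overlap examples — e.g.
`overlap_coefficient(M17, M18) = 0.5`, below the 2/3 overlap rule, so the
two final modules are related but distinct.

## Numerical and design notes

* Feasibility comparisons use a $10^{-12}$ slack so boundary densities
  (e.g. an exact 2/3) are not lost to floating error; the 2/3 module-overlap
  rule itself is decided in exact integer arithmetic.
* Duplicate edges in input files keep the maximum weight; self-loops are
  dropped with a warning; top-edge ties at the cutoff break
  lexicographically on the sorted gene-id pair, making edge selection
  deterministic. Edge counts use `ceiling(fraction * |E|)`.
* Gene identifiers are compared as exact strings; no alias resolution.
* All text outputs write weights at full precision (`%.17g`), so
  write/read round-trips are bit-exact, including the sparse tensor
  directory format.
* The pipeline expands one global seed into per-stage seeds
  (`seed * 100 + stage number`), so any stage can be reproduced in
  isolation; reruns with the same configuration are byte-identical.
* Problem sizes in the shipped tests and validation script — tensors up to
  200 genes x 3 layers, 20 recovery seeds, 50 oracle tensors, 200
  calibration replicates at 500 permutations — were chosen so the whole
  suite documents the method's behaviour in minutes on a laptop while
  keeping every oracle comparison exhaustive where it claims to be.

## Known limitations

* The miner is greedy-with-restarts; on adversarial instances it can return
  a locally optimal module. The oracle bound is verified only at small
  scale.
* The enrichment engine is a plain hypergeometric test over opaque term
  identifiers: no term-hierarchy traversal, no modified scores from any
  specific web service, so term counts will not match any particular online
  tool's output.
* Empirical-Bayes moderated fold-change estimation is out of scope; the
  two-group mean difference stands in, and on noisy low-replicate data a
  moderated estimator should be substituted upstream.
* The permutation scheme shuffles weights over a fixed topology (the
  published design); it does not test topology itself against a
  degree-preserving rewiring null.
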