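---
title: "Methods: weighted bipartite projection for miRNA-disease ranking"
author: "wbnproj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted bipartite projection for miRNA-disease ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbnproj)
```

## The problem and the modelling assumption

Known miRNA-disease associations form a sparse bipartite graph: a
binary matrix `A` with rows indexed by miRNAs and columns by diseases
(`A[j, i] = 1` iff the pair is experimentally confirmed). The package
ranks the unobserved pairs by how strongly the known graph, reweighted
by independent similarity information, "recommends" them. The single
substantive assumption is guilt by association on both sides:
functionally similar miRNAs tend to regulate similar diseases, and
semantically similar diseases tend to involve similar miRNAs. Every
stage below is a way of injecting that assumption into an otherwise
purely topological recommender.

## Similarity layer

**Disease semantic similarity.** Each disease is represented by the DAG
of its ontology ancestors (edges child -> parent). Two complementary
contribution schemes are computed per disease `S` over its term set
`T(S)`:

* model 1 (depth decay): `D1_S(S) = 1` and
  `D1_S(t) = max{ delta * D1_S(t') : t' a child of t in DAG(S) }`, so a
  term's contribution is `delta^depth` along its best path;
* model 2 (information content): `D2(t) = -log(n_t / n)` where `n_t`
  counts the DAGs containing `t` among the `n` diseases — rarer, more
  specific terms contribute more, and a term present in every DAG
  contributes nothing.

Similarity is shared-ancestry mass over total mass,
`SS(A,B) = sum_{t in T(A) & T(B)} (D_A(t) + D_B(t)) / (DV(A) + DV(B))`,
and the final semantic matrix averages the two models. Numerical edge
cases: self-similarity is fixed at 1; a model-2 pair whose semantic
values are both zero (every term ubiquitous) is given similarity 0 with
a warning rather than 0/0. The logarithm base in model 2 is immaterial
— changing base rescales every `D2` by a common factor that cancels in
the ratio — and the natural log is used; a test verifies the
invariance.

**Interaction-profile kernels.** Pairs without semantic (or, for
miRNAs, functional) similarity still get a similarity from the
association matrix itself: the Gaussian interaction-profile kernel
`K(i,j) = exp(-beta * ||IP_i - IP_j||^2)` over binary profiles (rows or
columns of `A`). The bandwidth is the user parameter (default 1)
rescaled by the mean squared profile norm. Two conventions exist for
the rescaling; this package divides by the mean squared norm by
default, which normalises the kernel against overall network density
and is the convention in the lineage of interaction-profile methods.
The literal multiplicative form is retained behind
`bandwidthForm = "multiply"` for comparability.

**Integration.** The integrated miRNA similarity `MS` takes the
functional score where both miRNAs appear in the functional matrix and
the kernel elsewhere; `DS` does the same with the combined semantic
similarity for diseases that have DAGs. "Availability" is per pair:
coverage of both identifiers by the primary source.

## Projection layer

**Transfer weights.** Each edge of the bipartite graph is weighted by
how strongly the whole similarity neighbourhood of its miRNA endpoint
points at the disease:
`wr(m_j, d_i) = sum_k MS(m_j, m_k) A(m_k, d_i) / sum_k MS(m_j, m_k)`,
and symmetrically `wd` from `DS` over the disease axis. The sums
include the self term; since the integrated similarities have unit
diagonal the denominators are strictly positive. As weighted averages
of 0/1 entries the weights live in [0, 1]. Two degenerate cases anchor
intuition and the tests: `MS = I` collapses `wr` to `A` itself, while
`MS = all-ones` erases the dependence on the source miRNA entirely
(`wr(., d_i) = k_i / nm`).

**Damped initial information.** The resource placed on known edges is
`S_ini(m_j, d_i) = A_ji * k_i^beta` (disease degree `k_i` for the
disease-based run; mirrored with miRNA degree for the other direction).
With `beta < 0`, heavily annotated nodes start with proportionally less
resource, counteracting the popularity bias of pure resource
allocation. The default is `beta = -0.1`; `beta = 0` is accepted as the
undamped diagnostic limit in which `S_ini = A` exactly. The convention
`0 * k^beta = 0` applies: an entry with `A = 0` is zero regardless of
degree, and a degree of 0 with `A = 1` cannot occur.

**Two-step propagation.** The disease-based direction diffuses the
resource miRNA -> disease -> miRNA along `wr`, which in matrix form is
`S_M = P S_ini` with
`P(m_j, m_k) = (1/d(m_k)) sum_i wr(m_j, d_i) wr(m_k, d_i) / d(d_i)`
and `d(.)` the weighted degrees (row/column sums of `wr`). Substituting
the degree definitions shows every column of `P` sums to 1, so
propagation redistributes but never creates or destroys resource; the
suite checks column-stochasticity and mass conservation on random
instances, and checks the matrix form against a naive per-target-column
nested-loop evaluation of the two steps.

The miRNA-based direction is implemented as the exact mirror — `wd` in
both steps, disease-side resource damped by miRNA degree, an `nd x nd`
propagation matrix — sharing one transposition-based code path with the
disease-based direction so the two cannot drift apart. Only the
miRNA-side weights appear in the printed recursions of the method this
package implements; treating the second network as the full mirror is
this package's design choice, made for symmetry, and is stated here
rather than asserted as the only reading. The final prediction is the
average `S_fin = (S_M + S_D) / 2`.

**Isolated nodes.** A node with zero weighted degree has no diffusion
path; rather than silently scoring it zero, propagation fails with an
error listing the offending identifiers, and `dropIsolated()` (or the
command-line `--drop-isolated` flag) removes such nodes beforehand.
This is a real limitation of projection methods: a disease with no
known miRNA cannot be ranked at all.

## Evaluation layer

**Protocols.** Leave-one-out CV masks each known association in turn;
k-fold (default 5) masks random near-equal groups (sizes differ by at
most one, remainder on the first groups), repeated with per-repetition
shuffles. By default every stage downstream of `A` — kernels,
integrated similarities, transfer weights, initial information — is
recomputed from the masked matrix in every fold, which is the leak-free
choice. `cvRecomputeFlags()` lets any stage be frozen at its
full-matrix value to quantify how much that stage's leakage would
inflate the AUC; with the transfer weights and initial information both
frozen the scores no longer depend on the fold at all, which is the
intended extreme of that probe.

**AUC.** The negative set is every pair never observed in the full
matrix. Each held-out positive is compared, within its own fold's score
matrix, against all negative scores; its record stores the fraction of
negatives it beats (ties half). The reported AUC is the mean of those
fractions — the pooled Mann-Whitney statistic with fold-matched
negatives — and the ROC curve is derived exactly from the same
quantiles. For k-fold, each repetition yields one AUC and the mean ± sd
over repetitions is reported. Folds that isolate a node are recorded as
failed and excluded with a warning, never silently dropped.

**Baseline.** On request the degree-product score `k_m * k_d`
(recomputed from each fold's masked matrix) is evaluated on identical
folds; a method that cannot beat it is only rediscovering popularity.

## Synthetic data

The generator emulates the three real inputs at configurable size with
planted co-membership structure, which is the minimal structure
realising the guilt-by-association assumption: miRNAs and diseases are
assigned round-robin to blocks; associations are Bernoulli
(`pWithin`/`pBetween`); functional similarity blends the block
indicator with uniform noise (`fsSignal`); disease DAGs hang each
disease at a random depth of a per-block ancestor chain meeting a
global root, so same-block diseases share more ancestors. One user seed
drives a named sub-stream per artifact, so changing the DAG scheme
cannot perturb the association draw, and resampling (bounded, then
error) guarantees no isolated node.

The reference conditions used by the tests and the acceptance script
are two blocks of 60 miRNAs x 40 diseases with `pWithin = 0.6`,
`pBetween = 0.02` and `fsSignal = 0.8` — a dense planted signal with
noisy but informative similarities, at a size where a full LOOCV
(~700 folds with all stages recomputed) runs in seconds; the
structureless control uses one block at density 0.3 with pure-noise
functional similarity (40 x 30); fivefold CV uses 10 repetitions and
the damping sweep 3. What passing these benchmarks shows is that the
implementation recovers planted block structure well above both chance
and the popularity baseline, and sits at chance when there is nothing
to find. What it does not show: real association data have heavy-tailed
degree distributions, curated-ontology DAG shapes and literature-driven
ascertainment bias that the generator deliberately does not mimic, so
absolute AUCs here do not transfer to any real corpus.

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.5 | model-1 depth decay per DAG level (dimensionless, (0,1]) |
| `beta` | -0.1 | popularity damping exponent, (-1, 0] |
| `bandwidthPrime` | 1 | kernel bandwidth before profile-norm rescaling |
| `bandwidthForm` | divide | bandwidth rescaling convention |
| `k`, `repeats` | 5, 10 | k-fold protocol shape |

`delta = 0.5` is the established value of the DAG-similarity scheme the
semantic model follows; `beta = -0.1` is the conventional mild damping
for this projection family, and the sweep utility (`betaSweep()`)
exists precisely because the AUC is nearly flat in beta on planted
data, so any choice in the range is defensible.

## Determinism and tie-breaking

All ranking output breaks score ties lexicographically on the miRNA
identifier; CV shuffles derive per-repetition seeds from the single
user seed via a fixed documented formula (`seed + 1000003 * r` mod
2^31 - 1); prediction itself is deterministic. Identical seeds and
configs therefore give bit-identical artifacts, which the suite
asserts.

## Known limitations

* Nodes without associations cannot be scored (fail-fast by design).
* Dense matrices throughout: intended for up to a few thousand nodes
  per side, not genome-scale bipartite graphs.
* The miRNA functional similarity is an input, not computed here.
* No multi-step (>2) diffusion, restart walks, or heterogeneous-network
  variants; no statistical machinery for comparing methods.
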