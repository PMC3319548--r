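---
title: "Hierarchical modularity scoring and TAFI: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical modularity scoring and TAFI: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiermod)
```

## The model

`hiermod` scores the functional coherence of a *hierarchical gene module* —
a rooted tree whose leaves are genes — against a *hierarchical taxonomy of
functional terms*: a rooted tree or DAG such as the Gene Ontology, in which
child terms refine their parents. The central assumptions are:

1. **Specificity grows with depth.** A term's informativeness is a function
   of its position in the taxonomy, not of how often it is used in a
   corpus. We deliberately use no background term-frequency model
   (no information content): the score is a property of the module and the
   taxonomy alone, so it does not shift when the annotation corpus does.
2. **Annotations are unrelated sets.** A gene's annotation, and every
   internal node's, is an antichain of the taxonomy — keeping a term
   together with its ancestor adds no information. Inputs violating this
   are reduced to their most specific members.
3. **Coherence is judged level by level.** Every internal node is annotated
   with the most specific functions *common* to its children, and its
   contribution is discounted when the children's own annotations sit far
   from it in the taxonomy.

### Specificity

A term occurring at level `l` (distance from the root) gets the level
specificity `ζ(l) = l / L`, where `L` is the taxonomy depth. In a DAG a
term can occur at several levels; its specificity `σ(t)` aggregates `ζ`
over the occurrence levels, with the **mean** as default (`min` and `max`
via `scoring_config(level_aggregation=)`). The mean keeps `σ(root) = 0`,
`σ = 1` exactly for terms confined to the deepest level, and changes
smoothly when a DAG edge adds a second occurrence level. Note one DAG
subtlety: with mean aggregation an ancestor can, in principle, carry a
larger σ than one of its descendants if its other paths run deep; on
tree-shaped taxonomies σ is strictly monotone along every lineage.

### Node annotation

Leaves carry their gene's annotation. An internal node `v` with children
`c_1..c_k` is annotated with

```
F(v) = the largest unrelated subset of  ∩_i ancestors(F(c_i)),
```

where `ancestors(S)` is the closure of `S` under "all terms on any simple
path to the root" (it always contains the root, so `F(v)` is never empty).
The maximization is solved exactly by branch and bound, with deterministic
tie-breaking: larger summed specificity first, then lexicographically
smallest term IDs. A node with a single child (possible after a hierarchy
cut) copies the child's annotation and is not penalized.

### Dissimilarity, penalization, HMS

For a parent annotation `F(v)` and child annotation `F(c)` the set distance
`D` aggregates, over the parent's terms, the minimum shortest-path distance
to a related child term (`max` over parent terms by default, `mean`
optionally); `D = ∞` when some parent term has no related partner. The
dissimilarity is

```
d = D / (D + θ),
```

so immediate neighbours (`D = 1`) are penalized 50% at `θ = 1`, and terms
15 levels apart — the deepest separation a GO-sized taxonomy offers — are
penalized 13% at `θ = 100`. The penalization factor of a node is
`P(v) = 1 − max_c d(F(v), F(c))` (the *reciprocal* variant; *exponential*
`exp(−D/θ)` and *linear* `max(0, 1 − D/L)` variants are provided for
comparison and behave similarly at small `D`).

The hierarchical modularity score averages the node contributions:

```
HMS(M) = (1/|I|) Σ_{v∈I} P(v) · σ*(F(v)),
```

with `σ*` the maximum specificity within `F(v)` (mean optionally). Whether
the aggregation over internal nodes should be the arithmetic mean or some
other normalization is genuinely open; the mean makes modules of different
sizes comparable and is the default, and a `sum-normalized` alternative
(`Σ P·σ / Σ σ`, the penalty-weighted fraction of attainable specificity) is
kept behind `scoring_config(node_aggregation=)`. HMS is undefined for a
single-leaf module; a forest is scored by pooling the internal nodes of its
trees, and a forest with no internal node at all scores 0.

### Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `theta` | distance tolerance of the penalty (taxonomy edges) | 10 | forgives 1–2 edges of drift (d ≈ 0.09–0.17) while still zeroing unrelated branches; calibratable per corpus with `calibrate_theta()` |
| `alpha` | TAFI merging factor in (0,1] | 0.9 | admits merges within 10% of the best similarity — moderate fuzziness; `alpha = 1` is classic AHC |
| `beta` | TAFI stopping criterion | 0.1 | stops agglomeration once even the best merge is nearly incoherent |
| `N` | Monte-Carlo samples | 1000 | resolves p-values down to ~0.001; reduce for exploratory runs |

## TAFI

TAFI reconstructs a hierarchy from a flat gene set. Each gene starts as its
own cluster; the similarity between two clusters is the HMS of the
*hypothetical* module obtained by putting a new root over them (computed
incrementally from each cluster's running node sums — unchanged nodes keep
their contribution). Because this similarity is a semi-metric, no
triangle-inequality-based linkage (such as Ward's) is applicable; the
hypothetical-merge score itself is the linkage.

Per iteration, all cluster pairs with similarity at least `α · S_max` merge
(with `S_max` the iteration's best); a multiplicative factor keeps the
admission band proportionally tight at every scale, where an additive one
would be lenient for small `S_max` and stringent for large. Every
constituent of at least one executed merge then retires from the active
set, living on inside each merge it joined; that duplication is the
fuzziness by which multi-functional genes reach several subtrees. Merging
stops when `S_max < β` or nothing remains mergeable, so the result may be a
forest (`force_single_root = TRUE` joins the leftovers).

Three rules keep the process well-defined:

* **Disjointness.** A merge is admissible only between clusters with no
  shared gene: a gene occurs at most once per tree, and overlap between
  *different* trees of the forest is exactly the fuzzy multi-membership.
* **Pruning.** A merge whose resulting leaf set has already been formed is
  skipped; ineligible pairs are excluded *before* `S_max` is taken, so a
  dead top pair cannot stall the loop.
* **Determinism.** Admitted merges execute in order of descending
  similarity, ties broken by the lexicographically smallest merged leaf
  set. At `α = 1` exactly one merge (the best) executes per iteration, so
  the algorithm reduces to classic best-pair AHC; on tie-free inputs the
  result is a single binary tree identical to the classic construction.

Under heavily tied similarities (many identically annotated genes) the
fuzzy mode can produce a redundant forest of overlapping alternatives —
registry pruning bounds, but does not collapse, them. For partition-style
evaluation we therefore run TAFI with the fuzziness off (`α = 1`), mirroring
how consistency analyses against disjoint reference pathways are done.

`cut_hierarchy(x, k)` undoes the highest merges (greatest-height internal
nodes first; ties: smaller subtree, then leaf set) until `k` subtrees
remain — the analogue of `cutree()` for possibly-fuzzy forests.

## Significance and calibration

`monte_carlo_pvalue()` draws `N` same-size gene sets from a background
universe, rebuilds each with the *same* builder as the observed module
(TAFI for bags of genes; for a fixed input topology, the null permutes
sampled genes onto the same tree), and reports `p = (r+1)/(N+1)`, `r` being
the null scores at or above the observed one. The `+1` correction keeps
p-values strictly positive; a printed `p = 0.00` is therefore impossible by
construction. `calibrate_theta()` scans a θ grid and returns the largest
value for which a target fraction of known-coherent validation modules is
significant at a chosen level, falling back (with a warning) to the
coverage-maximizing θ when the target is unreachable.

## Evaluation

`build_contingency()` counts genes shared between k reference modules and k
predicted subtrees, then aligns columns to rows to maximize the diagonal —
exactly (all permutations) for `k ≤ 8`, greedily beyond; fuzzy genes count
in every predicted set containing them. The Heidke score is
`(PC − E)/(1 − E)` with `E` the chance agreement from both marginals; the
Peirce score normalizes by the reference marginals only; the Gerrity score
uses the Gandin–Murphy equitable weight matrix built from the reference
marginals (rarer categories earn more for a hit, misses are debited by
category separation). All three are 1 exactly on a positive diagonal table
and 0 at marginal chance; references with an empty row are rejected. One
caveat: Heidke and Peirce are invariant to relabeling the categories, but
Gerrity is an *ordinal* score — its weights are built from cumulative
marginals, so off-diagonal tables score differently under different row
orders; we keep the order of the reference list as given. These
standard forecast-verification forms are unit-tested against hand
computations.

## The synthetic generator

`generate_taxonomy()` grows a rooted tree level by level — children per
term drawn from `branching` (default 3–4, echoing the high fan-out near
GO's root), the frontier capped at `max_width` (default 50) so deep
taxonomies stay tractable — and reaches *exactly* depth `L` (default 5).
With `dag_extra_parent_prob > 0`, terms at level ≥ 2 gain an extra parent
from a strictly shallower level, producing multi-level DAG terms without
cycles or extra depth.

`generate_planted_modules()` selects `m` disjoint subtrees (preferring
subtrees that reach the full taxonomy depth, so the planted signals are
equally specific) and gives every gene of module *i* the same small core of
maximally deep terms of subtree *i* — the way members of one complex or
pathway share the same specific annotations. Heterogeneity is injected
explicitly: `multi_function_prob` adds a second module's core to a gene
(and the gene to that reference set), and `annotation_noise` replaces each
term by a uniformly random one with the given probability. Each generator
call uses one RNG stream seeded from `seed` (taxonomy) and `seed + 1`
(modules), restoring the caller's RNG state afterwards.

What the clean (`noise = 0`) data deliberately does **not** emulate:
within-module annotation heterogeneity, incomplete annotation, term-usage
frequency bias, and evidence-code quality. Passing the planted-recovery and
separation tests therefore shows the machinery is correct under its own
model — it does not certify performance on real, noisy annotation corpora,
where the noise and multi-function dials give a first approximation.

## Numerical choices and degenerate inputs

* Equal terms are related with distance 0; unrelated pairs have distance ∞,
  mapping to dissimilarity 1 in every penalty variant.
* Floating-point comparisons in merge admission use a 1e-12 slack so exact
  ties admit reproducibly.
* Genes missing from the annotation map either abort (`unannotated =
  "error"`) or are annotated with the root term (`"root"`), which makes all
  downstream scores total (such genes simply contribute 0 specificity); the
  Monte-Carlo machinery defaults to `"root"` because arbitrary background
  draws must always score.
* Single-leaf modules have no internal node and no HMS (error); two-leaf
  modules are scored by their root alone.
* OBO input keeps only `is_a` edges by default (`part_of` optional),
  drops obsolete terms, and maps `alt_id`s to primary IDs; a synthetic root
  can be added when a namespace filter leaves several top terms.

## Problem sizes used in the shipped checks

The test-suite checks run on taxonomies of a few hundred terms and modules
of up to 24 genes: 100 random DAGs for the exhaustive-oracle comparison,
20 seeds for planted recovery (3 × 8 genes), 200 replicates × 99 null
samples for the p-value uniformity check. These sizes were chosen so the
full suite documents the package's behaviour in minutes while still
exercising every code path; the algorithms themselves have no hard size
limits, and ~100-gene TAFI runs remain interactive.

## Known limitations

* TAFI's similarity, a mean over internal nodes, lets two large coherent
  but unrelated clusters merge with little dilution; the stopping criterion
  `β` acts on `S_max`, so such merges are pruned only by cutting the
  hierarchy afterwards. Deep shared cores within modules (the realistic
  annotation pattern) keep within-module merges dominant.
* The exact maximum-antichain search is exponential in the worst case; it
  is exact and fast for the ancestor-intersection sets that actually arise
  (tens of terms), but adversarial inputs with hundreds of mutually
  unrelated candidates would be slow.
* The uniformity of Monte-Carlo p-values degrades when the null HMS
  distribution is heavily tied (e.g. sparsely annotated backgrounds):
  ties make the test conservative, never anti-conservative.
* Cross-ontology relations (`regulates`, `occurs_in`) and evidence-code
  weighting are out of scope.
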