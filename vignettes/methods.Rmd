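---
title: "Methods: expression scales, network statistics, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression scales, network statistics, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmaxnet)
```

`pmaxnet` analyses how composite molecular-interaction networks decompose
into tissue- and stage-specific subnetworks. This vignette documents the
models it implements, the parameters that matter, the design decisions that
were genuinely open, and what the bundled synthetic-data generator does and
does not emulate.

## Expression scales and classification

Two per-gene normalizations underlie everything else.

**Expression specificity.** For gene abundance measured across $n$
conditions, $Es_i = \mathrm{abundance}_i / \sum_{i=1}^{n}
\mathrm{abundance}_i$. Values lie in $[0,1]$ and sum to one per gene, so
$Es$ captures *where* a gene is expressed, independent of *how much*.
Missing measurements (e.g. probe sets not called present in every
replicate) contribute zero to the total: an unreliably measured condition
is treated as not showing expression, which also means a missing cell
disqualifies a gene from ubiquity. Genes with zero usable total get an
undefined profile and are reported as degenerate rather than erroring.

**Percent of maximum.** $pmax_i = 100 \cdot \mathrm{abundance}_i /
\mathrm{abundance}_{\max}$, the expression in a condition as a percentage
of the gene's own maximal level. The maximum is taken over non-missing
conditions only. $pmax$ is the filtering scale: absolute levels of fully
functional genes span several orders of magnitude, so a shared absolute
cutoff is meaningless, while "close to its own maximum" is comparable
across genes. Ties for the maximal condition break to the
lexicographically first label, for determinism. A numerical detail: the
ratio is computed before scaling by 100, so the maximal condition is
exactly 100 and no value exceeds 100 by a rounding ulp.

**Classification.** Genes fall into three non-overlapping bins per regime.
The tissue regime uses a specific cutoff of $Es \ge 0.8$ and requires
non-zero expression in *every* tissue for ubiquity; the stage regime uses
$Es \ge 0.19$ and a strict $Es > 0.005$ floor at every time point. The two
regimes are configuration presets (`classification_thresholds()`), not
separate code paths, so other cutoffs can be explored. Two decisions here
were open and are resolved as follows: the descriptive property that
stage-specific expression spikes span at most a few consecutive time
points is *not* enforced — the $Es$ cutoff is the sole rule; and the stage
ubiquity floor is strict (`> 0.005`), excluding exact equality. The
assigned condition of a specific gene is its $Es$-argmax condition, ties
again lexicographic.

## Fold differences and Monte-Carlo p-values

The central statistic compares a gene set's internal edge count to
size-matched random sets: draw $|S|$ genes uniformly without replacement
from the network's node universe minus $S$ (minus the fixed set too, in
between-set mode), count edges, and report the per-trial ratio
observed/random averaged over 5000 trials with its standard deviation.
Design choices:

- **Zero denominators.** A random set can have zero internal edges; the
  per-trial fold uses $\max(\text{count}, 1)$ and the number of floored
  trials is reported. This biases the mean fold downward slightly for very
  sparse tests, which is the conservative direction for enrichment claims.
- **Exclusion of the test set** from the random pool prevents planted
  edges from leaking into the null.
- **Node universe** = genes incident to at least one edge; isolated genes
  are not representable in an edge list. Random sets are therefore
  conditioned on network membership, exactly like the observed set.

p-values come from $N$ simulations (default 100,000) of the same null:
count the simulations whose statistic is at least as extreme as observed
(weak inequality, the conservative convention for permutation-style
tests), then report the *upper bound of the two-sided Clopper–Pearson
binomial confidence interval* for that exceedance proportion as the
p-value. At CI 0.9999 the zero-success bound is $1 - (\alpha/2)^{1/N}
\approx 9.90\times10^{-5}$ for $N = 10^5$ — the floor of resolvable
significance under this protocol. The exact (Clopper–Pearson) interval was
chosen among the many binomial CI variants because it is the conservative
exact choice; the interval method is a genuine degree of freedom in this
protocol, and reported p-value floors differ slightly between variants.
Enriched and depleted tails are explicit parameters; the p-value is
monotone in the observed count at fixed seed.

Indirect interactions — set members that share a common neighbor outside
the set without being directly connected — use the same machinery through
a count-function switch.

## Degree-preserving PDI nulls

TF → target networks have a few high-out-degree sources and many targets,
so class-label shuffles are inappropriate; the null must respect degrees.
"Keeping the node degree constant while assigning random targets" is
ambiguous between preserving TF out-degrees only and preserving both
degree sequences, so both are implemented:

- `tf_degree` (default, the literal reading): each TF keeps its out-degree
  and draws its targets uniformly without replacement from the full target
  pool. Only TFs classified specific can contribute to the
  matched-specificity statistic, so non-specific TFs are skipped in the
  statistic computation — a pure optimization with identical distribution.
- `both_degrees`: bipartite double-edge swaps (degree-sequence-preserving
  rewiring, via `igraph::rewire(keeping_degseq())`), preserving in-degrees
  too.

The statistic is the number of edges whose TF and target are specific to
the same condition; the p-value is the Clopper–Pearson upper bound at CI
0.95 over the null networks.

## Context filters

pmax thresholds are strict (`>`, not `≥`): "expressed above 75 pmax"
excludes boundary equality. Gene lists and subnetworks are deliberately
different artifacts: a gene list contains only genes with computable pmax
(no data → no membership), while a filtered *network* retains no-data
genes by default (`missing_policy = "retain"`) because deleting a gene
solely for lacking expression data would silently disconnect well-supported
interactions. In a filtered subnetwork an edge survives only if *both*
endpoints pass, and passing genes left without any surviving edge drop out
— membership in the subnetwork implies a surviving partner, which is why a
subnetwork is always a subset of the same-threshold gene list plus
retained no-data genes. Raising the threshold is monotone: nodes and edges
never increase.

## Enrichment and context clustering

Term enrichment is the one-sided hypergeometric tail (upper for
enrichment, lower for depletion) against an explicit background — the
package does not hard-code any particular annotation corpus, and the
background is a required input because published analyses differ in
whether they use all genes or only annotated ones. The hypergeometric test
stands in for the various phenotype/GO enrichment tools in routine use,
which are all hypergeometric-family tests; the package needs a
self-contained implementation rather than a web-service dependency.
Corrections: Bonferroni ($\min(1, m p)$) or Benjamini–Hochberg. Terms
annotating zero background genes are skipped; query genes outside the
background are dropped with a message.

For heat maps, corrected p-values are $-\log_{10}$-transformed (the base
is irrelevant after scaling; 10 is the conventional choice), term/context
pairs missing from a context's results fill with 0, and the matrix is
min–max scaled to $[0,1]$ — globally by default, per-row as an option,
since "scaled 0–1" does not determine the axis. A constant matrix carries
no contrast and maps to 0.5 everywhere with a warning; any constant is
information-free and the midpoint avoids manufacturing false extremes.
Context columns are clustered agglomeratively; default average linkage on
Euclidean distances, both configurable, since no canonical choice exists
for enrichment profiles.

## The synthetic study design

The generator exists so every downstream stage has a ground truth. Its
defaults *are* the study conditions and are not tuned per analysis:
15 tissue / 30 stage conditions; class proportions 0.314 / 0.462 / 0.225
(ubiquitous / NUNS / specific), matching genome-scale tissue
classifications; per-gene maximal abundance log10-uniform over 4 decades;
planted interaction folds 8 (ubiquitous–ubiquitous), 1/5
(specific–specific), 5 (ubiquitous–specific); PDI matched fold 3; mean PPI
degree 10; 50 TFs with mean out-degree 100 (real regulatory compendia
reach hundreds of targets per TF, and this gives the matched-specificity
test reasonable power at 3-fold enrichment); 4 replicates with 5% dropout.

**Expression.** Within-gene condition profiles are Dirichlet draws shaped
per class: specific genes get one concentrated home component drawn above
the cutoff; ubiquitous genes get a near-uniform draw mixed with a hard
uniform floor so every condition clears the ubiquity floor by
construction; NUNS genes have a random subset of conditions zeroed and the
remainder flattened below the specific cutoff, with a deterministic
repair step (mixing toward uniform) guarding the rare heavy draw. This
construction controls $Es$ directly, so classification recovers the
planted classes essentially perfectly; the ≥ 99% recovery requirement
leaves slack for boundary noise only.

**PPI.** Degree heterogeneity comes from per-gene Pareto activity weights
(tail exponent 2.5, truncated at 8 so that no gene pair's edge probability
saturates the Bernoulli ceiling — untruncated weights would silently
compress the planted fold for hub–hub pairs). Edges are independent
Bernoulli draws with probability proportional to the weight product times
a class-pair propensity multiplier. Crucially, the configured folds are
*target measured folds*, not raw multipliers: the fold-difference
estimator's baseline is the mean propensity among the complement classes,
so a raw specific–specific multiplier of 0.2 would measure as ≈ 0.09
(the complement of the specific set is enriched for high-propensity
ubiquitous pairs). The generator solves the corresponding two-equation
linear fixed point for the within-class multipliers (the between
multiplier needs no correction, because between-mode random sets are drawn
from the NUNS pool whose cross-propensity is the unit baseline). Residual
deviations of recovered folds (typically a few percent low, ±5–8% across
seeds at 2000 genes) come from weight-realization noise and the exclusion
of isolated nodes from the sampling universe.

**PDI.** TFs are sampled stratified by class so the TF set mirrors the
class proportions; out-degrees are Pareto around the mean. Targets are
included by independent Bernoulli draws with inclusion probability
proportional to a weight that multiplies matched (same-condition-specific)
targets by the planted fold, capped at 1 by water-filling. Inclusion
sampling keeps the planted fold multiplicative in expectation — weighted
sampling *without replacement* at fixed degree would deplete the small
matched pool for high-degree TFs and attenuate the planted signal — at
the cost of realized out-degrees varying around their targets. Expected
measured enrichment is $3 \cdot P/(P + 2m) \approx 2.9$ for pool size $P$
and matched-pool size $m$, i.e. within a few percent of the planted value.

**Annotations.** Terms draw genes uniformly, except planted terms that
oversample genes specific to a chosen condition by a configurable factor
(weighted sampling). **Replicates** are the true abundance under
multiplicative log-normal noise with independent per-replicate Bernoulli
absent calls — the simplest model consistent with an
all-replicates-present inclusion filter.

**What the generator does not emulate.** Correlated expression between
interacting genes; assortativity beyond the three-class propensity
structure; measurement noise in the main expression matrix (only the
replicate tables are noisy); edge dependence (co-complex cliques);
identifier ambiguity. Passing tests therefore demonstrate that the
*statistics* recover *planted* structure, not that real interactomes have
that structure.

## Determinism and problem sizes

Every stochastic function takes an explicit seed; the pipeline derives
per-stage child seeds from one master seed, so re-running any stage — or
the whole pipeline — reproduces its outputs bit-for-bit. RNG state is
restored after each call.

The test suite exercises the estimators at the sizes where their
guarantees are stated: expression-scale invariants on 10,000 genes,
classification recovery on 5,000 genes per regime, fold/parameter recovery
on 2,000-gene networks with 5,000 trials and 10,000 simulations,
enumeration-oracle equivalence on 12-node graphs (where all
$\binom{8}{4}$ random sets can be enumerated exactly), and 1,000 null
networks per degree-preservation check. These sizes were chosen so the
Monte-Carlo error bars in the assertions (3 standard errors) are
meaningfully tight while the whole suite stays interactive.

## Known limitations

- Composition percentages exclude unclassified interaction partners from
  the denominator (their count is reported separately); published tables
  do not state their convention, so cross-study comparisons of such
  percentages should check denominators.
- The fold-difference denominator floor makes mean folds for nearly
  edge-free random sets conservative rather than undefined.
- `tf_degree` nulls resample targets from the *realized* target pool, so
  genes never targeted in the observed network cannot appear in nulls.
- The p-value floor is set by the simulation count and CI level, not by
  effect size; increasing simulations is the only way to resolve smaller
  p-values.
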