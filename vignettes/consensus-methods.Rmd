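---
title: "Cross-database consensus for pathway enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-database consensus for pathway enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathconsensus)
```

## The problem

The same biological pathway is usually represented in several pathway
databases (KEGG, Reactome, WikiPathways, PathBank, ...) by gene sets that
overlap substantially but not completely. Enrichment analysis run against
different databases can therefore disagree — a pathway may be called
significant against one database's representation and not another's, or
even enriched in opposite directions. This package makes those
disagreements explicit: it runs over-representation analysis (ORA) and
gene set enrichment analysis (GSEA) against several databases at once,
merges equivalent pathways into a meta-database through curated
`equivalentTo` mappings, classifies every group of equivalent pathways as
concordant or contradictory, and decomposes contradictions at the gene
level.

All gene identifiers are HGNC symbols, uppercased on input and never
remapped: alias resolution is out of scope, and out-of-vocabulary symbols
are kept rather than dropped, so a mismatch surfaces as an empty overlap
instead of a silent repair.

## Equivalence groups and the pathway hierarchy

Equivalence is taken as a true equivalence relation: groups are connected
components of the graph whose edges are the `equivalentTo` mapping
records, so two pathways never directly mapped still merge when linked
through a third. Each component becomes one meta-pathway whose gene set
is the exact union of its members' genes. Merged groups receive fresh
`DC:`-prefixed identifiers, numbered after sorting components by their
smallest member id so the scheme does not depend on input order;
singleton pathways keep their original identifiers, matching the
convention of the published four-database hierarchy.

`isPartOf` mapping records assemble the pathway hierarchy: a directed
acyclic graph over the collapsed nodes and a set of top-level categories
(eight by default: metabolism, immune, signaling, communication and
transport, cell death, disease, DNA repair and replication, others).
Where an `isPartOf` record references a database pathway that belongs to
a merged group, the edge attaches to the merged node — the original
per-database nodes no longer exist after collapsing, and attaching to the
merged node keeps the hierarchy's node set identical to the consensus
table's. Depth is counted with the category roots at depth 1 and the
constraint is depth ≤ 4 inclusive; a deeper chain marks the hierarchy
invalid (a flag plus a report, since the input may still be usable),
whereas a cycle is a fatal error. Nodes with no path to any root are
reported as orphans but retained.

The circle-packing export converts the DAG to a strict tree (a node with
*k* parents is duplicated under each), because a circle packing is a
nesting. Color semantics follow the method: for score-based results,
nodes not significant at the adjusted-statistic threshold are flagged for
gray rendering and significant nodes carry the signed NES; for ORA only
the significance flag is set. Node size is gene-set cardinality.

## Over-representation analysis

For a query list of $n$ genes within a universe of $N$, and a gene set
covering $K$ universe genes of which $k$ are in the query, the one-sided
Fisher's exact test p-value is the hypergeometric upper tail

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

computed through the exact hypergeometric survival function. The test
suite sweeps every configuration with $N \le 30$ (≈ 87,000 cases) against
an independent integer-enumeration oracle; all terms in that enumeration
are exact in double precision, and the observed worst relative
disagreement is below $10^{-13}$.

Because the same query is tested against every set in a database,
p-values are corrected with the Benjamini–Yekutieli step-up rule, which
controls the FDR under arbitrary dependence — gene sets within one
database overlap heavily, so the independence assumption of
Benjamini–Hochberg is not defensible here. Correction is applied within
each database collection separately: each database is analyzed as its own
family of tests, matching the per-database result tables that the
consensus step aligns. The cost is conservatism (BY ≥ BH elementwise,
by the factor $c(m)=\sum_{j\le m} 1/j$).

Two choices the method itself does not fix, both surfaced as arguments
and recorded in the output metadata:

* **Universe.** Defaults to the union of all genes in the selected
  collections — the common gene-set-only convention — and can be
  overridden with the measured background, which is preferable whenever
  the experiment's detected-gene list is available.
* **Size filters.** Gene sets with fewer than 3 or more than 1000
  in-universe genes are excluded by default (tiny sets are unstable,
  huge sets uninformative); exclusions are logged.

The significance level $\alpha$ (default 0.05) only sets the
`significant` flag; it never alters the statistics.

## Gene set enrichment analysis

The package implements the canonical weighted Kolmogorov–Smirnov-style
method natively. Genes are ranked by a two-class metric; the default
signal-to-noise statistic is

$$s = \frac{\mu_A - \mu_B}{\sigma_A + \sigma_B},$$

with each class standard deviation floored at $\max(0.2\,|\mu|,
\varepsilon)$, $\varepsilon = 10^{-8}$ — the usual variance-stabilization
against near-constant genes. Ties are broken by ascending gene symbol, so
every downstream quantity is deterministic. The first class recorded in
the design is the positive class by default; `positive_class` overrides
it, and exchanging the classes negates every score (an invariant the
tests assert).

Walking the ranked list of $N$ genes, the running sum gains
$|s_i|^w / \sum_{\mathrm{hits}} |s_j|^w$ at members of the set ($w = 1$
by default) and loses $1/(N-|S|)$ elsewhere; the enrichment score (ES)
is the deviation of greatest magnitude, with an exact magnitude tie
broken toward the positive extremum. The leading edge is the hits at or
before the extremum (positive ES) or at or after it (negative ES). A set
covering the whole ranked list, or a ranked list of all-zero scores, is
rejected as degenerate.

The null distribution comes from `B` permutations (default 1000):

* **Phenotype permutation** (`run_gsea`): class labels are permuted and
  the ranking metric recomputed each time, preserving inter-gene
  correlation. When the number of distinct label assignments is at most
  `B`, all of them are enumerated instead (with a warning).
* **Gene-set permutation** (`run_prerank`): for a user-supplied ranked
  list, random sets of equal size are drawn from the ranked genes.

Normalization and significance follow the two-sided design of the
canonical method: NES = ES divided by the mean magnitude of same-sign
null ES values (positive and negative nulls normalized separately); the
nominal p is the add-one-smoothed tail frequency within the same-sign
null, so it is never exactly zero at finite `B`; and the FDR q compares
the pooled sign-normalized null NES distribution with the observed NES
distribution by the ratio-of-tails rule, capped at 1. All randomness
flows through one seeded generator, and a fixed seed makes the full
result table bit-reproducible.

Default size filters for GSEA are 5–500 (on the overlap with the
measured genes). These defaults, and `B`, `w` and the metric, are
deliberate package defaults of the canonical method — recorded in every
output's metadata, not a claim about any particular published analysis.

## Consensus classification

For each equivalence group, per-database significance is the adjusted
statistic (BY-adjusted p for ORA, FDR q for GSEA) below $\alpha$.
Comparison happens only among databases in which the pathway exists and
has a result: absence is never treated as non-significance. The label
taxonomy:

* `concordant_significant` — significant everywhere, and for score-based
  methods with agreeing NES signs;
* `concordant_nonsignificant` — significant nowhere. Kept distinct
  rather than folded into "concordant", so either counting convention
  can be recomputed from the output;
* `contradictory_significance` — significant in some databases, not in
  others;
* `contradictory_direction` — score-based only: at least two significant
  members with opposing NES signs. Direction conflict takes precedence
  over significance concordance: a pathway significant everywhere but
  enriched at the top of the ranking for one database and at the bottom
  for another is contradictory, which is exactly the situation the
  gene-level decomposition exists to explain;
* `single_database` — no comparison possible.

The merged meta-database's own result row is displayed alongside (its
column block in the consensus table) but never enters the label: it is
derived from the members and would double-count them. Labels partition
the groups — every classified group receives exactly one — and the
classification is invariant to database ordering.

`compare_methods` cross-tabulates two analyses (e.g. ORA vs GSEA) over
shared groups, counting groups concordant in both, in exactly one, and
in neither, where "concordant" means either concordant label.

## Gene-level decomposition

`venn_decompose` partitions the union of 2–4 equivalent gene sets into
Venn regions by membership signature. The cap at four sets matches the
four supported source databases and the legibility of a Venn diagram;
larger families fall back to a pairwise-overlap table.
`annotate_fold_changes` attaches per-region log2-fold-change histograms
and means from a supplied DGE table (the DGE computation itself is
upstream of this package); all regions share one set of bin edges —
by default 21 equal-width bins spanning the observed range symmetrized
about zero, recorded in the output — so counts are additive across
regions. Region genes absent from the DGE table are counted as
`missing`, never dropped. By default all region genes present in the DGE
table are annotated; a `p_adj_max` filter restricts to significant DEGs
when that is the question being asked.

`explain_discrepancy` orders the exclusive regions (genes unique to one
database's representation) by the magnitude of their mean log2 fold
change. The canonical pattern it surfaces: member sets share a core with
no consistent signal, while the genes exclusive to one database's set
are coherently up- or down-regulated — which flips that database's NES
relative to the others.

## The synthetic-data generator

`simulate_database_family` emulates the one structural feature of real
pathway databases this package depends on: the same pathway represented
by variant gene sets that share a core. Each group is realized as one
variant per database, sized so every pairwise Jaccard index falls in the
requested range (default 0.4–0.6, the regime where databases agree on a
core but differ in the periphery); `equivalentTo` records are emitted
pairwise and each group is attached to a category with an `isPartOf`
record. Gene pools of distinct groups are disjoint, which real databases
violate — cross-pathway gene sharing is deliberately absent so that
planted signal cannot leak between groups and recovery tests are
interpretable.

`simulate_expression` draws log2-scale values
$\mathcal{N}(\mu_0, \sigma^2)$ (defaults $\mu_0 = 7$, $\sigma = 1$) and
shifts planted pathway genes by $\pm\,\mathrm{effect}\cdot\sigma$ in
class A. Because values are log2-scale, the expected log2 fold change of
a planted gene equals $\mathrm{effect}\cdot\sigma$ directly. The
companion DGE table (per-gene Welch t-tests, BH-adjusted) is synthetic
fixture support for the annotation path, not a count-model analysis.
The generator's Gaussian model omits mean–variance coupling, batch
effects, correlation structure and count noise; passing recovery tests
therefore demonstrate correctness of the machinery under a clean signal
model, not performance on real RNA-Seq data.

Generator defaults are the package's reference study conditions: 10
groups across 3 databases, 50 genes per set, a 2000-gene universe, one
planted up-regulated group at effect 1.0, and 20 samples per class.

## Numerical and validation choices

* Exact hypergeometric tails via the survival function; validated
  against integer enumeration (exact below $N = 30$) across the full
  configuration sweep.
* BY via the standard step-up implementation; the closed-form
  equally-spaced case and elementwise dominance over BH are asserted.
* ES tie-break toward the positive extremum; brute-force straight-line
  recomputation agrees on 1000 random instances, and the ES also
  cross-checks against an independent reference implementation where
  available.
* Type-I calibration: on null data (no planted signal, 200 random
  50-gene sets, B = 500, 20 vs 20 samples) the fraction of sets with
  nominal p < 0.05 must fall inside the exact binomial 99% interval
  around 0.05.
* Recovery: under the reference conditions (effect 1.0, 50-gene set,
  20 vs 20, B = 500), the planted set must reach NES > 0 and nominal
  p < 0.05 in at least 19 of 20 replicate seeds, and the planted group
  must be labeled `concordant_significant` across databases.
* Set algebra: Venn partition verified on 10,000 random families;
  equivalence grouping against brute-force connected components; merged
  gene sets against brute-force unions.

These problem sizes (N ≤ 30 sweep, 1000 ES instances, 200 null sets,
B = 500, 20 seeds, 10,000 families) are the package's documented
validation scale, chosen so the whole suite runs in minutes on one core
while keeping every Monte-Carlo assertion comfortably powered.

## Known limitations

* No identifier mapping: inputs must already use HGNC symbols.
* The pre-ranked null (gene-set permutation) ignores inter-gene
  correlation and is anti-conservative on correlated data; phenotype
  permutation is preferred whenever the expression matrix is available.
* The consensus layer reports agreement; it deliberately does not
  combine databases into a single ensemble score.
* Equivalence and hierarchy quality is bounded by the curated mapping
  table supplied; the package validates structure (vocabulary, cycles,
  depth, orphans) but cannot detect a wrong mapping.
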