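# pathconsensus

Pathway enrichment analysis depends on which pathway database you ask.
The same biological pathway is represented in KEGG, Reactome,
WikiPathways and PathBank by gene sets that overlap substantially but
not completely, and enrichment calls against different representations
can disagree — in significance, or even in the direction of regulation.
`pathconsensus` is a toolkit for transcriptomics analysts who want those
disagreements on the table instead of hidden by a single-database
choice. It:

* runs **ORA** (one-sided Fisher's exact test per gene set,
  Benjamini–Yekutieli FDR correction per database) and **GSEA**
  (two-group or pre-ranked; weighted running-sum enrichment score,
  permutation null, sign-matched NES, add-one nominal p, ratio-of-tails
  FDR q) against several gene-set databases at once;
* merges equivalent pathways across databases into a **meta-database**
  via curated `equivalentTo` mappings (equivalence groups are connected
  components of the mapping graph; merged gene sets are exact unions),
  and assembles and validates the `isPartOf` **pathway hierarchy** as a
  DAG (8 top-level categories, maximum depth 4);
* classifies every group of equivalent pathways as
  `concordant_significant`, `concordant_nonsignificant`,
  `contradictory_significance` or `contradictory_direction` (opposing
  NES signs among significant members), and cross-tabulates methods;
* decomposes disagreements at the gene level: **Venn-region analysis**
  of 2–4 equivalent gene sets with log2-fold-change annotation, ranking
  the database-exclusive regions that drive a contradiction;
* ships a **synthetic-data module** (overlapping database families with
  known equivalence structure; two-group expression with planted
  pathway signal) and a **command-line interface** over the whole
  workflow.

## The statistics in brief

ORA tests over-representation of a gene set of in-universe size *K* in a
query of size *n* from a universe of size *N* via the hypergeometric
upper tail

p = Σ<sub>i≥k</sub> C(K,i)·C(N−K,n−i) / C(N,n),

corrected across each database's tests with Benjamini–Yekutieli (valid
under the arbitrary dependence created by overlapping gene sets). GSEA
ranks genes by signal-to-noise (μ_A−μ_B)/(σ_A+σ_B) (σ floored at
0.2·|μ|), walks the ranking with hit increments |s|^w/Σ|s|^w and miss
decrements 1/(N−|S|), and takes the maximum-deviation running sum as the
ES; the null comes from phenotype permutation (pre-ranked: gene-set
permutation), NES normalizes by the same-sign null mean, and q is the
ratio-of-tails FDR. See `vignettes/consensus-methods.Rmd` for the full
account of models, defaults and validation.

## Worked example

Simulate three databases that each represent the same five pathways
(pairwise Jaccard 0.4–0.6), with one pathway group planted up-regulated
at effect 1.0 in a 20 vs 20 two-group design, then run GSEA per database
and classify the consensus:

```r
library(pathconsensus)

fam <- simulate_database_family(n_groups = 5, seed = 42)
sim <- simulate_expression(fam$truth$universe, 20, fam$truth, seed = 43)
results <- do.call(rbind, lapply(fam$collections, function(cl)
  run_gsea(sim$expr, cl, B = 500, seed = 44)))
groups <- build_equivalence_groups(fam$mappings, fam$collections)
ct <- consensus_table(groups, results)

head(results[results$database == "DB1", 1:7], 3)
#>          set_id database size     es   nes p_nominal q_fdr
#> DB1.1 DB1_PW001      DB1   50  0.895  2.36   0.00386 0.000
#> DB1.2 DB1_PW003      DB1   50 -0.274 -1.13   0.25197 0.552
#> DB1.3 DB1_PW004      DB1   50  0.299  1.16   0.25600 0.348

ct$summary
#>     concordant_significant  concordant_nonsignificant
#>                          1                          4
#> contradictory_significance    contradictory_direction
#>                          0                          0
#>            single_database
#>                          0
```

The planted pathway (`DC:0001`, the merged group of `DB1_PW001`,
`DB2_PW001`, `DB3_PW001`) is the one concordant-significant group — NES
above 2.3 in all three databases — while the four null groups are
concordant-nonsignificant:

```r
ct$records[ct$records$label == "concordant_significant",
           c("group_id", "label", "DB1.nes", "DB2.nes", "DB3.nes")]
#>   group_id                  label DB1.nes DB2.nes DB3.nes
#> 1  DC:0001 concordant_significant    2.36    2.34    2.34
```

Gene-level drill-down decomposes the group's three member sets into
Venn regions (signature bits follow the member order), with mean log2
fold changes from the companion DGE table — here the planted signal sits
in every region, shared core (`111`, 33 genes) and exclusives alike:

```r
explain_discrepancy(groups[["DC:0001"]], dge = sim$dge)$regions
#>   signature   exclusive_to  n n_in_dge mean_log2fc
#> 1       001 DB3||DB3_PW001 17       17       1.150
#> 2       010 DB2||DB2_PW001 17       17       0.972
#> 3       100 DB1||DB1_PW001 17       17       0.781
#> 4       111           <NA> 33       33       0.960
```

When a contradiction is real — e.g. signal confined to genes exclusive
to one database's representation — the exclusive region with the
strongest directional mean ranks first, naming the genes behind the
disagreement.

The same workflow runs from the shell via the installed CLI
(subcommands `ora`, `gsea`, `prerank`, `consensus`, `overlap`,
`hierarchy-validate`, `simulate`):

```sh
cli=$(Rscript -e 'cat(system.file("cli/pathconsensus", package = "pathconsensus"))')
Rscript $cli simulate --out demo --seed 17
Rscript $cli gsea --expression demo/expression.tsv --design demo/design.tsv \
    --gmt demo/DB1.gmt,demo/DB2.gmt,demo/DB3.gmt --mappings demo/mappings.tsv \
    --seed 1 --out demo/out
Rscript $cli consensus --results demo/out/gsea_DB1.tsv,demo/out/gsea_DB2.tsv,demo/out/gsea_DB3.tsv \
    --gmt demo/DB1.gmt,demo/DB2.gmt,demo/DB3.gmt --mappings demo/mappings.tsv --out demo/out
```

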