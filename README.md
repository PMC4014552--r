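# mirmodwalk

Integrated miRNA–mRNA–pathway survival analysis for expression cohorts
with clinical follow-up. The package identifies a bipartite **core
miRNA–gene survival module** and evaluates its expression signatures as
patient risk predictors. It is aimed at cancer-genomics analysts working
with sample-matched miRNA and mRNA profiles (the motivating application
is glioma), and it ships a synthetic-cohort generator with a planted
module so every stage is testable without any external download.

## The method

Given expression matrices, a clinical table, a pathway collection
(typed node and directed edge lists), and a miRNA→target table with
per-pair support counts:

1. **Screen.** Each feature's samples are split at the feature's mean
   expression and compared with the log-rank test; features with
   p < 0.001 are survival-associated.
2. **Pathways.** Survival pathways are those enriched for the survival
   genes (hypergeometric upper tail
   `P(X ≥ r) = Σ_{x=r}^{min(n,t)} C(t,x)·C(m−t,n−x)/C(m,n)`
   at p < 0.01 and BH FDR < 0.15) and regulated by at least one survival
   miRNA whose reliably supported targets (support ≥ 6 of 11 sources)
   are enriched at p < 0.01.
3. **Walk.** On each selected pathway's column-normalized adjacency
   matrix `W`, a random walk with restart
   `p_{t+1} = (1−r)·W·p_t + r·p_0`, r = 0.7, is run from seeds (survival
   genes ∪ the focal miRNA's targets, equal mass) to L1 convergence
   below 1e-6; the top 3% of gene nodes by steady-state probability are
   the pathway's core survival genes.
4. **Module.** Every survival miRNA is linked to the core genes of the
   pathways it regulates; the merged bipartite graph is the core module,
   cut into sub-modules by hierarchical clustering (uncentered
   correlation, complete linkage).
5. **Evaluation.** Signatures (miRNA/gene sets) are normalized, samples
   are grouped into high/low risk by K-means (k = 2) or leave-one-out
   nearest-centroid classification, and groups are compared by the
   log-rank test; robustness is measured by the recurrence ratio under
   partial-sample perturbation and repeated shuffle-and-split.

## Worked example

```r
library(mirmodwalk)

truth    <- planted_truth()                      # 3 miRNAs, 12 genes planted
cohort   <- generate_cohort(seed = 101)          # 160 samples, 5000 genes
pathways <- generate_pathways(truth = truth, seed = 102,
                              gene_pool = rownames(cohort$mrna))
targets  <- generate_target_map(truth, seed = 103)

res <- run_pipeline(cohort$mirna, cohort$mrna, cohort$clinical,
                    pathways, targets, run_config(rng_seed = 1, verbose = TRUE))
#> [filter] samples=131 min_days=30
#> [screen] mirnas=3 genes=18 alpha=0.001
#> [enrich] pathways=3 m=5000 alpha=0.01 fdr=0.15
#> [module] mirnas=3 genes=12 edges=36

recurrence_ratio(truth$planted_genes, res$module$genes)
#> [1] 1

sig <- list(mirnas = res$module$mirnas, genes = res$module$genes)
evaluate_signature(cohort$mirna, cohort$mrna, cohort$clinical, sig,
                   method = "kmeans", seed = 5)$p_value
#> [1] 5.170203e-14
```

Reading the output: the screen finds the 3 planted miRNAs and 18
survival genes (the 12 planted plus a handful of expected false
positives at α = 0.001 over 5000 genes); all 3 planted pathways are
selected; the walk recovers exactly the 12 planted module genes
(recurrence ratio 1, no decoys); and the module signature splits the
cohort into risk groups whose survival differs at p ≈ 5e-14.

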