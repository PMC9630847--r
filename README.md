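# triadnet

Pan-cancer co-regulatory network analysis for gene families: feed-forward
loops, hub/module topology, hazard-weighted patient scores, and
drug-response association screens — with a synthetic-cohort generator that
plants the ground truth every stage is tested against.

## The problem

Transcription factors (TFs) and microRNAs jointly regulate gene families of
clinical interest (the motivating case is a family of phosphatases, but any
family works). The recurring regulatory unit is the **feed-forward loop
(FFL)**: a TF and a miRNA that both regulate a common target gene and are
cross-linked to each other. FFLs come in three flavours depending on the
cross edge — *TF-FFL* (TF→miRNA only), *miRNA-FFL* (miRNA→TF only) and
*composite-FFL* (both). `triadnet` implements the full analysis chain a
study of such a family needs:

1. **Priors and motifs.** miRNA→target edges are kept only when supported by
   ≥ 2 of several prediction databases. TF→target edges are called by
   scanning promoter windows (−1000..+200 bp around the TSS, both strands)
   with position weight matrices; a window is a binding site when its
   log-odds score has tail probability p < 10⁻⁵, computed *exactly* by
   dynamic programming over the score distribution.
2. **FFL enumeration and refinement.** Triads (TF, miRNA, target) are
   enumerated from the edge sets and classified. Each edge is then tested by
   Spearman correlation on an expression cohort: miRNA-source edges must
   have Rs < 0 and p < 0.05 (repression), TF-source edges Rs > 0 and
   p < 0.05 (activation); a triad survives only if every edge passes.
3. **Topology.** The refined network is projected to an undirected graph;
   hubs are ranked by **Maximal Clique Centrality** —
   MCC(v) = Σ over maximal cliques C ∋ v of (|C|−1)! — and modules are
   extracted with **Markov clustering (MCL)**.
4. **Clinical scoring.** Per-gene univariate Cox models (Breslow ties) give
   hazard ratios HR = exp(β); genes with Wald p < 0.05 form the roster, and
   each patient receives the hazard-weighted score
   `score(s) = (1/n) Σ_g z_gs · HR_g` over the n roster genes (z = per-gene
   z-normalized log2 expression). Patients are split at the maximally
   selected log-rank cut-point and compared by Kaplan–Meier / log-rank.
5. **Pharmacology.** Spearman screens link expression (|Rs| > 0.25,
   BH FDR < 0.05) or the patient score (|Rs| > 0.3, FDR < 0.05) to
   drug-response AUC; negative correlation (lower AUC = more sensitive)
   labels a pair *sensitive*, positive *resistant*. Multi-layer
   (mRNA/protein/methylation vs mutation/SCNA) bias between high- and
   low-score patients uses rank-sum + log fold-change or Fisher tests.

Every input can be simulated with planted truth (`sim_config()`,
`simulate_cohort()`), so the whole chain is testable without any download.

## Worked example

```r
library(triadnet)

cfg <- sim_config(seed = 3, edge_density = 0.5)
co  <- simulate_cohort(cfg)

# network construction and refinement
triads <- enumerate_ffls_from_edges(co$truth$edges)
rn     <- refine_ffls(triads, co$expr, co$mirna_expr, group = "simA")
glance(rn)
#> # A tibble: 1 x 10
#>   group n_triads n_tf_ffl n_mirna_ffl n_composite_ffl  n_tf n_mirna n_gene
#>   <chr>    <int>    <int>       <int>           <int> <int>   <int>  <int>
#> 1 simA        35        3          32               0     4       5     17

# hubs and modules
g  <- ffl_graph(rn)
head(mcc_scores(g), 3)
#> # A tibble: 3 x 4
#>   node    mcc degree betweenness
#>   <chr> <dbl>  <dbl>       <dbl>
#> 1 TF05     28     11        30.6
#> 2 miR04    24     10        26.1
#> 3 miR05    20     10        39.6

# hazard-weighted score and stratification
st <- score_stratify(co$expr, co$survival)
st$logrank
#> # A tibble: 1 x 4
#>   chisq    df  p_value n_groups
#>   <dbl> <int>    <dbl>    <int>
#> 1  82.4     1 1.13e-19        2

# drug-response screen on the score
score_drug_screen(st$score, co$drug_response)
#> # A tibble: 2 x 6
#>   feature drug      rho        p      fdr label
#>   <chr>   <chr>   <dbl>    <dbl>    <dbl> <chr>
#> 1 score   Drug01 -0.868 5.24e-62 7.86e-62 sensitive
#> 2 score   Drug02  0.874 6.84e-64 2.05e-63 resistant
```

The simulated cohort plants TF-activation and miRNA-repression effects on
log2 expression, survival times whose log-hazard is linear in z-normalized
expression of designated genes, and drug responses linearly coupled to
designated genes; the numbers above show the pipeline recovering exactly
that structure — 35 surviving triads including the planted ones, a strongly
separated Kaplan–Meier split (χ² = 82.4), and the planted
sensitising/resistance drug couplings with the correct labels.

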