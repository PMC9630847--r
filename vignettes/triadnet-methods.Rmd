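---
title: "Models and methods behind triadnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triadnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadnet)
```

`triadnet` analyses the co-regulation of a gene family by transcription
factors (TFs) and microRNAs: it builds feed-forward-loop (FFL) networks,
ranks hubs and extracts modules, converts per-gene hazard estimates into a
per-patient risk score, and screens expression and score against drug
response. This vignette explains the models, the tunable parameters, and
the numerical choices, in the package's own terms.

## 1. Regulatory edges and feed-forward loops

Four directed edge classes exist: TF→gene, miRNA→gene, TF→miRNA and
miRNA→TF. miRNA→target priors from several prediction sources are
integrated by a consensus rule: a pair is kept when it appears in at least
`min_sources = 2` distinct sources (`integrate_mirna_priors()`). TF→target
edges come from promoter scanning (section 2).

A triad (t, m, g) is an FFL when t→g and m→g both exist and the regulators
are cross-linked. The cross edge fixes the type: TF-FFL (only t→m),
miRNA-FFL (only m→t), composite-FFL (both). `enumerate_ffls()` emits triads
in lexicographic order, and the three types partition the triad set by
construction.

### Expression-based refinement

Within a sample group, every edge of every triad is tested with Spearman
correlation: miRNA-source edges are significant when `p < 0.05` and
`Rs < 0` (repression); TF-source edges when `p < 0.05` and `Rs > 0`
(activation). The same sign semantics are applied to the TF–miRNA cross
edges — activation for TF→miRNA, repression for miRNA→TF — because the
package treats regulator class, not edge position, as what determines the
expected sign. A triad survives only if **all** of its constituent edges
pass (strict AND, relaxable to the two target-directed edges with
`require_all = FALSE`). Degenerate inputs (constant expression, features
missing from a matrix) skip the triad with a recorded reason instead of
failing.

Two consequences are worth stating plainly:

* Spearman correlation is symmetric, so a composite-FFL — whose cross pair
  must satisfy `Rs > 0` (TF→miRNA) *and* `Rs < 0` (miRNA→TF) — can never
  survive the strict-AND filter. This is an honest property of combining
  the published sign rules with a per-triad AND, not an implementation
  accident; composite triads are therefore reported in the raw enumeration
  and excluded from recovery-rate statements.
* Under null expression each one-sided filter passes with probability about
  0.025 at `p < 0.05`, so a k-edge triad survives at about `0.025^k` —
  the property the null-calibration tests check.

## 2. Promoter scanning and exact motif p-values

Promoter windows are `[TSS − 1000, TSS + 200)` on the coding strand
(0-based half-open coordinates; minus-strand genes take the reverse
complement of the mirrored window; windows clipped at contig ends are
truncated and flagged). Position weight matrices are column-normalized
counts with a background-split pseudocount (default 0.8, uniform
background): `freq = (count + 0.8 · bg) / (colsum + 0.8)`. Scores are
`log2(freq / bg)` summed over a window; both strands are scanned.

A hit is retained when the tail probability of its score under the
background model is below `1e-5` (strict). The tail is computed by dynamic
programming over the distribution of the window score:

* **exact mode** (motif width ≤ 10): the DP carries the full achievable
  score support (partial sums merged at 10⁻⁹ resolution), so the tail
  equals exhaustive enumeration over all 4^w words to floating-point
  accuracy;
* **lattice mode** (wider motifs): scores are rounded to a lattice with bin
  width 10⁻³ on the log-odds scale; the reported tail is exact for
  integer-rescaled matrices and conservative within half a bin per column
  otherwise.

A query above the attainable maximum returns exactly 0; retained hits
always carry positive p-values because their scores are achieved. One
deterministic-width consequence the tests rely on: a width-w consensus-only
motif cannot beat `4^-w`, so the `1e-5` threshold needs w ≥ 9 — narrower
deterministic motifs simply cannot produce retained hits at the default
threshold.

TF→gene edges are one per (TF, promoter) with at least one retained hit,
deduplicated, carrying the best hit p-value as evidence
(`call_tf_gene_edges()`; idempotent and order-independent).

## 3. Network topology

FFL triads are projected to an undirected simple graph (one edge per
regulator–target relation; the projection is a documented choice, not a
canonical one). Hubs are ranked by Maximal Clique Centrality,

MCC(v) = Σ_{C ∋ v, C maximal clique} (|C| − 1)! ,

computed over Bron–Kerbosch maximal cliques. Nodes whose only maximal
cliques are single edges score their degree (each 2-clique contributes
1! = 1) — this emerges from the formula and needs no special case; isolated
nodes score 0. `top_k_core()` induces the subgraph on the k best nodes with
deterministic lexicographic tie-breaks.

Markov clustering (`mcl_cluster()`) runs the standard flow simulation:
unit self-loops (damping periodicity), column-stochastic normalization,
then alternating expansion (matrix squaring) and inflation (entrywise power
`r` = 2 by default, renormalized), with entries below 10⁻¹⁰ pruned each
iteration, until the iterate moves less than `tol = 1e-6` in max-norm or
`max_iter = 100` is hit (non-convergence returns the current clustering
with a warning). Clusters are read off as connected components of the
limit-matrix support; every node gets exactly one cluster.

## 4. Hazard-weighted patient score

Log2 expression is z-normalized per gene (sample standard deviation,
`n − 1`; constant genes become zero rows and are flagged). Each gene gets a
univariate Cox proportional-hazards fit (partial likelihood, Breslow tie
handling by default, Efron optional); `HR = exp(β)` with a two-sided Wald
p-value. A cohort with no events is an explicit error; constant expression
or non-convergence yields a flagged estimate, never a silent number.

Genes with Wald `p < 0.05` form the roster, and the per-patient score is
the roster mean of z-scores weighted by hazard ratios:

score(s) = (1 / n_genes) Σ_g z_{g,s} · HR_g .

The normalizer is the number of roster genes — the score is a per-patient
mean over genes; a per-sample normalizer would not define a per-patient
quantity at all. The score is linear in the z-matrix and reduces to
`z · HR` for a single-gene roster.

Patients are stratified at the cut-point maximizing the standardized
log-rank statistic over observed score values (maximally selected rank
statistic in the Lausen–Schumacher permutation-variance form, computed in
O(n log n) from Nelson–Aalen log-rank scores). Both groups must hold at
least `minprop = 0.1` of the cohort; ties take the lower cut-point, and
`minprop = 0.5` forces the median split. Because the cut-point is chosen to
maximize separation, the subsequent log-rank p-value is selection-biased;
the package reports it as such and applies no small-sample correction —
users comparing groups defined *a priori* should call `km_logrank()`
directly.

## 5. Drug-response association

Spearman screens run feature-by-drug with pairwise deletion of missing
values (≥ 3 shared samples per pair) and Benjamini–Hochberg adjustment
across **all pairs tested in one call** — that is the FDR family; callers
who want a different family split their calls. Retention requires
`|Rs| > 0.25` (expression vs cell-line AUC) or `|Rs| > 0.3` (score or
patient-level imputed response), both with `FDR < 0.05`, all strict
inequalities. Negative correlation with response is labeled *sensitive*
(lower AUC = greater sensitivity), positive *resistant*; the labeling is
anti-symmetric under response negation and invariant under monotone
response transforms.

Between high- and low-score groups (median split by default), continuous
layers (mRNA, protein, methylation) are compared per gene with the
Wilcoxon rank-sum test plus the log fold-change, and binary layers
(mutation, SCNA) with Fisher's exact test on the 2×2 table, each layer
BH-adjusted separately. The log fold-change is defined as the difference
of group means on the log2 scale — a deliberate, documented choice (means,
not medians) since competing conventions exist.

## 6. The synthetic cohort generator

`sim_config()` fixes the study conditions; the defaults used throughout the
tests are n = 200 samples, edge density 0.3 (0.5 where planted exemplar
triads are required), effect size 1 on the log2 scale, noise sd 0.3,
censoring 0.2, prior recall 0.9 and false-positive rate 0.05 per source —
values in the range of what cohort-scale expression studies report for
detectable regulatory effects. A single master seed drives everything;
per-stage child seeds are `(seed mod 2146489)·1000 + offset`, so stages
regenerate independently.

**Expression.** Root regulators are i.i.d. standard Gaussian. Target genes
follow `g = Σ coef · parent + N(0, noise_sd)` with `+effect` for TF parents
and `−effect` for miRNA parents. Cross-regulated regulators follow the same
linear model with two deliberate differences: cross effects enter at half
strength and the intrinsic noise stays standard Gaussian. The covariance
algebra explains why. With full-strength cross edges, a TF-FFL would give
`m = t + ε` and `g = t − m + δ = −ε + δ`, so cov(t, g) = 0 — the planted
TF→gene edge becomes statistically invisible and no refinement filter could
ever recover the triad. With the half-strength/unit-noise choice
(`m = t/2 + ε`, ε standard), cov(t, m) = 1/2, cov(t, g) = 1/2,
cov(m, g) = −3/4: all three edges carry their regulatory sign at
comfortably detectable magnitude for n = 200. Composite pairs would induce
a cycle; the generation order breaks it deterministically and the dropped
edge carries no structural signal (consistent with composite triads being
unrecoverable anyway, section 1).

**Designated exemplar triads.** At density ≥ 0.5 (and ≥ 2 nodes per class)
one triad of each type is planted deterministically and recorded in
`planted_triads`. Their nodes receive no *additional* planted regulators:
extra random parents would dilute the marginal correlations and the
recovery rate would measure confounder load rather than filter fidelity.
The rest of the network keeps the full random density, so enumeration and
topology still see a realistic edge mix.

**Survival.** Event times are exponential with hazard
`h0 · exp(Σ β_g z_g)`; censoring is an independent exponential whose single
rate is calibrated by root finding so the expected censored fraction equals
`censor_rate` (0 and 1 are handled as the all-events / all-censored
degenerate cases). **Drug response** is `intercept + Σ effect · expression
+ noise` per drug, with designated sensitising (negative) and
resistance-associated (positive) couplings and a null drug. **Promoters**
are uniform-background sequences carrying one PWM-sampled site at a
recorded position with probability `plant_rate`.

What the generator does **not** emulate: read-level counts and library-size
effects, copy-number segments, miRNA biogenesis, batch structure,
non-linear or context-dependent regulation, correlated censoring. Passing
tests therefore demonstrate that the algorithms recover the planted linear
structure under Gaussian noise at the stated n — they do not certify
performance on real cohorts with those additional complications.

## 7. Problem sizes used by the checks

The test-suite and the acceptance script run entirely on simulated data at
sizes chosen to make the statistical guarantees sharp while staying quick
on a laptop: 200 random instances (≤ 30 nodes) for enumeration
equivalence; 100 cohorts of n = 200 for refinement power and null
calibration; exhaustive-enumeration cross-checks up to 15-node graphs and
width-6 motifs; 50 seeds of n = 500 for Cox recovery (median HR within
[1.8, 2.2] of the planted 2.0) plus 500 null fits for Wald-p uniformity;
50 seeds of n = 400 for cut-point recovery; 200 null screens of 30 genes ×
8 drugs for FDR calibration.

## 8. Known limitations

* Refinement tests marginal correlations; it cannot separate direct from
  mediated regulation, and strongly confounded true edges can fail the
  sign filters (by design — the filters are the published rules).
* The cut-point p-value is selection-biased (section 4).
* The undirected projection for MCC/MCL discards edge direction; other
  projections would give other hub sets, which is why the projection is
  configurable at the triad-table level.
* Spearman p-values use the t approximation; at n < 10 exact permutation
  (used as the test oracle) would be preferable.
* The lattice DP p-value is conservative near bin boundaries for motifs
  wider than 10; the exact path covers the widths where exactness is
  testable.
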