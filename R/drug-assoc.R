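# Expression/score vs drug-response Spearman screens, sensitive/resistant
# labeling, multi-layer alteration bias between score groups, and the
# FFL-drug integrated network.

label_association <- function(rho) {
  dplyr::case_when(rho < 0 ~ "sensitive", rho > 0 ~ "resistant",
                   TRUE ~ NA_character_)
}

#' Gene-expression vs drug-response screen
#'
#' Spearman correlation of every gene against every drug over shared samples
#' (pairwise deletion of missing response values), BH adjustment across all
#' tested pairs of the call, and retention at `|Rs| > rs_threshold` and
#' `FDR < fdr_threshold` (both strict). Negative correlation with response
#' (lower AUC = more sensitive) is labeled `sensitive`, positive
#' `resistant`. Pairs with fewer than 3 shared samples or degenerate values
#' are skipped with a reason (attribute `skipped`).
#'
#' @param expr Expression tibble (features x samples).
#' @param drugs Response tibble (first column `sample`, one column per drug;
#'   AUC-like, lower = more sensitive).
#' @param rs_threshold Absolute-correlation threshold (default 0.25, the
#'   cell-line screen convention; use 0.3 for imputed patient response).
#' @param fdr_threshold BH FDR threshold (default 0.05).
#' @return Tibble `feature`, `drug`, `rho`, `p`, `fdr`, `label`, retained
#'   associations only, with all tested pairs in attribute `tested` and
#'   skipped pairs in attribute `skipped`.
#' @export
gene_drug_screen <- function(expr, drugs, rs_threshold = 0.25,
                             fdr_threshold = 0.05) {
  em <- expr_as_matrix(expr)
  stopifnot(is.data.frame(drugs), names(drugs)[1] == "sample")
  dm <- as.matrix(drugs[-1])
  rownames(dm) <- drugs$sample
  shared <- intersect(colnames(em), rownames(dm))
  em <- em[, shared, drop = FALSE]
  dm <- dm[shared, , drop = FALSE]

  complete <- !anyNA(dm) && !anyNA(em)
  if (complete && length(shared) >= 3L) {
    sm <- spearman_matrix(t(em), dm)
    tested <- tibble(feature = rep(rownames(em), times = ncol(dm)),
                     drug = rep(colnames(dm), each = nrow(em)),
                     rho = as.vector(sm$rho), p = as.vector(sm$p),
                     n = length(shared))
  } else {
    grid <- tidyr::expand_grid(feature = rownames(em), drug = colnames(dm))
    tested <- purrr::pmap_dfr(grid, function(feature, drug) {
      x <- em[feature, ]
      y <- dm[, drug]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L) {
        return(tibble(feature = feature, drug = drug, rho = NA_real_,
                      p = NA_real_, n = sum(ok)))
      }
      ct <- spearman_cor(x[ok], y[ok])
      tibble(feature = feature, drug = drug, rho = ct$rho, p = ct$p_value,
             n = ct$n)
    })
  }
  skipped <- tested |>
    filter(is.na(.data$rho)) |>
    mutate(reason = ifelse(.data$n < 3L, "too_few_samples",
                           "degenerate_feature"))
  tested_ok <- tested |> filter(!is.na(.data$rho))
  tested_ok <- tested_ok |>
    mutate(fdr = if (nrow(tested_ok)) bh_adjust(.data$p)$fdr else double())
  retained <- tested_ok |>
    filter(abs(.data$rho) > rs_threshold, .data$fdr < fdr_threshold) |>
    mutate(label = label_association(.data$rho)) |>
    select("feature", "drug", "rho", "p", "fdr", "label") |>
    arrange(.data$feature, .data$drug)
  attr(retained, "tested") <- tested_ok
  attr(retained, "skipped") <- skipped
  retained
}

#' Score vs drug-response screen
#'
#' [gene_drug_screen()] with a per-patient score as the single feature and
#' the imputed-response thresholds (`|Rs| > 0.3`, `FDR < 0.05`) as defaults.
#' A constant score is skipped with a degenerate-feature reason.
#'
#' @param score A `ptp_score_result` or named numeric vector.
#' @param drugs Response tibble (first column `sample`).
#' @param rs_threshold,fdr_threshold Retention thresholds.
#' @return As [gene_drug_screen()], with `feature = "score"`.
#' @export
score_drug_screen <- function(score, drugs, rs_threshold = 0.3,
                              fdr_threshold = 0.05) {
  if (inherits(score, "ptp_score_result")) {
    score <- setNames(score$score, score$sample)
  }
  expr <- matrix_as_expr(matrix(score, nrow = 1,
                                dimnames = list("score", names(score))),
                         id_col = "feature")
  gene_drug_screen(expr, drugs, rs_threshold = rs_threshold,
                   fdr_threshold = fdr_threshold)
}

#' Multi-layer alteration bias between score groups
#'
#' Compares high- versus low-score patients layer by layer: continuous layers
#' (mRNA, protein, methylation) per gene by Wilcoxon rank-sum with the group
#' log fold-change; binary layers (mutation, SCNA events) by Fisher's exact
#' test on the 2x2 altered-by-group table with the frequency difference. BH
#' adjustment is applied within each layer. The biased group is the sign of
#' the difference (high means larger in the high-score group). Genes missing
#' from a layer are recorded as untested.
#'
#' @param high,low Character vectors of sample ids.
#' @param layers Named list of feature tibbles (first column gene id, one
#'   column per sample).
#' @param binary_layers Names of layers to treat as binary 0/1 (default
#'   `c("mutation", "scna")` intersected with `names(layers)`).
#' @param genes Optional gene universe; defaults to the union over layers.
#' @return Tibble `gene`, `layer`, `statistic` (logFC or frequency
#'   difference), `p`, `fdr`, `biased_group` (`"high"`/`"low"`), `tested`.
#' @export
cag_bias <- function(high, low, layers,
                     binary_layers = intersect(c("mutation", "scna"),
                                               names(layers)),
                     genes = NULL) {
  stopifnot(is.list(layers), !is.null(names(layers)))
  genes <- genes %||% unique(unlist(purrr::map(layers, ~ .x[[1]])))
  purrr::imap_dfr(layers, function(layer_tbl, layer_name) {
    m <- expr_as_matrix(layer_tbl)
    hi <- intersect(high, colnames(m))
    lo <- intersect(low, colnames(m))
    binary <- layer_name %in% binary_layers
    purrr::map_dfr(genes, function(gn) {
      if (!gn %in% rownames(m) || length(hi) < 2L || length(lo) < 2L) {
        return(tibble(gene = gn, layer = layer_name, statistic = NA_real_,
                      p = NA_real_, biased_group = NA_character_,
                      tested = FALSE))
      }
      a <- m[gn, hi]
      b <- m[gn, lo]
      if (binary) {
        tab <- matrix(c(sum(a == 1), sum(a == 0), sum(b == 1), sum(b == 0)),
                      nrow = 2L)
        p <- fisher.test(tab)$p.value
        stat <- mean(a) - mean(b)       # frequency difference
      } else {
        rs <- rank_sum_logfc(a, b)
        p <- rs$p_value
        stat <- rs$logfc
      }
      tibble(gene = gn, layer = layer_name, statistic = stat, p = p,
             biased_group = dplyr::case_when(stat > 0 ~ "high",
                                             stat < 0 ~ "low",
                                             TRUE ~ NA_character_),
             tested = TRUE)
    }) |>
      (function(tb) {
        tb$fdr <- NA_real_
        tb$fdr[tb$tested] <- p.adjust(tb$p[tb$tested], method = "BH")
        tb
      })()
  }) |>
    select("gene", "layer", "statistic", "p", "fdr", "biased_group",
           "tested")
}

#' Integrated FFL-drug network
#'
#' Joins the refined co-regulatory network with feature-drug associations:
#' nodes are TFs, miRNAs, target genes, and drugs; edges are the triad
#' regulatory relations plus one association edge per retained feature-drug
#' pair, labeled sensitive/resistant.
#'
#' @param refined A `refined_network` or triad tibble.
#' @param gene_assocs,mirna_assocs,tf_assocs Association tibbles from
#'   [gene_drug_screen()] (any may be empty or NULL).
#' @return An undirected [igraph::graph] with vertex attribute `class`
#'   (TF/miRNA/gene/drug) and edge attributes `relation`
#'   (`"regulatory"`/`"association"`) and `label`.
#' @export
ffl_drug_network <- function(refined, gene_assocs = NULL,
                             mirna_assocs = NULL, tf_assocs = NULL) {
  triads <- if (inherits(refined, "refined_network")) refined$triads else
    refined
  g <- ffl_graph(triads)
  assoc <- bind_rows(gene_assocs, mirna_assocs, tf_assocs)
  if (is.null(assoc) || nrow(assoc) == 0L) {
    igraph::E(g)$relation <- "regulatory"
    igraph::E(g)$label <- NA_character_
    return(g)
  }
  assoc <- assoc |> filter(.data$feature %in% igraph::V(g)$name)
  drugs <- unique(assoc$drug)
  g <- igraph::add_vertices(g, length(drugs), name = drugs, class = "drug")
  igraph::E(g)$relation <- "regulatory"
  igraph::E(g)$label <- NA_character_
  if (nrow(assoc)) {
    g <- igraph::add_edges(
      g, rbind(match(assoc$feature, igraph::V(g)$name),
               match(assoc$drug, igraph::V(g)$name)),
      attr = list(relation = rep("association", nrow(assoc)),
                  label = assoc$label, rho = assoc$rho))
  }
  g
}
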