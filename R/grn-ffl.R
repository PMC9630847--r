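# miRNA-target prior integration, feed-forward-loop enumeration and typing,
# and expression-based refinement with signed correlation filters.

#' Integrate miRNA-target priors across sources
#'
#' Keeps a miRNA -> gene pair only when it is reported by at least
#' `min_sources` distinct sources (default 2), the standard multi-database
#' consensus rule. Evidence lists the supporting sources.
#'
#' @param sources Either a list of tibbles each with columns `mirna`,
#'   `target`, or one long tibble with columns `mirna`, `target`, `source`.
#' @param min_sources Minimum number of distinct supporting sources.
#' @return Regulatory-edge tibble: `regulator`, `regulator_class` (miRNA),
#'   `target`, `target_class`, `evidence` (`;`-joined source names),
#'   `n_sources`.
#' @export
integrate_mirna_priors <- function(sources, min_sources = 2L) {
  if (is.data.frame(sources)) {
    stopifnot(all(c("mirna", "target", "source") %in% names(sources)))
    long <- sources
    n_avail <- dplyr::n_distinct(long$source)
  } else {
    if (length(sources) < min_sources) {
      abort(sprintf("Need at least %d sources, got %d.", min_sources,
                    length(sources)))
    }
    nm <- names(sources) %||% sprintf("source%d", seq_along(sources))
    long <- purrr::imap_dfr(sources, function(s, i) {
      stopifnot(all(c("mirna", "target") %in% names(s)))
      mutate(s, source = if (is.character(i)) i else nm[[i]])
    })
    n_avail <- length(sources)
  }
  if (n_avail < min_sources) {
    abort(sprintf("Need at least %d sources, got %d.", min_sources, n_avail))
  }
  long |>
    distinct(.data$mirna, .data$target, .data$source) |>
    group_by(regulator = .data$mirna, target = .data$target) |>
    summarise(evidence = paste(sort(.data$source), collapse = ";"),
              n_sources = n(), .groups = "drop") |>
    filter(.data$n_sources >= min_sources) |>
    mutate(regulator_class = "miRNA", target_class = "gene") |>
    select("regulator", "regulator_class", "target", "target_class",
           "evidence", "n_sources") |>
    arrange(.data$regulator, .data$target)
}

validate_edge_classes <- function(edges, from, to) {
  if (nrow(edges) == 0L) return(invisible(edges))
  need <- c("regulator", "target")
  stopifnot(all(need %in% names(edges)))
  if ("regulator_class" %in% names(edges) &&
      !all(edges$regulator_class == from)) {
    abort(sprintf("Expected regulator_class '%s'.", from))
  }
  if ("target_class" %in% names(edges) && !all(edges$target_class == to)) {
    abort(sprintf("Expected target_class '%s'.", to))
  }
  if (any(edges$regulator == edges$target)) abort("Self-edges not allowed.")
  invisible(edges)
}

#' Enumerate and classify feed-forward loops
#'
#' A triad `(tf, mirna, gene)` is a feed-forward loop when both `tf -> gene`
#' and `mirna -> gene` exist and the TF and miRNA are cross-linked. The type
#' follows the direction of the cross edge: `TF-FFL` when only `tf -> mirna`
#' exists, `miRNA-FFL` when only `mirna -> tf` exists, and `composite-FFL`
#' when both do. Output is in lexicographic `(tf, mirna, target)` order.
#'
#' @param tf_gene,mirna_gene,tf_mirna,mirna_tf Edge tibbles with columns
#'   `regulator`, `target` (class columns optional but validated when
#'   present).
#' @return Tibble `tf`, `mirna`, `target`, `ffl_type`.
#' @export
enumerate_ffls <- function(tf_gene, mirna_gene, tf_mirna, mirna_tf) {
  validate_edge_classes(tf_gene, "TF", "gene")
  validate_edge_classes(mirna_gene, "miRNA", "gene")
  validate_edge_classes(tf_mirna, "TF", "miRNA")
  validate_edge_classes(mirna_tf, "miRNA", "TF")
  tg <- distinct(tf_gene, tf = .data$regulator, target = .data$target)
  mg <- distinct(mirna_gene, mirna = .data$regulator, target = .data$target)
  tm <- distinct(tf_mirna, tf = .data$regulator, mirna = .data$target)
  mt <- distinct(mirna_tf, mirna = .data$regulator, tf = .data$target)
  if (nrow(tg) == 0L || nrow(mg) == 0L) {
    return(tibble(tf = character(), mirna = character(), target = character(),
                  ffl_type = character()))
  }
  pairs <- inner_join(tg, mg, by = "target",
                      relationship = "many-to-many")
  pairs |>
    mutate(has_tm = purrr::map2_lgl(.data$tf, .data$mirna, function(t, m) {
      any(tm$tf == t & tm$mirna == m)
    }),
    has_mt = purrr::map2_lgl(.data$tf, .data$mirna, function(t, m) {
      any(mt$tf == t & mt$mirna == m)
    })) |>
    filter(.data$has_tm | .data$has_mt) |>
    mutate(ffl_type = dplyr::case_when(
      .data$has_tm & .data$has_mt ~ "composite-FFL",
      .data$has_tm ~ "TF-FFL",
      TRUE ~ "miRNA-FFL")) |>
    select("tf", "mirna", "target", "ffl_type") |>
    arrange(.data$tf, .data$mirna, .data$target)
}

#' Enumerate FFLs straight from a combined edge table
#'
#' Convenience front-end to [enumerate_ffls()] for a single edge tibble with
#' `regulator_class` / `target_class` columns (e.g. `truth$edges` from
#' [generate_truth()]).
#'
#' @param edges Combined regulatory-edge tibble.
#' @return Tibble as from [enumerate_ffls()].
#' @export
enumerate_ffls_from_edges <- function(edges) {
  pick <- function(rc, tc) filter(edges, .data$regulator_class == rc,
                                  .data$target_class == tc)
  enumerate_ffls(pick("TF", "gene"), pick("miRNA", "gene"),
                 pick("TF", "miRNA"), pick("miRNA", "TF"))
}

# Signed significance rule for one edge: TF-source edges must correlate
# positively, miRNA-source edges negatively, both at p < p_threshold.
edge_passes <- function(rho, p, regulator_class, p_threshold) {
  !is.na(rho) & !is.na(p) & p < p_threshold &
    ((regulator_class == "TF" & rho > 0) |
       (regulator_class == "miRNA" & rho < 0))
}

#' Refine feed-forward loops against an expression cohort
#'
#' Every edge of every triad is tested by Spearman correlation within the
#' given sample group. miRNA-source edges are significant at `p < p_threshold`
#' and `Rs < 0` (repression); TF-source edges at `p < p_threshold` and
#' `Rs > 0` (activation); the same sign rules apply to the TF-miRNA cross
#' edges. A triad survives only if all of its constituent edges pass
#' (strict AND; set `require_all = FALSE` to require only the two
#' target-directed edges). Triads with features missing from the matrices, or
#' with degenerate (constant) expression, are reported as skipped with a
#' reason rather than failing.
#'
#' @param triads Tibble from [enumerate_ffls()].
#' @param expr Expression tibble containing TF and target-gene rows.
#' @param mirna_expr Expression tibble containing miRNA rows.
#' @param samples Optional character vector restricting to a sample group
#'   (at least 3 samples); defaults to all shared samples.
#' @param group Label for the group (cancer type), stored on the result.
#' @param p_threshold Per-edge significance threshold (default 0.05).
#' @param require_all Require every edge of the triad to pass (default TRUE).
#' @return Object of class `refined_network`: list with `triads` (surviving
#'   triads with per-edge `rho`/`p` columns), `edge_stats` (per-edge tests for
#'   all triads), `skipped` (tibble with reasons), `group`, `nodes`.
#' @export
refine_ffls <- function(triads, expr, mirna_expr, samples = NULL,
                        group = "all", p_threshold = 0.05,
                        require_all = TRUE) {
  em <- expr_as_matrix(expr)
  mm <- expr_as_matrix(mirna_expr)
  samples <- samples %||% intersect(colnames(em), colnames(mm))
  if (length(samples) < 3L) abort("Need at least 3 samples in the group.")
  if (!all(samples %in% colnames(em)) || !all(samples %in% colnames(mm))) {
    abort("Some requested samples are absent from the expression matrices.")
  }
  em <- em[, samples, drop = FALSE]
  mm <- mm[, samples, drop = FALSE]
  val <- function(id) {
    if (id %in% rownames(em)) em[id, ] else if (id %in% rownames(mm)) {
      mm[id, ]
    } else NULL
  }

  # Unique edges implied by the triad list (cross edges by type).
  edges <- bind_rows(
    triads |> distinct(.data$tf, .data$target) |>
      mutate(regulator = .data$tf, node = .data$target,
             regulator_class = "TF", edge = "tf_gene"),
    triads |> distinct(.data$mirna, .data$target) |>
      mutate(regulator = .data$mirna, node = .data$target,
             regulator_class = "miRNA", edge = "mirna_gene"),
    triads |> filter(.data$ffl_type %in% c("TF-FFL", "composite-FFL")) |>
      distinct(.data$tf, .data$mirna) |>
      mutate(regulator = .data$tf, node = .data$mirna,
             regulator_class = "TF", edge = "tf_mirna"),
    triads |> filter(.data$ffl_type %in% c("miRNA-FFL", "composite-FFL")) |>
      distinct(.data$tf, .data$mirna) |>
      mutate(regulator = .data$mirna, node = .data$tf,
             regulator_class = "miRNA", edge = "mirna_tf")
  ) |>
    distinct(.data$regulator, .data$node, .data$regulator_class, .data$edge)

  edge_stats <- purrr::pmap_dfr(edges, function(regulator, node,
                                                regulator_class, edge, ...) {
    xv <- val(regulator)
    yv <- val(node)
    if (is.null(xv) || is.null(yv)) {
      return(tibble(regulator = regulator, node = node,
                    regulator_class = regulator_class, edge = edge,
                    rho = NA_real_, p = NA_real_, status = "missing_feature"))
    }
    ct <- spearman_cor(xv, yv)
    tibble(regulator = regulator, node = node,
           regulator_class = regulator_class, edge = edge,
           rho = ct$rho, p = ct$p_value, status = ct$status)
  })
  edge_stats <- edge_stats |>
    mutate(pass = edge_passes(.data$rho, .data$p, .data$regulator_class,
                              p_threshold))

  lookup <- function(reg, node, edge_name) {
    i <- which(edge_stats$regulator == reg & edge_stats$node == node &
                 edge_stats$edge == edge_name)
    if (length(i) == 0L) {
      tibble(rho = NA_real_, p = NA_real_, status = "absent", pass = NA)
    } else edge_stats[i[1], c("rho", "p", "status", "pass")]
  }
  assessed <- purrr::pmap_dfr(triads, function(tf, mirna, target, ffl_type,
                                               ...) {
    tg <- lookup(tf, target, "tf_gene")
    mg <- lookup(mirna, target, "mirna_gene")
    tm <- if (ffl_type %in% c("TF-FFL", "composite-FFL")) {
      lookup(tf, mirna, "tf_mirna")
    } else tibble(rho = NA_real_, p = NA_real_, status = "absent", pass = NA)
    mt <- if (ffl_type %in% c("miRNA-FFL", "composite-FFL")) {
      lookup(mirna, tf, "mirna_tf")
    } else tibble(rho = NA_real_, p = NA_real_, status = "absent", pass = NA)
    parts <- list(tf_gene = tg, mirna_gene = mg, tf_mirna = tm, mirna_tf = mt)
    used <- parts[!vapply(parts, function(p) p$status == "absent",
                          logical(1))]
    degenerate <- any(vapply(used, function(p) p$status != "ok", logical(1)))
    passes <- vapply(used, function(p) isTRUE(p$pass), logical(1))
    core <- c(isTRUE(tg$pass), isTRUE(mg$pass))
    survives <- if (degenerate) FALSE else if (require_all) {
      all(passes)
    } else all(core)
    reason <- if (any(vapply(used, function(p) p$status == "missing_feature",
                             logical(1)))) {
      "missing_feature"
    } else if (degenerate) "degenerate_expression" else if (!survives) {
      "filter_failed"
    } else NA_character_
    tibble(tf = tf, mirna = mirna, target = target, ffl_type = ffl_type,
           tf_gene_rho = tg$rho, tf_gene_p = tg$p,
           mirna_gene_rho = mg$rho, mirna_gene_p = mg$p,
           tf_mirna_rho = tm$rho, tf_mirna_p = tm$p,
           mirna_tf_rho = mt$rho, mirna_tf_p = mt$p,
           survives = survives, reason = reason)
  })
  surviving <- assessed |> filter(.data$survives) |> select(-"reason")
  skipped <- assessed |>
    filter(!.data$survives,
           .data$reason %in% c("missing_feature", "degenerate_expression")) |>
    select("tf", "mirna", "target", "ffl_type", "reason")
  nodes <- tibble(
    node = c(unique(surviving$tf), unique(surviving$mirna),
             unique(surviving$target)),
    class = c(rep("TF", dplyr::n_distinct(surviving$tf)),
              rep("miRNA", dplyr::n_distinct(surviving$mirna)),
              rep("gene", dplyr::n_distinct(surviving$target))))
  structure(list(triads = surviving, edge_stats = edge_stats,
                 skipped = skipped, group = group, nodes = nodes,
                 p_threshold = p_threshold),
            class = "refined_network")
}

#' @export
print.refined_network <- function(x, ...) {
  cat(sprintf("<refined_network '%s'> %d surviving triads (%d skipped)\n",
              x$group, nrow(x$triads), nrow(x$skipped)))
  invisible(x)
}

#' @method tidy refined_network
#' @export
tidy.refined_network <- function(x, ...) x$triads

#' @method glance refined_network
#' @export
glance.refined_network <- function(x, ...) {
  tibble(group = x$group,
         n_triads = nrow(x$triads),
         n_tf_ffl = sum(x$triads$ffl_type == "TF-FFL"),
         n_mirna_ffl = sum(x$triads$ffl_type == "miRNA-FFL"),
         n_composite_ffl = sum(x$triads$ffl_type == "composite-FFL"),
         n_tf = sum(x$nodes$class == "TF"),
         n_mirna = sum(x$nodes$class == "miRNA"),
         n_gene = sum(x$nodes$class == "gene"),
         n_skipped = nrow(x$skipped))
}

#' Merge per-group refined networks into a pan-cancer network
#'
#' Union of surviving triads across groups, each annotated with the set of
#' groups in which it survived; the node roster is the union by class.
#'
#' @param networks List of [refine_ffls()] results.
#' @return Tibble `tf`, `mirna`, `target`, `ffl_type`, `groups`
#'   (`;`-joined), `n_groups`, with the union node roster in attribute
#'   `nodes`.
#' @export
pan_cancer_merge <- function(networks) {
  stopifnot(length(networks) >= 1L,
            all(vapply(networks, inherits, logical(1), "refined_network")))
  merged <- purrr::map_dfr(networks, function(nw) {
    nw$triads |>
      select("tf", "mirna", "target", "ffl_type") |>
      mutate(group = nw$group)
  }) |>
    group_by(.data$tf, .data$mirna, .data$target, .data$ffl_type) |>
    summarise(groups = paste(sort(unique(.data$group)), collapse = ";"),
              n_groups = dplyr::n_distinct(.data$group), .groups = "drop") |>
    arrange(.data$tf, .data$mirna, .data$target)
  nodes <- purrr::map_dfr(networks, ~ .x$nodes) |> distinct()
  attr(merged, "nodes") <- nodes
  merged
}

#' Write a triad table or edge list to TSV
#'
#' @param x Tibble.
#' @param path File path.
#' @export
write_triads_tsv <- function(x, path) readr::write_tsv(x, path)
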