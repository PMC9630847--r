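# Hub and module analysis of the refined network: maximal cliques, Maximal
# Clique Centrality, top-k core subnetwork, degree/betweenness, and Markov
# clustering.

#' Project triads onto an undirected simple graph
#'
#' Each regulator-target relation of each triad becomes one undirected edge
#' (tf-target, mirna-target, tf-mirna); duplicates collapse, self-loops are
#' forbidden. Node classes (TF / miRNA / gene) are kept as a vertex
#' attribute.
#'
#' @param triads Triad tibble (`tf`, `mirna`, `target`, `ffl_type`) or a
#'   `refined_network`.
#' @return An undirected simple [igraph::graph].
#' @export
ffl_graph <- function(triads) {
  if (inherits(triads, "refined_network")) triads <- triads$triads
  stopifnot(all(c("tf", "mirna", "target") %in% names(triads)))
  nodes <- bind_rows(tibble(name = triads$tf, class = "TF"),
                     tibble(name = triads$mirna, class = "miRNA"),
                     tibble(name = triads$target, class = "gene")) |>
    distinct(.data$name, .keep_all = TRUE)
  edges <- bind_rows(tibble(from = triads$tf, to = triads$target),
                     tibble(from = triads$mirna, to = triads$target),
                     tibble(from = triads$tf, to = triads$mirna)) |>
    distinct()
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::simplify(g)
}

#' Enumerate maximal cliques
#'
#' All maximal cliques of an undirected simple graph (Bron-Kerbosch with
#' pivoting), each returned as a sorted character vector of vertex names.
#'
#' @param g An [igraph::graph] (undirected).
#' @return List of character vectors; empty list for the empty graph.
#' @export
maximal_cliques <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) return(list())
  cl <- igraph::max_cliques(g)
  out <- purrr::map(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}

#' Maximal Clique Centrality and companion centralities
#'
#' MCC of a node v is the sum over all maximal cliques C containing v of
#' `(|C| - 1)!`. An isolated node scores 0; a node whose only maximal cliques
#' are single edges scores its degree (each 2-clique contributes 1! = 1).
#' Degree and exact (Brandes) betweenness are reported alongside.
#'
#' @param g An undirected [igraph::graph].
#' @return Tibble `node`, `mcc`, `degree`, `betweenness`, sorted by
#'   decreasing `mcc` then node name.
#' @export
mcc_scores <- function(g) {
  stopifnot(igraph::is_igraph(g))
  nodes <- igraph::V(g)$name
  if (length(nodes) == 0L) {
    return(tibble(node = character(), mcc = double(), degree = double(),
                  betweenness = double()))
  }
  mcc <- setNames(numeric(length(nodes)), nodes)
  for (cl in maximal_cliques(g)) {
    if (length(cl) < 2L) next  # isolated vertices score 0
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1L)
  }
  tibble(node = nodes,
         mcc = unname(mcc[nodes]),
         degree = as.numeric(igraph::degree(g)),
         betweenness = as.numeric(igraph::betweenness(g, directed = FALSE))) |>
    arrange(dplyr::desc(.data$mcc), .data$node)
}

#' Top-k core subnetwork by MCC
#'
#' Induced subgraph on the k highest-MCC nodes; ties at the boundary are
#' broken lexicographically by node name (deterministic).
#'
#' @param g An undirected [igraph::graph].
#' @param scores Optional tibble from [mcc_scores()] (recomputed if omitted).
#' @param k Number of core nodes.
#' @return Induced [igraph::graph] on the selected nodes.
#' @export
top_k_core <- function(g, scores = NULL, k = 50L) {
  scores <- scores %||% mcc_scores(g)
  k <- min(k, nrow(scores))
  picked <- scores |>
    arrange(dplyr::desc(.data$mcc), .data$node) |>
    head(k) |>
    pull("node")
  igraph::induced_subgraph(g, picked)
}

#' Markov clustering (MCL)
#'
#' Column-stochastic flow simulation on the adjacency matrix with unit
#' self-loops: alternate expansion (matrix squaring) and inflation
#' (entrywise power + column renormalization) until the iterate changes by
#' less than `tol` (max absolute entry difference) or `max_iter` is reached.
#' Clusters are the connected components of the support of the limit matrix;
#' every node is assigned exactly one cluster.
#'
#' @param g An undirected [igraph::graph].
#' @param inflation Inflation exponent (> 1; default 2).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance (default 1e-6).
#' @param prune Entries below this are zeroed each iteration (numerical
#'   hygiene; default 1e-10).
#' @return Tibble `node`, `cluster` (integer, 1-based, ordered by first
#'   member), with attribute `converged` (logical).
#' @export
mcl_cluster <- function(g, inflation = 2, max_iter = 100L, tol = 1e-6,
                        prune = 1e-10) {
  stopifnot(igraph::is_igraph(g), igraph::vcount(g) >= 1L)
  if (inflation <= 1) abort("`inflation` must be > 1.")
  nodes <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  diag(A) <- 1  # self-loops damp periodicity
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged) warn("MCL did not converge; returning current clustering.")
  support <- (M + t(M)) > prune
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                        diag = FALSE))
  out <- tibble(node = nodes, cluster = as.integer(comp$membership))
  attr(out, "converged") <- converged
  out
}

#' Hubs and bottlenecks by centrality quantile
#'
#' Hubs are nodes with degree strictly above the `degree_quantile` of the
#' degree distribution; bottlenecks are nodes with exact Brandes betweenness
#' strictly above the `betweenness_quantile` of the betweenness distribution.
#' On a fully symmetric graph (all values equal) neither set is populated.
#'
#' @param g An undirected [igraph::graph].
#' @param degree_quantile,betweenness_quantile Quantile cut-offs in `[0, 1)`
#'   (default 0.9).
#' @return Tibble `node`, `degree`, `betweenness`, `is_hub`,
#'   `is_bottleneck`.
#' @export
hubs_bottlenecks <- function(g, degree_quantile = 0.9,
                             betweenness_quantile = 0.9) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) {
    return(tibble(node = character(), degree = double(),
                  betweenness = double(), is_hub = logical(),
                  is_bottleneck = logical()))
  }
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  dq <- quantile(deg, degree_quantile)
  bq <- quantile(btw, betweenness_quantile)
  tibble(node = igraph::V(g)$name,
         degree = as.numeric(deg),
         betweenness = as.numeric(btw),
         is_hub = deg > dq,
         is_bottleneck = btw > bq)
}

#' Export / import networks as GraphML or SIF
#'
#' @param g An [igraph::graph].
#' @param path File path.
#' @name network_io
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname network_io
#' @export
read_graphml <- function(path) igraph::read_graph(path, format = "graphml")

#' @rdname network_io
#' @param relation Interaction label written in the middle SIF column.
#' @export
write_sif <- function(g, path, relation = "interacts") {
  e <- igraph::as_edgelist(g)
  lines <- if (nrow(e)) sprintf("%s\t%s\t%s", e[, 1], relation, e[, 2])
  iso <- setdiff(igraph::V(g)$name, unique(as.vector(e)))
  writeLines(c(lines, iso), path)
  invisible(path)
}
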