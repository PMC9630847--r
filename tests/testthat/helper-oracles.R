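# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration / closed form, not by calling the package
# functions they check.

# Triple-loop FFL enumeration over explicit pair sets.
brute_ffls <- function(tf_gene, mirna_gene, tf_mirna, mirna_tf) {
  key <- function(a, b) paste(a, b, sep = "\r")
  tg <- key(tf_gene$regulator, tf_gene$target)
  mg <- key(mirna_gene$regulator, mirna_gene$target)
  tm <- key(tf_mirna$regulator, tf_mirna$target)
  mt <- key(mirna_tf$regulator, mirna_tf$target)
  tfs <- unique(c(tf_gene$regulator, tf_mirna$regulator, mirna_tf$target))
  mirs <- unique(c(mirna_gene$regulator, mirna_tf$regulator, tf_mirna$target))
  genes <- unique(c(tf_gene$target, mirna_gene$target))
  out <- list()
  for (t in tfs) for (m in mirs) for (g in genes) {
    if (!(key(t, g) %in% tg)) next
    if (!(key(m, g) %in% mg)) next
    has_tm <- key(t, m) %in% tm
    has_mt <- key(m, t) %in% mt
    if (!has_tm && !has_mt) next
    type <- if (has_tm && has_mt) "composite-FFL" else if (has_tm) {
      "TF-FFL"
    } else "miRNA-FFL"
    out[[length(out) + 1L]] <- data.frame(tf = t, mirna = m, target = g,
                                          ffl_type = type)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(tf = character(), mirna = character(),
                      target = character(), ffl_type = character())
  }
  res[order(res$tf, res$mirna, res$target), , drop = FALSE]
}

# Exhaustive maximal-clique enumeration by subset scan (adjacency matrix,
# feasible to ~15 nodes).
brute_max_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(members) >= 2L) {
      sub <- adj[members, members, drop = FALSE]
      if (any(sub[upper.tri(sub)] == 0)) next
    }
    outside <- setdiff(seq_len(n), members)
    extendable <- length(outside) > 0L &&
      any(vapply(outside, function(v) all(adj[v, members] == 1), logical(1)))
    if (!extendable) cliques[[length(cliques) + 1L]] <- sort(nodes[members])
  }
  cliques[order(vapply(cliques, paste, character(1), collapse = "|"))]
}

brute_mcc <- function(adj) {
  cl <- brute_max_cliques(adj)
  mcc <- stats::setNames(numeric(nrow(adj)), rownames(adj))
  for (s in cl) {
    if (length(s) < 2L) next
    mcc[s] <- mcc[s] + factorial(length(s) - 1L)
  }
  mcc
}

# Exact Brandes-free betweenness via shortest-path counting with matrix
# powers (walks of length == distance are exactly the shortest paths).
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  pow <- list(diag(n), adj)
  for (L in 2:max(2L, n)) pow[[L + 1L]] <- pow[[L]] %*% adj
  dist <- matrix(Inf, n, n)
  npaths <- matrix(0, n, n)
  for (s in 1:n) for (t in 1:n) {
    if (s == t) { dist[s, t] <- 0; npaths[s, t] <- 1; next }
    for (L in 1:n) {
      if (pow[[L + 1L]][s, t] > 0) {
        dist[s, t] <- L
        npaths[s, t] <- pow[[L + 1L]][s, t]
        break
      }
    }
  }
  btw <- stats::setNames(numeric(n), rownames(adj))
  for (v in 1:n) {
    tot <- 0
    for (s in 1:n) for (t in 1:n) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(dist[s, t])) next
      inner <- 0
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        inner <- npaths[s, v] * npaths[v, t]
      }
      tot <- tot + inner / npaths[s, t]
    }
    btw[v] <- tot
  }
  btw
}

# Step-up BH oracle: adjusted_i = min_{j >= i} (p_(j) * m / j), capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(po[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Tie-free Spearman closed form.
brute_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exhaustive two-sided rank-sum permutation p (no ties assumed).
brute_wilcox_p <- function(a, b) {
  z <- c(a, b)
  n <- length(z)
  k <- length(a)
  r <- rank(z)
  mu <- k * (n + 1) / 2
  obs <- abs(sum(r[seq_len(k)]) - mu)
  labs <- utils::combn(n, k)
  stat <- apply(labs, 2L, function(idx) abs(sum(r[idx]) - mu))
  mean(stat >= obs - 1e-9)
}

# Exhaustive PWM tail probability over all 4^w words.
brute_pwm_tail <- function(lom, s, background = rep(0.25, 4)) {
  w <- ncol(lom)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- words
  sc <- vapply(seq_len(nrow(words)), function(i) {
    sum(lom[cbind(words[i, ], seq_len(w))])
  }, numeric(1))
  pr <- vapply(seq_len(nrow(words)), function(i) {
    prod(background[words[i, ]])
  }, numeric(1))
  sum(pr[sc >= s - 1e-9])
}

# Random undirected simple graph as an adjacency matrix with letter names.
random_adj <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  adj
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

# Random class-consistent edge sets for FFL property tests.
random_edge_sets <- function(seed, n_tf = 5, n_mir = 5, n_gene = 8,
                             density = 0.3) {
  set.seed(seed)
  mk <- function(from, to) {
    g <- expand.grid(regulator = from, target = to,
                     stringsAsFactors = FALSE)
    g[stats::runif(nrow(g)) < density, , drop = FALSE]
  }
  tfs <- sprintf("t%d", 1:n_tf)
  mirs <- sprintf("m%d", 1:n_mir)
  genes <- sprintf("g%d", 1:n_gene)
  list(tf_gene = mk(tfs, genes), mirna_gene = mk(mirs, genes),
       tf_mirna = mk(tfs, mirs), mirna_tf = mk(mirs, tfs))
}
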