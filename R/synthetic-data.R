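# Synthetic-cohort generator: regulatory truth, expression, survival, drug
# response, prior edge lists, and promoter sequences with planted structure.

#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic cohort. Defaults are the
#' standing study conditions used throughout the test-suite: a small family of
#' target genes under TF activation (positive linear effect) and miRNA
#' repression (negative linear effect) with Gaussian noise on the log2 scale.
#'
#' A single master `seed` governs everything; per-stage child seeds are derived
#' as `(seed mod 2146489) * 1000 + stage_offset` (offsets 1..6 for truth,
#' priors, expression, survival, drugs, promoters), so any stage can be
#' regenerated independently and identically.
#'
#' @param seed Integer master seed.
#' @param n_tf,n_mirna,n_target Feature counts (each at least 1).
#' @param n_samples Number of samples (columns) in the cohort.
#' @param edge_density Probability in `[0, 1]` that any admissible
#'   regulator-target pair carries a true edge.
#' @param effect_size Absolute linear coefficient of a true edge on log2
#'   expression (TF edges `+effect_size`, miRNA edges `-effect_size`).
#' @param noise_sd Gaussian noise standard deviation (> 0), log2 units.
#' @param censor_rate Expected proportion of censored samples in `[0, 1]`.
#' @param prior_recall Per-source probability that a true miRNA-gene edge is
#'   reported.
#' @param prior_fpr Per-source rate at which decoy (false) edges are reported.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_tf = 5L, n_mirna = 5L, n_target = 20L,
                       n_samples = 200L, edge_density = 0.3,
                       effect_size = 1, noise_sd = 0.3, censor_rate = 0.2,
                       prior_recall = 0.9, prior_fpr = 0.05) {
  counts <- c(n_tf = n_tf, n_mirna = n_mirna, n_target = n_target,
              n_samples = n_samples)
  if (any(counts < 1L)) {
    abort("All counts (n_tf, n_mirna, n_target, n_samples) must be >= 1.")
  }
  probs <- c(edge_density = edge_density, censor_rate = censor_rate,
             prior_recall = prior_recall, prior_fpr = prior_fpr)
  if (any(probs < 0 | probs > 1)) {
    abort("edge_density, censor_rate, prior_recall, prior_fpr must be in [0, 1].")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  structure(list(seed = as.integer(seed), n_tf = as.integer(n_tf),
                 n_mirna = as.integer(n_mirna), n_target = as.integer(n_target),
                 n_samples = as.integer(n_samples), edge_density = edge_density,
                 effect_size = effect_size, noise_sd = noise_sd,
                 censor_rate = censor_rate, prior_recall = prior_recall,
                 prior_fpr = prior_fpr),
            class = "sim_config")
}

# Deterministic child seed per stage; keeps values well below 2^31.
derive_seed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 2146489L) * 1000L + as.integer(offset)
}

#' Generate the planted regulatory truth
#'
#' Samples directed true edges in the four admissible classes (TF->gene,
#' miRNA->gene, TF->miRNA, miRNA->TF) independently at `edge_density`, with
#' signed coefficients: `+effect_size` for TF-source edges (activation) and
#' `-effect_size` for miRNA-source edges (repression). When `edge_density > 0`
#' each class is guaranteed at least one edge (provided both node sets are
#' non-empty); when `edge_density >= 0.5` and all node sets have at least two
#' members, one triad of each feed-forward-loop type (TF-FFL, miRNA-FFL,
#' composite-FFL) is deterministically planted and recorded.
#'
#' Survival log-hazard coefficients are attached to the first
#' `n_survival_genes` target genes; drug effects couple designated genes to
#' `n_drugs` drugs with alternating sign (odd drugs sensitizing, i.e. negative
#' coefficient on response, even drugs resistance-associated) and the last
#' drug left null when `n_drugs >= 3`.
#'
#' @param config A [sim_config()].
#' @param survival_beta Log-hazard coefficient planted on survival genes
#'   (default `log(2)`).
#' @param n_survival_genes Number of target genes with non-zero hazard.
#' @param n_drugs Number of drugs in the response matrix.
#' @param drug_effect Absolute linear drug-coupling coefficient.
#' @return A list of class `planted_truth` with elements `edges` (tibble:
#'   `regulator`, `regulator_class`, `target`, `target_class`, `coefficient`),
#'   `planted_triads` (tibble of deterministically planted FFLs, possibly
#'   empty), `survival_betas` (tibble `gene`, `beta`), `drug_effects` (tibble
#'   `gene`, `drug`, `effect`), and the node rosters.
#' @export
generate_truth <- function(config, survival_beta = log(2),
                           n_survival_genes = max(1L, config$n_target %/% 4L),
                           n_drugs = 3L, drug_effect = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  tfs <- sprintf("TF%02d", seq_len(config$n_tf))
  mirs <- sprintf("miR%02d", seq_len(config$n_mirna))
  genes <- sprintf("G%03d", seq_len(config$n_target))

  sample_class <- function(from, to, from_class, to_class, coef) {
    pairs <- tidyr::expand_grid(regulator = from, target = to)
    keep <- runif(nrow(pairs)) < config$edge_density
    if (!any(keep) && config$edge_density > 0 && nrow(pairs) > 0) {
      keep[sample.int(nrow(pairs), 1L)] <- TRUE
    }
    pairs[keep, ] |>
      mutate(regulator_class = from_class, target_class = to_class,
             coefficient = coef)
  }
  eff <- config$effect_size
  edges <- bind_rows(
    sample_class(tfs, genes, "TF", "gene", eff),
    sample_class(mirs, genes, "miRNA", "gene", -eff),
    sample_class(tfs, mirs, "TF", "miRNA", eff),
    sample_class(mirs, tfs, "miRNA", "TF", -eff)
  )

  planted <- tibble(tf = character(), mirna = character(), target = character(),
                    ffl_type = character())
  if (config$edge_density >= 0.5 && config$n_tf >= 2L &&
      config$n_mirna >= 2L && config$n_target >= 2L) {
    add_edge <- function(ed, r, rc, t, tc, coef) {
      ed |>
        filter(!(.data$regulator == r & .data$target == t)) |>
        bind_rows(tibble(regulator = r, target = t, regulator_class = rc,
                         target_class = tc, coefficient = coef))
    }
    drop_edge <- function(ed, r, t) {
      filter(ed, !(.data$regulator == r & .data$target == t))
    }
    # TF-FFL on (TF1, miR1, G1): TF->miRNA cross edge only.
    edges <- edges |>
      add_edge(tfs[1], "TF", genes[1], "gene", eff) |>
      add_edge(mirs[1], "miRNA", genes[1], "gene", -eff) |>
      add_edge(tfs[1], "TF", mirs[1], "miRNA", eff) |>
      drop_edge(mirs[1], tfs[1])
    # miRNA-FFL on (TF2, miR2, G2): miRNA->TF cross edge only.
    edges <- edges |>
      add_edge(tfs[2], "TF", genes[2], "gene", eff) |>
      add_edge(mirs[2], "miRNA", genes[2], "gene", -eff) |>
      add_edge(mirs[2], "miRNA", tfs[2], "TF", -eff) |>
      drop_edge(tfs[2], mirs[2])
    # composite-FFL on (TF1, miR2, G2): both cross edges.
    edges <- edges |>
      add_edge(tfs[1], "TF", genes[2], "gene", eff) |>
      add_edge(mirs[2], "miRNA", genes[2], "gene", -eff) |>
      add_edge(tfs[1], "TF", mirs[2], "miRNA", eff) |>
      add_edge(mirs[2], "miRNA", tfs[1], "TF", -eff)
    planted <- tibble(
      tf = c(tfs[1], tfs[2], tfs[1]),
      mirna = c(mirs[1], mirs[2], mirs[2]),
      target = c(genes[1], genes[2], genes[2]),
      ffl_type = c("TF-FFL", "miRNA-FFL", "composite-FFL"))
    # The designated exemplar triads are isolated: no additional planted
    # regulators feed their nodes, so their recovery reflects the refinement
    # filters rather than confounder load. The rest of the network keeps the
    # full random density.
    allowed <- list()
    allowed[[genes[1]]] <- c(tfs[1], mirs[1])
    allowed[[genes[2]]] <- c(tfs[2], mirs[2], tfs[1])
    allowed[[mirs[1]]] <- tfs[1]
    allowed[[mirs[2]]] <- tfs[1]
    allowed[[tfs[1]]] <- mirs[2]
    allowed[[tfs[2]]] <- mirs[2]
    prot <- names(allowed)
    edges <- edges |>
      filter(!(.data$target %in% prot) |
               purrr::map2_lgl(.data$regulator, .data$target,
                               function(r, t) r %in% allowed[[t]]))
  }
  if (config$edge_density == 0) {
    edges <- edges[0, ]
  }
  edges <- edges |>
    distinct(.data$regulator, .data$target, .keep_all = TRUE) |>
    arrange(.data$regulator_class, .data$regulator, .data$target) |>
    select("regulator", "regulator_class", "target", "target_class",
           "coefficient")

  n_surv <- min(n_survival_genes, config$n_target)
  survival_betas <- tibble(gene = genes,
                           beta = c(rep(survival_beta, n_surv),
                                    rep(0, config$n_target - n_surv)))
  drugs <- sprintf("Drug%02d", seq_len(n_drugs))
  drug_effects <- purrr::map_dfr(seq_len(n_drugs), function(d) {
    if (d >= 3L && d == n_drugs) {
      return(tibble(gene = character(), drug = character(), effect = double()))
    }
    g <- genes[((d - 1L) %% config$n_target) + 1L]
    tibble(gene = g, drug = drugs[d],
           effect = if (d %% 2L == 1L) -drug_effect else drug_effect)
  })
  structure(list(edges = edges, planted_triads = planted,
                 survival_betas = survival_betas, drug_effects = drug_effects,
                 drugs = drugs, tfs = tfs, mirnas = mirs, genes = genes),
            class = "planted_truth")
}

#' Simulate noisy prior miRNA-target sources
#'
#' Emulates several target-prediction databases: each source reports each true
#' miRNA->gene edge independently with probability `recall` and adds decoy
#' edges (absent from the truth) at rate `fpr` over the non-edge pairs.
#'
#' @param truth A [generate_truth()] result.
#' @param n_sources Number of sources (at least 2).
#' @param recall Per-source recall probability.
#' @param fpr Per-source false-positive rate over non-edges.
#' @param seed Integer seed.
#' @return Tibble with columns `mirna`, `target`, `source`.
#' @export
generate_prior_sources <- function(truth, n_sources = 4L, recall = 0.9,
                                   fpr = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  if (n_sources < 2L) abort("`n_sources` must be >= 2.")
  set.seed(derive_seed(seed, 2L))
  true_pairs <- truth$edges |>
    filter(.data$regulator_class == "miRNA", .data$target_class == "gene") |>
    select(mirna = "regulator", target = "target")
  all_pairs <- tidyr::expand_grid(mirna = truth$mirnas, target = truth$genes)
  decoys <- anti_join(all_pairs, true_pairs, by = c("mirna", "target"))
  purrr::map_dfr(seq_len(n_sources), function(s) {
    hit <- true_pairs[runif(nrow(true_pairs)) < recall, ]
    fp <- decoys[runif(nrow(decoys)) < fpr, ]
    bind_rows(hit, fp) |> mutate(source = sprintf("source%d", s))
  })
}

# Breaks cycles among cross-regulatory edges so regulators can be generated in
# topological order; an edge is kept in the structural model only if its
# target cannot already reach its source.
acyclic_cross_edges <- function(cross) {
  if (nrow(cross) == 0L) return(cross)
  nodes <- unique(c(cross$regulator, cross$target))
  reach <- function(adj, from, to) {
    seen <- character(0); stack <- from
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v == to) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, adj[[v]] %||% character(0))
    }
    FALSE
  }
  adj <- setNames(vector("list", length(nodes)), nodes)
  keep <- logical(nrow(cross))
  for (i in seq_len(nrow(cross))) {
    r <- cross$regulator[i]; t <- cross$target[i]
    if (!reach(adj, t, r)) {
      adj[[r]] <- c(adj[[r]], t)
      keep[i] <- TRUE
    }
  }
  cross[keep, ]
}

#' Simulate log2 expression for the cohort
#'
#' Root regulators (those with no planted cross-regulatory parent) are i.i.d.
#' standard Gaussian across samples. Target genes follow the linear
#' structural model `value = sum(coefficient * parent) + N(0, noise_sd)`.
#' Regulators with cross-regulatory parents follow the same model with two
#' deliberate differences: cross-regulatory effects enter at half strength
#' (`coefficient / 2`) and the intrinsic noise is standard Gaussian (sd 1),
#' so every regulator keeps unit-scale variability of its own. This is what
#' makes a coherent planted feed-forward loop statistically recoverable: with
#' full-strength cross edges the miRNA would track its TF so closely that the
#' TF->gene and miRNA->gene contributions cancel and the marginal
#' correlations lose the signs the refinement filters test for (see the
#' methods vignette for the covariance algebra).
#'
#' Cross-regulatory cycles (which arise only for composite-FFL pairs) are
#' broken deterministically before generation; the dropped edge remains in the
#' truth edge list but carries no structural signal. Constant log2 baselines
#' (8 for TFs/genes, 6 for miRNAs) are added.
#'
#' @param truth A [generate_truth()] result.
#' @param config The [sim_config()].
#' @return List with `expr` (tibble, TFs + target genes x samples, first
#'   column `gene`) and `mirna_expr` (tibble, miRNAs x samples, first column
#'   `mirna`).
#' @export
generate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "planted_truth"), inherits(config, "sim_config"))
  if (config$noise_sd <= 0) abort("`noise_sd` must be > 0.")
  set.seed(derive_seed(config$seed, 3L))
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))

  cross <- truth$edges |>
    filter(.data$target_class %in% c("TF", "miRNA"))
  cross_dag <- acyclic_cross_edges(cross)
  regs <- c(truth$tfs, truth$mirnas)
  g <- igraph::graph_from_data_frame(
    cross_dag[, c("regulator", "target")], directed = TRUE,
    vertices = data.frame(name = regs))
  order <- igraph::V(g)$name[as.integer(igraph::topo_sort(g, mode = "out"))]

  vals <- matrix(0, nrow = length(regs) + length(truth$genes), ncol = n,
                 dimnames = list(c(regs, truth$genes), samples))
  for (v in order) {
    parents <- cross_dag[cross_dag$target == v, ]
    if (nrow(parents) == 0L) {
      vals[v, ] <- rnorm(n)
    } else {
      base <- colSums(vals[parents$regulator, , drop = FALSE] *
                        parents$coefficient / 2)
      vals[v, ] <- base + rnorm(n)
    }
  }
  gene_edges <- truth$edges |> filter(.data$target_class == "gene")
  for (gname in truth$genes) {
    parents <- gene_edges[gene_edges$target == gname, ]
    base <- if (nrow(parents)) {
      colSums(vals[parents$regulator, , drop = FALSE] * parents$coefficient)
    } else 0
    vals[gname, ] <- base + rnorm(n, sd = config$noise_sd)
  }
  vals[c(truth$tfs, truth$genes), ] <- vals[c(truth$tfs, truth$genes), ] + 8
  vals[truth$mirnas, ] <- vals[truth$mirnas, ] + 6

  list(expr = matrix_as_expr(vals[c(truth$tfs, truth$genes), , drop = FALSE],
                             "gene"),
       mirna_expr = matrix_as_expr(vals[truth$mirnas, , drop = FALSE],
                                   "mirna"))
}

#' Simulate survival with log-hazard linear in z-normalized expression
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(sum(beta_g * z_g))`, where `z_g` is the z-normalized
#' log2 expression of gene `g`. Censoring is independent exponential with the
#' single rate calibrated (by root finding) so the expected censored fraction
#' equals `censor_rate`; `censor_rate = 1` marks every sample censored.
#'
#' @param expr Expression tibble (genes x samples).
#' @param betas Tibble with columns `gene`, `beta`.
#' @param baseline_hazard Positive baseline hazard rate.
#' @param censor_rate Expected censored proportion in `[0, 1]`.
#' @param seed Integer seed.
#' @return Tibble with columns `sample`, `time` (> 0), `event` (0/1).
#' @export
generate_survival <- function(expr, betas, baseline_hazard = 0.1,
                              censor_rate = 0.2, seed = 1L) {
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be > 0.")
  if (censor_rate < 0 || censor_rate > 1) abort("`censor_rate` in [0, 1].")
  set.seed(derive_seed(seed, 4L))
  m <- expr_as_matrix(expr)
  betas <- betas |> filter(.data$gene %in% rownames(m), .data$beta != 0)
  lp <- rep(0, ncol(m))
  if (nrow(betas) > 0) {
    z <- t(scale(t(m[betas$gene, , drop = FALSE])))
    z[!is.finite(z)] <- 0
    lp <- colSums(z * betas$beta)
  }
  lambda <- baseline_hazard * exp(lp)
  t_event <- rexp(ncol(m), rate = lambda)
  if (censor_rate == 0) {
    return(tibble(sample = colnames(m), time = t_event, event = 1L))
  }
  if (censor_rate == 1) {
    return(tibble(sample = colnames(m), time = t_event, event = 0L))
  }
  # E[censored] for exponential censoring at rate mu: mean(mu / (mu + lambda)).
  f <- function(log_mu) mean(exp(log_mu) / (exp(log_mu) + lambda)) - censor_rate
  log_mu <- uniroot(f, lower = log(min(lambda)) - 20,
                    upper = log(max(lambda)) + 20)$root
  t_cens <- rexp(ncol(m), rate = exp(log_mu))
  tibble(sample = colnames(m),
         time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
}

#' Simulate a drug-response matrix coupled to expression
#'
#' Response (AUC-like; lower = more sensitive) for sample `s` and drug `d` is
#' `intercept + sum(effect_gd * expression_gs) + N(0, noise_sd)`.
#'
#' @param expr Expression tibble.
#' @param drug_effects Tibble with columns `gene`, `drug`, `effect`.
#' @param drugs Optional character vector of drug names (defaults to those in
#'   `drug_effects`); drugs without effects get pure-noise columns.
#' @param noise_sd Gaussian noise sd (> 0).
#' @param intercept Baseline response level.
#' @param seed Integer seed.
#' @return Tibble, samples x drugs, first column `sample`.
#' @export
generate_drug_response <- function(expr, drug_effects, drugs = NULL,
                                   noise_sd = 0.3, intercept = 0.5,
                                   seed = 1L) {
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  set.seed(derive_seed(seed, 5L))
  m <- expr_as_matrix(expr)
  drugs <- drugs %||% unique(drug_effects$drug)
  out <- sapply(drugs, function(d) {
    eff <- drug_effects |> filter(.data$drug == d, .data$gene %in% rownames(m))
    base <- if (nrow(eff)) {
      colSums(m[eff$gene, , drop = FALSE] * eff$effect)
    } else 0
    intercept + base + rnorm(ncol(m), sd = noise_sd)
  })
  out <- matrix(out, nrow = ncol(m), dimnames = list(colnames(m), drugs))
  tibble(sample = colnames(m)) |> dplyr::bind_cols(as_tibble(out))
}

#' Simulate promoter sequences with planted motif instances
#'
#' Uniform-background DNA sequences; with probability `plant_rate` a site is
#' sampled column-wise from the motif's frequency matrix and written at a
#' uniformly chosen position on the forward strand. The returned manifest
#' records every planted site.
#'
#' @param pwm A [pwm()] object.
#' @param n_seq Number of sequences.
#' @param length Sequence length (bases).
#' @param plant_rate Probability each sequence carries one planted site.
#' @param seed Integer seed.
#' @return List with `sequences` (named [Biostrings::DNAStringSet], names of
#'   the form `"prom_001 gene=G001 tss=1000 strand=+"`) and `manifest` (tibble
#'   `seq_id`, `start` 0-based, `strand`, `site`).
#' @export
generate_promoters <- function(pwm, n_seq = 50L, length = 1200L,
                               plant_rate = 1, seed = 1L) {
  stopifnot(inherits(pwm, "triadnet_pwm"))
  set.seed(derive_seed(seed, 6L))
  w <- ncol(pwm$freq)
  bases <- c("A", "C", "G", "T")
  ids <- sprintf("prom_%03d", seq_len(n_seq))
  seqs <- character(n_seq)
  manifest <- vector("list", n_seq)
  for (i in seq_len(n_seq)) {
    s <- sample(bases, length, replace = TRUE)
    if (length >= w && runif(1) < plant_rate) {
      site <- vapply(seq_len(w), function(j) {
        sample(bases, 1L, prob = pwm$freq[, j])
      }, character(1))
      pos <- sample.int(length - w + 1L, 1L) - 1L  # 0-based
      s[(pos + 1L):(pos + w)] <- site
      manifest[[i]] <- tibble(seq_id = ids[i], start = pos, strand = "+",
                              site = paste(site, collapse = ""))
    }
    seqs[i] <- paste(s, collapse = "")
  }
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- sprintf("%s gene=G%03d tss=%d strand=+",
                              ids, seq_len(n_seq), 1000L)
  list(sequences = sequences, manifest = bind_rows(manifest))
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper running [generate_truth()], [generate_expression()],
#' [generate_prior_sources()], [generate_survival()] and
#' [generate_drug_response()] under the config's master seed.
#'
#' @param config A [sim_config()].
#' @param ... Passed to [generate_truth()].
#' @return List with elements `truth`, `expr`, `mirna_expr`, `priors`,
#'   `survival`, `drug_response`, `config`.
#' @export
simulate_cohort <- function(config, ...) {
  truth <- generate_truth(config, ...)
  ex <- generate_expression(truth, config)
  priors <- generate_prior_sources(truth, n_sources = 4L,
                                   recall = config$prior_recall,
                                   fpr = config$prior_fpr, seed = config$seed)
  surv <- generate_survival(ex$expr, truth$survival_betas,
                            censor_rate = config$censor_rate,
                            seed = config$seed)
  drugs <- generate_drug_response(ex$expr, truth$drug_effects,
                                  drugs = truth$drugs, seed = config$seed)
  list(truth = truth, expr = ex$expr, mirna_expr = ex$mirna_expr,
       priors = priors, survival = surv, drug_response = drugs,
       config = config)
}

# ---- plain-text I/O ---------------------------------------------------------

#' Read and write the package's TSV formats
#'
#' Expression: first column the feature identifier, one column per sample.
#' Survival: `sample`, `time`, `event`. Drug response: `sample` then one
#' column per drug. Edge lists: `regulator`, `target`, `regulator_class`,
#' `source`. Numeric values use shortest round-trip formatting, so files
#' re-read bit-exactly.
#'
#' @param x Table to write.
#' @param path File path.
#' @name triadnet_io
#' @export
write_expression_tsv <- function(x, path) readr::write_tsv(x, path)

#' @rdname triadnet_io
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname triadnet_io
#' @export
write_survival_tsv <- function(x, path) {
  stopifnot(all(c("sample", "time", "event") %in% names(x)))
  readr::write_tsv(x, path)
}

#' @rdname triadnet_io
#' @export
read_survival_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(event = as.integer(.data$event))
}

#' @rdname triadnet_io
#' @export
write_edges_tsv <- function(x, path) readr::write_tsv(x, path)

#' @rdname triadnet_io
#' @export
read_edges_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname triadnet_io
#' @param truth A `planted_truth` object (JSON manifest I/O).
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
}

#' @rdname triadnet_io
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$edges <- as_tibble(raw$edges)
  raw$planted_triads <- as_tibble(raw$planted_triads)
  raw$survival_betas <- as_tibble(raw$survival_betas)
  raw$drug_effects <- as_tibble(raw$drug_effects)
  structure(raw, class = "planted_truth")
}
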