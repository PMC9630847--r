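test_that("sim_config validates its fields", {
  expect_error(sim_config(n_tf = 0), ">= 1")
  expect_error(sim_config(edge_density = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
})

test_that("generator output is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth$edges, b$truth$edges)
  expect_identical(a$expr, b$expr)
  expect_identical(a$survival, b$survival)
  expect_identical(a$drug_response, b$drug_response)
  expect_identical(a$priors, b$priors)
})

test_that("edge-density limits behave as specified", {
  empty <- generate_truth(sim_config(edge_density = 0))
  expect_equal(nrow(empty$edges), 0L)
  cfg <- sim_config(seed = 5, edge_density = 0.05, n_tf = 2, n_mirna = 2,
                    n_target = 2)
  tr <- generate_truth(cfg)
  combos <- paste(tr$edges$regulator_class, tr$edges$target_class)
  expect_setequal(unique(combos),
                  c("TF gene", "miRNA gene", "TF miRNA", "miRNA TF"))
})

test_that("a complete single-triple graph yields one composite FFL", {
  edges <- tibble::tibble(
    regulator = c("TF01", "miR01", "TF01", "miR01"),
    regulator_class = c("TF", "miRNA", "TF", "miRNA"),
    target = c("G001", "G001", "miR01", "TF01"),
    target_class = c("gene", "gene", "miRNA", "TF"),
    coefficient = c(1, -1, 1, -1))
  tri <- enumerate_ffls_from_edges(edges)
  expect_equal(nrow(tri), 1L)
  expect_equal(tri$ffl_type, "composite-FFL")
})

test_that("planted FFLs are recoverable by brute-force enumeration", {
  cfg <- sim_config(seed = 1, edge_density = 0.3, n_tf = 5, n_mirna = 5,
                    n_target = 20)
  tr <- generate_truth(cfg)
  pick <- function(rc, tc) {
    e <- tr$edges[tr$edges$regulator_class == rc & tr$edges$target_class ==
                    tc, ]
    e[, c("regulator", "target")]
  }
  got <- enumerate_ffls_from_edges(tr$edges)
  want <- brute_ffls(pick("TF", "gene"), pick("miRNA", "gene"),
                     pick("TF", "miRNA"), pick("miRNA", "TF"))
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$ffl_type, want$ffl_type)
  # one designated triad of each type at density >= 0.5
  tr2 <- generate_truth(sim_config(seed = 3, edge_density = 0.5, n_tf = 2,
                                   n_mirna = 2, n_target = 2))
  all_ffls <- enumerate_ffls_from_edges(tr2$edges)
  found <- dplyr::semi_join(tr2$planted_triads, all_ffls,
                            by = c("tf", "mirna", "target", "ffl_type"))
  expect_equal(nrow(found), 3L)
})

test_that("prior sources hit the recall/fpr contract at the extremes", {
  cfg <- sim_config(seed = 7)
  tr <- generate_truth(cfg)
  true_pairs <- tr$edges[tr$edges$regulator_class == "miRNA" &
                           tr$edges$target_class == "gene", ]
  perfect <- generate_prior_sources(tr, n_sources = 3, recall = 1, fpr = 0,
                                    seed = 2)
  for (s in unique(perfect$source)) {
    sub <- perfect[perfect$source == s, ]
    expect_setequal(paste(sub$mirna, sub$target),
                    paste(true_pairs$regulator, true_pairs$target))
  }
  none <- generate_prior_sources(tr, n_sources = 4, recall = 0, fpr = 0,
                                 seed = 2)
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(integrate_mirna_priors(
    list(tibble::tibble(mirna = character(), target = character()),
         tibble::tibble(mirna = character(), target = character())))), 0L)
  expect_error(generate_prior_sources(tr, n_sources = 1), ">= 2")
})

test_that("expression encodes the planted signs", {
  # single miRNA -> gene edge, tiny noise: Spearman exactly -1
  cfg <- sim_config(seed = 9, n_tf = 1, n_mirna = 1, n_target = 1,
                    n_samples = 50, edge_density = 0, noise_sd = 1e-9)
  tr <- generate_truth(cfg)
  tr$edges <- tibble::tibble(regulator = "miR01", regulator_class = "miRNA",
                             target = "G001", target_class = "gene",
                             coefficient = -1)
  ex <- generate_expression(tr, cfg)
  m <- expr_as_matrix(ex$expr)
  mm <- expr_as_matrix(ex$mirna_expr)
  expect_equal(spearman_cor(mm["miR01", ], m["G001", ])$rho, -1)
})

test_that("null expression gives uniform correlation p-values", {
  pvals <- vapply(1:300, function(s) {
    set.seed(s)
    spearman_cor(rnorm(30), rnorm(30))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("survival generation respects censoring contracts", {
  cfg <- sim_config(seed = 13, n_samples = 400)
  co <- simulate_cohort(cfg)
  ex <- co$expr
  none <- generate_survival(ex, co$truth$survival_betas, censor_rate = 0,
                            seed = 1)
  expect_true(all(none$event == 1L))
  allc <- generate_survival(ex, co$truth$survival_betas, censor_rate = 1,
                            seed = 1)
  expect_true(all(allc$event == 0L))
  expect_error(cox_screen(ex, allc), "No events")
  mid <- generate_survival(ex, co$truth$survival_betas, censor_rate = 0.3,
                           seed = 1)
  expect_true(all(mid$time > 0))
  # calibrated censoring lands near the requested rate
  expect_lt(abs(mean(1 - mid$event) - 0.3), 0.08)
  expect_error(generate_survival(ex, co$truth$survival_betas,
                                 baseline_hazard = 0), "> 0")
})

test_that("drug response carries the planted sign into the screen", {
  cfg <- sim_config(seed = 17, n_samples = 300)
  co <- simulate_cohort(cfg)
  assoc <- gene_drug_screen(co$expr, co$drug_response)
  eff <- co$truth$drug_effects
  for (i in seq_len(nrow(eff))) {
    row <- assoc[assoc$feature == eff$gene[i] & assoc$drug == eff$drug[i], ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$label, if (eff$effect[i] < 0) "sensitive" else
      "resistant")
  }
})

test_that("promoter planting writes sites where the manifest says", {
  det <- pwm(diag(4)[, c(1, 3, 4, 2)] * 10, name = "det", pseudocount = 0)
  # consensus ACGT order: columns A, G, T, C
  pr <- generate_promoters(det, n_seq = 10, length = 60, plant_rate = 1,
                           seed = 3)
  expect_equal(nrow(pr$manifest), 10L)
  seqs <- as.character(pr$sequences)
  for (i in seq_len(nrow(pr$manifest))) {
    st <- pr$manifest$start[i]
    expect_equal(substr(seqs[[i]], st + 1, st + 4), pr$manifest$site[i])
  }
  short <- generate_promoters(det, n_seq = 3, length = 2, plant_rate = 1,
                              seed = 3)
  expect_equal(nrow(short$manifest), 0L)
})

test_that("emitted files round-trip bit-exactly", {
  withr::with_tempdir({
    cfg <- sim_config(seed = 23, n_samples = 20)
    co <- simulate_cohort(cfg)
    write_expression_tsv(co$expr, "expr.tsv")
    expect_equal(read_expression_tsv("expr.tsv"), co$expr,
                 ignore_attr = TRUE)
    write_survival_tsv(co$survival, "surv.tsv")
    expect_equal(read_survival_tsv("surv.tsv"), co$survival,
                 ignore_attr = TRUE)
    write_edges_tsv(co$priors, "priors.tsv")
    expect_equal(read_edges_tsv("priors.tsv"), co$priors, ignore_attr = TRUE)
    write_truth_json(co$truth, "truth.json")
    back <- read_truth_json("truth.json")
    expect_equal(back$edges, co$truth$edges, ignore_attr = TRUE)
    expect_equal(back$survival_betas, co$truth$survival_betas,
                 ignore_attr = TRUE)
    p <- pwm(matrix(c(8, 1, 1, 0, 0, 9, 1, 0), nrow = 4), name = "M1")
    write_jaspar_pfm(p, "m1.pfm")
    p2 <- read_jaspar_pfm("m1.pfm")[[1]]
    expect_equal(p2$counts, p$counts, ignore_attr = TRUE)
    pr <- generate_promoters(p, n_seq = 4, length = 30, seed = 1)
    write_fasta(pr$sequences, "prom.fa")
    expect_equal(as.character(read_fasta("prom.fa")),
                 as.character(pr$sequences), ignore_attr = TRUE)
  })
})
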